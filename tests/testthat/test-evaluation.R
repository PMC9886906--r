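test_that("summed squared error behaves like a metric on patterns", {
  expect_equal(sse(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(sse(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(sse(1:3, 1:4), "equal length")
  set.seed(1)
  a <- runif(200); b <- runif(200)
  expect_equal(sse(a, b), sum((a - b)^2))
  expect_equal(sse(a, b), sse(b, a))
  expect_true(sse(a, b) > 0)
})

test_that("phoneme decoding equals the exhaustive nearest-neighbour scan", {
  lex <- tiny_lexicon()
  inv <- lex$inventory
  # exact encodings decode to themselves
  for (i in 1:5) {
    p <- encode_phonology(lex, item_phonemes(lex, i))
    expect_equal(decode_phonemes(p, inv)$labels,
                 phoneme_slots(lex, item_phonemes(lex, i)))
  }
  # random outputs agree with a plain double-loop oracle
  set.seed(2)
  for (r in 1:50) {
    out <- runif(200)
    dec <- decode_phonemes(out, inv)$labels
    m <- matrix(out, nrow = 25)
    oracle <- vapply(1:8, function(k) {
      d <- vapply(seq_len(ncol(inv)), function(j) sum((m[, k] - inv[, j])^2),
                  numeric(1))
      colnames(inv)[which.min(d)]
    }, character(1))
    expect_identical(dec, oracle)
  }
  # a slot nudged toward a different phoneme flips correctness
  p <- encode_phonology(lex, item_phonemes(lex, 1))
  other <- encode_phonology(lex, item_phonemes(lex, 2))
  mixed <- 0.4 * p + 0.6 * other
  expect_false(identical(decode_phonemes(mixed, inv)$labels,
                         phoneme_slots(lex, item_phonemes(lex, 1))))
  expect_error(decode_phonemes(runif(200), inv[, 0]), "empty")
})

test_that("semantic decoding equals the brute-force argmin with stable ties", {
  lex <- tiny_lexicon()
  S <- tiny_encodings()$S
  for (i in c(1, 7, 20))
    expect_equal(decode_semantics(S[, i], S)$item, i)
  set.seed(3)
  for (r in 1:50) {
    out <- runif(nrow(S))
    d <- colSums((S - out)^2)
    expect_equal(decode_semantics(out, S)$item, which.min(d))
  }
  # equidistant duplicate columns: lowest index wins, tie is flagged
  dup <- cbind(S[, 1], S[, 1], S[, 2])
  res <- decode_semantics(S[, 1], dup)
  expect_equal(res$item, 1)
  expect_true(res$tie)
})

test_that("nonword scoring accepts any attested family pronunciation", {
  lex <- tiny_lexicon()
  nw <- generate_nonwords(lex, 3, "inconsistent", seed = 4)
  for (i in seq_len(nrow(nw))) {
    for (pron in nw$acceptable[[i]]) {
      out <- encode_phonology(lex, pron)
      expect_true(score_nonword(out, nw$acceptable[[i]], lex))
    }
    # an unrelated word's phonology is rejected
    out_bad <- encode_phonology(lex, item_phonemes(lex, 1))
    same <- any(vapply(nw$acceptable[[i]], function(p)
      identical(p, item_phonemes(lex, 1)), logical(1)))
    if (!same) expect_false(score_nonword(out_bad, nw$acceptable[[i]], lex))
  }
  expect_error(score_nonword(runif(200), list(), lex), "empty")
})

test_that("evaluation summaries are consistent and order-invariant", {
  lex <- tiny_lexicon()
  net <- tiny_read_net()
  nw <- rbind(generate_nonwords(lex, 5, "consistent", seed = 1),
              generate_nonwords(lex, 5, "inconsistent", seed = 1))
  ev <- evaluate_model(net, lex, nonwords = nw, enc = tiny_encodings(),
                       condition = list(ovs = 30, ove = 30000, version = 1))
  wr <- ev$word_results
  expect_equal(nrow(wr), nrow(lex$items))
  expect_true(all(wr$phon_sse >= 0))
  expect_equal(ev$accuracy$reading_aloud, mean(wr$phon_correct))
  expect_equal(ev$accuracy$sp, mean(wr$sp_correct))
  expect_equal(unname(ev$nonword_accuracy["consistent"]),
               mean(ev$nonword_results$correct[
                 ev$nonword_results$condition == "consistent"]))
  # permutation invariance of the summaries
  perm <- sample(nrow(wr))
  expect_equal(mean(wr$phon_correct[perm]), ev$accuracy$reading_aloud)
  expect_true(all(wr$ovs == 30) && all(wr$version == 1))
})

test_that("an untrained network reads at chance", {
  lex <- tiny_lexicon()
  cfg <- triangle_config(lex)
  net <- init_network(cfg, seed = 9)
  for (cn in seq_along(net$weights)) net$weights[[cn]][] <- 0
  ev <- evaluate_model(net, lex, enc = tiny_encodings(), oral = FALSE)
  # all-0.5 output is far from every binary code: essentially nothing correct
  expect_lte(ev$accuracy$reading_aloud, 0.1)
  expect_true(all(ev$word_results$phon_sse > 10))
})

test_that("training-time loss and evaluation error share one definition", {
  lex <- tiny_lexicon()
  enc <- tiny_encodings()
  net <- tiny_read_net()
  tr <- forward_pass(net, "READ", list(orth = enc$O[, 3]))
  ev <- evaluate_model(net, lex, enc = enc, oral = FALSE)
  expect_equal(trial_loss(tr, "phon", enc$P[, 3], c(12, 12), "sse"),
               ev$word_results$phon_sse[3])
  expect_equal(sse(tr$acts$phon[, 13], enc$P[, 3]),
               ev$word_results$phon_sse[3])
})
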