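test_that("language specs are validated", {
  expect_error(language_spec(exception_fraction = 1), "exception_fraction")
  expect_error(language_spec(n_words = 1000, n_onsets = 10, n_rimes = 10),
               "infeasible")
  expect_error(language_spec(n_sem_features = 3,
                             sem_features_per_word = c(2, 8)),
               "n_sem_features")
  expect_error(language_spec(alphabet_size = 30), "alphabet_size")
})

test_that("generation is deterministic per seed and varies across seeds", {
  a <- build_language(tiny_spec(seed = 5))
  b <- build_language(tiny_spec(seed = 5))
  c <- build_language(tiny_spec(seed = 6))
  expect_identical(a$items, b$items)
  expect_identical(a$inventory, b$inventory)
  expect_false(identical(a$items$letters, c$items$letters))
})

test_that("a zero-exception language is fully consistent", {
  lex <- build_language(language_spec(n_words = 8, alphabet_size = 6,
                                      n_vowel_letters = 2, n_onsets = 4,
                                      n_rimes = 2, exception_fraction = 0,
                                      n_sem_features = 10,
                                      sem_features_per_word = c(1, 4),
                                      n_homophone_pairs = 0, seed = 3))
  expect_equal(nrow(lex$items), 8)
  expect_false(anyDuplicated(lex$items$letters) > 0)
  expect_true(all(lex$items$rc == 1))
})

test_that("the realized exception fraction matches the spec", {
  lex <- build_language(language_spec(n_words = 300, exception_fraction = 0.2,
                                      seed = 1))
  frac <- mean(lex$items$is_exception)
  expect_gte(frac, 0.18)
  expect_lte(frac, 0.22)
  # exception words are the minority pronunciation of their family
  expect_true(all(lex$items$rc[lex$items$is_exception] < 0.5))
})

test_that("homophone pairs share sound, split meanings and context units", {
  lex <- build_language(language_spec(n_homophone_pairs = 1, seed = 2))
  hp <- lex$items[lex$items$context_index > 0, ]
  expect_equal(nrow(hp), 2)
  expect_equal(hp$phonemes[1], hp$phonemes[2])
  expect_true(all(hp$context_index %in% 1:4))
  expect_false(hp$context_index[1] == hp$context_index[2])
  s1 <- as.integer(strsplit(hp$sem[1], ",")[[1]])
  s2 <- as.integer(strsplit(hp$sem[2], ",")[[1]])
  expect_length(intersect(s1, s2), 0)
  expect_true(all(lex$items$context_index[lex$items$phonemes %in%
                                            setdiff(lex$items$phonemes,
                                                    hp$phonemes)] == 0))
})

test_that("rime consistency equals the brute-force type count", {
  lex <- tiny_lexicon()
  it <- lex$items
  oracle <- vapply(seq_len(nrow(it)), function(i) {
    fam <- it$rime == it$rime[i]
    sum(fam & it$rime_phon == it$rime_phon[i]) / sum(fam)
  }, numeric(1))
  expect_equal(it$rc, oracle)
  expect_true(all(it$rc > 0 & it$rc <= 1))
  # hand-built family: 4 words, 3 sharing the pronunciation
  toy <- list(items = data.frame(rime = rep("ax", 4),
                                 rime_phon = c("a x", "a x", "a x", "o x")))
  expect_equal(rime_consistency(toy, 1), 0.75)
  expect_equal(rime_consistency(toy, 4), 0.25)
  singleton <- list(items = data.frame(rime = c("ax", "ef"),
                                       rime_phon = c("a x", "e f")))
  expect_equal(rime_consistency(singleton, 1), 1)
})

test_that("orthographic neighbourhood matches the pairwise oracle", {
  lex <- build_language(language_spec(seed = 4))
  it <- lex$items
  oracle <- vapply(seq_len(nrow(it)), function(i) {
    w <- strsplit(it$letters[i], "")[[1]]
    cands <- unique(it$letters)
    cands <- cands[nchar(cands) == length(w) & cands != it$letters[i]]
    sum(vapply(strsplit(cands, ""),
               function(b) sum(w != b) == 1L, logical(1)))
  }, numeric(1))
  expect_equal(it$ons, oracle)
  toy <- list(items = data.frame(letters = c("ba", "bo", "ta")))
  expect_equal(orth_neighbourhood(toy, 1), 2)
  unique_len <- list(items = data.frame(letters = c("ba", "abc")))
  expect_equal(orth_neighbourhood(unique_len, 2), 0)
})

test_that("frequency ranking and truncation build vocabulary conditions", {
  lex <- tiny_lexicon()
  for (k in c(1, 5, 10, 30)) {
    top <- top_vocabulary(lex, k)
    expect_length(top, k)
    expect_true(min(lex$items$wf[top]) >=
                  max(lex$items$wf[-top], -Inf))
  }
  expect_error(top_vocabulary(lex, 31), "exceeds")
})

test_that("word sampling follows normalized frequencies", {
  lex <- tiny_lexicon()
  # degenerate single-word vocabulary
  set.seed(1)
  expect_true(all(sample_word(lex, 50, vocab_size = 1) ==
                    top_vocabulary(lex, 1)))
  # two-word vocabulary: empirical proportion within 3 binomial SE
  top2 <- top_vocabulary(lex, 2)
  p1 <- lex$items$wf[top2[1]] / sum(lex$items$wf[top2])
  set.seed(2)
  draws <- sample_word(lex, 1e5, vocab_size = 2)
  se <- sqrt(p1 * (1 - p1) / 1e5)
  expect_lt(abs(mean(draws == top2[1]) - p1), 3 * se)
  # uniform case: chi-square goodness of fit should not reject
  ulex <- lex
  ulex$items$wf <- rep(1 / nrow(lex$items), nrow(lex$items))
  set.seed(3)
  u <- sample_word(ulex, 1e5)
  expect_gt(chisq.test(tabulate(u, 30))$p.value, 0.01)
})

test_that("nonwords are novel and carry the attested pronunciation sets", {
  lex <- build_language(language_spec(seed = 1))
  nc <- generate_nonwords(lex, 40, "consistent", seed = 9)
  ni <- generate_nonwords(lex, 40, "inconsistent", seed = 9)
  expect_false(any(nc$letters %in% lex$items$letters))
  expect_false(any(ni$letters %in% lex$items$letters))
  expect_true(all(lengths(nc$acceptable) == 1))
  expect_true(all(lengths(ni$acceptable) >= 2))
  # determinism
  expect_identical(generate_nonwords(lex, 40, "consistent", seed = 9), nc)
  # every acceptable pronunciation of an inconsistent nonword ends in an
  # attested pronunciation of some lexical rime family
  attested <- unique(lex$items$rime_phon)
  for (i in sample.int(nrow(ni), 5)) {
    for (p in ni$acceptable[[i]]) {
      tails <- vapply(seq_along(p), function(k)
        paste(p[k:length(p)], collapse = " "), character(1))
      expect_true(any(tails %in% attested))
    }
  }
  expect_error(generate_nonwords(lex, 1e5, "consistent", seed = 1),
               "insufficient")
})

test_that("encoders are injective over the lexicon", {
  lex <- tiny_lexicon()
  enc <- tiny_encodings()
  codes <- apply(rbind(enc$O, enc$P, enc$S, enc$C), 2, paste, collapse = "")
  expect_false(anyDuplicated(codes) > 0)
})
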