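test_that("initialisation is seeded and bounded", {
  cfg <- micro_config()
  a <- init_network(cfg, seed = 7)
  b <- init_network(cfg, seed = 7)
  c <- init_network(cfg, seed = 8)
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$weights, c$weights))
  expect_true(all(vapply(a$weights, function(w)
    all(abs(w) < cfg$init_range), logical(1))))
})

test_that("zero-weight units sit at logistic(0) and clamps override", {
  cfg <- micro_config()
  net <- init_network(cfg, seed = 1)
  for (cn in seq_along(net$weights)) net$weights[[cn]][] <- 0
  pats <- micro_patterns(net)
  tr <- forward_pass(net, "SP", list(sem = pats$sem))
  # clamped layer equals its input at every clamped step
  for (t in 2:9) expect_equal(tr$acts$sem[, t], pats$sem)
  # unclamped non-input layers are logistic(0) = 0.5 at every step
  expect_true(all(tr$acts$phon[, 2:9] == 0.5))
  expect_true(all(tr$acts$h_sp[, 2:9] == 0.5))
  # input layers are silent when not clamped
  expect_true(all(tr$acts$orth == 0))
  expect_true(all(tr$acts$ctx == 0))
})

test_that("the forward pass matches an independent R recurrence", {
  cfg <- micro_config()
  net <- init_network(cfg, seed = 3)
  pats <- micro_patterns(net, seed = 2)
  for (task in c("PS", "SP", "PP", "SS", "READ")) {
    sched <- make_schedule(net, task)
    tp <- task_patterns(task, pats)
    tr <- forward_pass(net, task, tp$clamps)
    # plain R re-implementation of the synchronous logistic recurrence
    ln <- net$layer_names
    acts <- lapply(net$layer_sizes, function(n) rep(0.5, n))
    for (l in seq_along(ln)) if (net$is_input[l]) acts[[l]][] <- 0
    for (t in seq_len(sched$steps)) {
      netin <- net$biases
      for (cn in which(sched$active)) {
        d <- net$conn_dst[cn]
        netin[[d]] <- netin[[d]] + drop(net$weights[[cn]] %*%
                                          acts[[net$conn_src[cn]]])
      }
      nxt <- acts
      for (l in seq_along(ln)) {
        ci <- which(sched$clamp_layer + 1 == l & sched$clamp_from <= t &
                      sched$clamp_to >= t)
        if (length(ci) == 1) nxt[[l]] <- tp$clamps[[sched$clamp_roles[ci]]]
        else if (net$is_input[l]) nxt[[l]][] <- 0
        else nxt[[l]] <- 1 / (1 + exp(-netin[[l]]))
      }
      acts <- nxt
      for (l in seq_along(ln))
        expect_equal(tr$acts[[l]][, t + 1], acts[[l]], tolerance = 1e-12)
    }
  }
})

test_that("trial loss matches direct summation and flags bad windows", {
  cfg <- micro_config()
  net <- init_network(cfg, seed = 4)
  pats <- micro_patterns(net, seed = 5)
  tr <- forward_pass(net, "SP", list(sem = pats$sem))
  # manual summation oracle over the scored window
  manual_sse <- 0
  manual_ce <- 0
  eps <- 1e-10
  for (t in 7:8) {
    a <- tr$acts$phon[, t + 1]
    manual_sse <- manual_sse + sum((a - pats$phon)^2)
    p <- pmin(pmax(a, eps), 1 - eps)
    manual_ce <- manual_ce - sum(pats$phon * log(p) +
                                   (1 - pats$phon) * log(1 - p))
  }
  expect_equal(trial_loss(tr, "phon", pats$phon, c(7, 8), "sse"), manual_sse)
  expect_equal(trial_loss(tr, "phon", pats$phon, c(7, 8), "cross_entropy"),
               manual_ce)
  # perfect reproduction scores zero; a half-off unit scores 0.25 under SSE
  expect_equal(trial_loss(tr, "sem", pats$sem, c(3, 8), "sse"), 0)
  tr2 <- tr
  tr2$acts$phon[] <- 0.5
  target <- rep(0, nrow(tr$acts$phon)); target[1] <- 1
  expect_equal(trial_loss(tr2, "phon", c(1, rep(0.5, length(target) - 1)),
                          c(8, 8), "sse"), 0.25)
  expect_error(trial_loss(tr, "phon", pats$phon, c(7, 9), "sse"), "window")
})

test_that("BPTT gradients match finite differences on a small network", {
  cfg <- micro_config()
  net <- init_network(cfg, seed = 6)
  pats <- micro_patterns(net, seed = 7)
  eps <- 1e-4
  for (task in c("SP", "READ")) {
    tp <- task_patterns(task, pats)
    sched <- make_schedule(net, task)
    g <- bptt_gradient(net, task, tp$clamps, tp$targets)
    for (cn in which(sched$active)) {
      set.seed(cn)
      for (i in sample(length(net$weights[[cn]]), 3)) {
        np <- net; np$weights[[cn]][i] <- np$weights[[cn]][i] + eps
        nm <- net; nm$weights[[cn]][i] <- nm$weights[[cn]][i] - eps
        fd <- (trace_loss(np, sched, tp$clamps, tp$targets, "cross_entropy") -
                 trace_loss(nm, sched, tp$clamps, tp$targets, "cross_entropy")) /
          (2 * eps)
        expect_equal(g$gw[[cn]][i], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("frozen parameters receive exactly zero gradient and never move", {
  cfg <- micro_config()
  net <- init_network(cfg, seed = 8)
  net$frozen_conn[1] <- TRUE
  pats <- micro_patterns(net, seed = 9)
  tp <- task_patterns("READ", pats)
  g <- bptt_gradient(net, "READ", tp$clamps, tp$targets)
  expect_true(all(g$gw[[1]] == 0))
  expect_true(any(g$gw[[2]] != 0))
  # an achieved target yields zero loss and zero gradient under SSE
  z <- init_network(cfg, seed = 1)
  for (cn in seq_along(z$weights)) z$weights[[cn]][] <- 0
  half <- lapply(setNames(z$layer_sizes, z$layer_names),
                 function(n) rep(0.5, n))
  g0 <- bptt_gradient(z, "SP", list(sem = half$sem),
                      list(phon = half$phon), loss = "sse")
  expect_equal(g0$loss, 0)
  expect_true(all(vapply(g0$gw, function(w) all(w == 0), logical(1))))
})

test_that("oral training draws tasks at the 40/40/10/10 mixture", {
  lex <- tiny_lexicon()
  cfg <- triangle_config(lex)
  net <- init_network(cfg, seed = 2)
  res <- train_oral(net, lex, ovs = 30, ove = 10000, seed = 3,
                    enc = tiny_encodings())
  counts <- res$task_counts
  expect_equal(sum(counts), 10000)
  probs <- c(PS = 0.4, SP = 0.4, PP = 0.1, SS = 0.1)
  for (tk in names(probs)) {
    se <- sqrt(probs[tk] * (1 - probs[tk]) * 10000)
    expect_lt(abs(counts[tk] - probs[tk] * 10000), 3 * se)
  }
})

test_that("training is bit-identical under a fixed seed", {
  lex <- tiny_lexicon()
  cfg <- triangle_config(lex)
  net <- init_network(cfg, seed = 2)
  a <- train_oral(net, lex, ovs = 20, ove = 2000, seed = 5,
                  enc = tiny_encodings())$net
  b <- train_oral(net, lex, ovs = 20, ove = 2000, seed = 5,
                  enc = tiny_encodings())$net
  expect_identical(a$weights, b$weights)
  expect_identical(a$biases, b$biases)
})

test_that("reading training freezes every oral-phase parameter", {
  lex <- tiny_lexicon()
  net <- tiny_oral_net()
  r <- train_reading(net, lex, 2000, seed = 6, enc = tiny_encodings())
  oral <- which(net$config$wiring$route %in% c("PS", "SP", "ATT_P", "ATT_S"))
  for (cn in oral)
    expect_identical(r$net$weights[[cn]], net$weights[[cn]])
  expect_identical(r$net$biases$phon, net$biases$phon)
  expect_identical(r$net$biases$sem, net$biases$sem)
  # the reading route does change
  expect_false(identical(r$net$weights[["h_op->phon"]],
                         net$weights[["h_op->phon"]]))
  # a zero-trial phase is a no-op
  r0 <- train_reading(net, lex, 0, seed = 6, enc = tiny_encodings())
  expect_identical(r0$net$weights, freeze_oral(net)$weights)
})

test_that("oral training teaches both spoken-language mappings", {
  lex <- tiny_lexicon()
  net <- tiny_oral_net()
  ev <- evaluate_model(net, lex, enc = tiny_encodings())
  expect_gte(ev$accuracy$sp, 0.9)
  expect_gte(ev$accuracy$ps, 0.9)
})

test_that("trained attractors hold a clamped pattern through free cycling", {
  lex <- tiny_lexicon()
  enc <- tiny_encodings()
  net0 <- init_network(triangle_config(lex), seed = 1)
  net1 <- tiny_oral_net()
  final_sse <- function(net) {
    mean(vapply(1:10, function(i) {
      tr <- forward_pass(net, "PP", list(phon = enc$P[, i]))
      sse(tr$acts$phon[, tr$steps + 1], enc$P[, i])
    }, numeric(1)))
  }
  trained <- final_sse(net1)
  untrained <- final_sse(net0)
  expect_lt(trained, 0.2 * untrained)
  expect_lt(trained, 10)
})

test_that("network parameters survive the plain-text round trip", {
  lex <- tiny_lexicon()
  net <- freeze_oral(tiny_oral_net())
  stem <- file.path(tempdir(), "tiny_net")
  write_network(net, stem)
  back <- read_network(stem, lex)
  for (k in seq_along(net$weights))
    expect_identical(back$weights[[k]], net$weights[[k]])
  expect_identical(back$biases, net$biases)
  expect_identical(back$frozen_conn, net$frozen_conn)
  expect_identical(back$oral_trained_bias, net$oral_trained_bias)
  # the reloaded network computes the same outputs
  enc <- tiny_encodings()
  a <- forward_pass(net, "READ", list(orth = enc$O[, 1]))
  b <- forward_pass(back, "READ", list(orth = enc$O[, 1]))
  expect_identical(a$acts$phon, b$acts$phon)
})

test_that("reading training reaches high word accuracy on a tiny language", {
  lex <- tiny_lexicon()
  net <- tiny_read_net()
  ev <- evaluate_model(net, lex, enc = tiny_encodings(), oral = FALSE)
  expect_gte(ev$accuracy$reading_aloud, 0.9)
})
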