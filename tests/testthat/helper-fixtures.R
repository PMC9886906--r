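# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# 30-word language used for fast training tests
tiny_spec <- function(seed = 5) {
  language_spec(n_words = 30, alphabet_size = 8, n_vowel_letters = 2,
                n_onsets = 10, n_rimes = 8, exception_fraction = 0.15,
                n_sem_features = 30, sem_features_per_word = c(2, 6),
                n_homophone_pairs = 1, seed = seed)
}

tiny_lexicon <- function() cached("tiny_lexicon", function() {
  build_language(tiny_spec())
})

tiny_encodings <- function() cached("tiny_encodings", function() {
  lexicon_encodings(tiny_lexicon())
})

# oral-trained tiny network, reused by several tests; 60K trials gives the
# 30-word language roughly 800 presentations per word on the mapping tasks
tiny_oral_net <- function() cached("tiny_oral_net", function() {
  cfg <- triangle_config(tiny_lexicon())
  net <- init_network(cfg, seed = 1)
  train_oral(net, tiny_lexicon(), ovs = 30, ove = 60000, seed = 11,
             enc = tiny_encodings())$net
})

# fully trained tiny network (oral + reading)
tiny_read_net <- function() cached("tiny_read_net", function() {
  train_reading(tiny_oral_net(), tiny_lexicon(), 30000, seed = 12,
                enc = tiny_encodings())$net
})

# a 27-unit network with the full triangle wiring, for gradient oracles
micro_config <- function() {
  cfg <- triangle_config(tiny_lexicon())
  cfg$layer_sizes <- c(orth = 4L, phon = 4L, sem = 3L, ctx = 2L,
                       h_op = 2L, h_os1 = 2L, h_os2 = 2L, h_ps = 2L,
                       h_sp = 2L, att_p = 2L, att_s = 2L)
  cfg
}

micro_patterns <- function(net, seed = 1) {
  set.seed(seed)
  sizes <- setNames(net$layer_sizes, net$layer_names)
  lapply(sizes, function(n) as.numeric(runif(n) > 0.5))
}

# loss of one trial recomputed in R from the forward trace (the
# finite-difference oracle evaluates this, independent of the C++ backward)
trace_loss <- function(net, sched, clamps, targets, loss) {
  tr <- forward_pass(net, sched, clamps)
  tot <- 0
  for (i in seq_along(sched$target_layer)) {
    role <- sched$target_roles[i]
    lay <- net$layer_names[sched$target_layer[i] + 1]
    tot <- tot + trial_loss(tr, lay, targets[[role]],
                            c(sched$target_from[i], sched$target_to[i]), loss)
  }
  tot
}

task_patterns <- function(task, pats) {
  clamps <- switch(task,
    PS = list(phon = pats$phon, ctx = pats$ctx),
    SP = list(sem = pats$sem),
    PP = list(phon = pats$phon),
    SS = list(sem = pats$sem),
    READ = list(orth = pats$orth))
  targets <- switch(task,
    PS = list(sem = pats$sem), SP = list(phon = pats$phon),
    PP = list(phon = pats$phon), SS = list(sem = pats$sem),
    READ = list(phon = pats$phon, sem = pats$sem))
  list(clamps = clamps, targets = targets)
}

# synthetic word-results table with a planted consistency effect:
# phon_sse = intercept + beta * rc + noise, covariates independent
planted_word_results <- function(n = 200, beta = -0.3, noise_sd = 0.1,
                                 seed = 1, intercept = 0.5) {
  set.seed(seed)
  rc <- runif(n, 0.1, 1)
  data.frame(item = seq_len(n), rc = rc,
             phon_sse = intercept + beta * rc + rnorm(n, 0, noise_sd),
             log_wf = rnorm(n), ons = rpois(n, 3),
             img = sample(2:8, n, replace = TRUE),
             phon_correct = TRUE)
}

# the scaled-down replication grid (the expensive fixture; built once)
toy_grid_results <- function() cached("toy_grid", function() {
  lex <- build_language(language_spec())
  run_grid(lex, grid_spec(), base_seed = 1)
})
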