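#' Configure the triangle network
#'
#' Defines the layer sizes, pathway wiring, trial time courses and training
#' hyperparameters of the recurrent triangle network. The three key layers
#' (orthography, phonology, semantics) are linked by hidden layers: one on the
#' direct orthography-to-phonology route, two on the deeper
#' orthography-to-semantics route, and one each on the phonology-to-semantics
#' and semantics-to-phonology routes. Phonology and semantics each have a
#' recurrent attractor (cleanup) layer, and four context units feed the
#' phonology-to-semantics hidden layer to disambiguate homophone meanings.
#' All wiring is fully connected layer-to-layer.
#'
#' @param lexicon a `lexicon`; fixes the orthographic, phonological and
#'   semantic layer sizes.
#' @param h_op,h_os1,h_os2,h_ps,h_sp hidden-layer sizes.
#' @param att_p,att_s attractor-layer sizes.
#' @param steps_oral,steps_read network time steps per oral and reading trial.
#' @param oral_target_window,read_target_window steps over which targets are
#'   scored (oral: the last two of eight; reading: steps seven to twelve).
#' @param att_clamp,att_target_window attractor trials clamp the pattern for
#'   the first two steps and score the free-running steps against it.
#' @param learning_rate online stochastic-gradient learning rate (both phases).
#' @param init_range initial weights drawn uniformly from `(-r, r)`.
#' @param init_act initial activation of non-input layers at step 0.
#' @param loss training objective per output unit: `"cross_entropy"` (default)
#'   or `"sse"`. Evaluation always uses summed squared error.
#' @return An object of class `triangle_config`.
#' @export
triangle_config <- function(lexicon,
                            h_op = 60, h_os1 = 50, h_os2 = 50,
                            h_ps = 50, h_sp = 50, att_p = 30, att_s = 30,
                            steps_oral = 8, steps_read = 12,
                            oral_target_window = c(7, 8),
                            read_target_window = c(7, 12),
                            att_clamp = c(1, 2), att_target_window = c(3, 8),
                            learning_rate = 0.005, init_range = 0.1,
                            init_act = 0.5,
                            loss = c("cross_entropy", "sse")) {
  loss <- match.arg(loss)
  sizes <- c(orth = 14L * lexicon$spec$alphabet_size, phon = 8L * 25L,
             sem = lexicon$spec$n_sem_features, ctx = 4L,
             h_op = as.integer(h_op), h_os1 = as.integer(h_os1),
             h_os2 = as.integer(h_os2), h_ps = as.integer(h_ps),
             h_sp = as.integer(h_sp), att_p = as.integer(att_p),
             att_s = as.integer(att_s))
  wiring <- data.frame(
    src = c("orth", "h_op", "orth", "h_os1", "h_os2",
            "phon", "ctx", "h_ps", "sem", "h_sp",
            "phon", "att_p", "sem", "att_s"),
    dst = c("h_op", "phon", "h_os1", "h_os2", "sem",
            "h_ps", "h_ps", "sem", "h_sp", "phon",
            "att_p", "phon", "att_s", "sem"),
    route = c("OP", "OP", "OS", "OS", "OS",
              "PS", "PS", "PS", "SP", "SP",
              "ATT_P", "ATT_P", "ATT_S", "ATT_S"),
    stringsAsFactors = FALSE)
  bad <- setdiff(c(wiring$src, wiring$dst), names(sizes))
  if (length(bad) > 0) stop("wiring references unknown layer: ", bad[1])
  structure(list(layer_sizes = sizes, wiring = wiring,
                 steps_oral = steps_oral, steps_read = steps_read,
                 oral_target_window = oral_target_window,
                 read_target_window = read_target_window,
                 att_clamp = att_clamp, att_target_window = att_target_window,
                 learning_rate = learning_rate, init_range = init_range,
                 init_act = init_act, loss = loss),
            class = "triangle_config")
}

conn_labels <- function(config) {
  paste(config$wiring$src, config$wiring$dst, sep = "->")
}

#' Initialise network parameters
#'
#' Weights are drawn i.i.d. uniform on `(-init_range, init_range)`; biases
#' start at zero. Layers with no incoming connections (orthography, context)
#' are input layers: zero when not clamped.
#'
#' @param config a [triangle_config()].
#' @param seed integer seed; identical seeds give identical parameters.
#' @return An object of class `triangle_net`.
#' @export
init_network <- function(config, seed = 1) {
  set.seed(seed)
  ln <- names(config$layer_sizes)
  nc <- nrow(config$wiring)
  is_input <- !ln %in% config$wiring$dst
  weights <- lapply(seq_len(nc), function(c) {
    nr <- config$layer_sizes[[config$wiring$dst[c]]]
    ncl <- config$layer_sizes[[config$wiring$src[c]]]
    matrix(runif(nr * ncl, -config$init_range, config$init_range), nr, ncl)
  })
  names(weights) <- conn_labels(config)
  biases <- lapply(config$layer_sizes, numeric)
  structure(list(config = config, layer_names = ln,
                 layer_sizes = unname(config$layer_sizes),
                 conn_src = match(config$wiring$src, ln),
                 conn_dst = match(config$wiring$dst, ln),
                 weights = weights, biases = biases, is_input = is_input,
                 frozen_conn = rep(FALSE, nc),
                 frozen_bias = rep(FALSE, length(ln)),
                 oral_trained_conn = rep(FALSE, nc),
                 oral_trained_bias = rep(FALSE, length(ln)),
                 seed = seed),
            class = "triangle_net")
}

#' @export
print.triangle_net <- function(x, ...) {
  cat("<triangle_net>", length(x$layer_names), "layers,",
      length(x$weights), "connections,",
      format(sum(vapply(x$weights, length, numeric(1))) +
               sum(vapply(x$biases, length, numeric(1))), big.mark = ","),
      "parameters\n")
  invisible(x)
}

net_to_cpp <- function(net) {
  list(layer_sizes = as.integer(net$layer_sizes),
       conn_src = as.integer(net$conn_src - 1L),
       conn_dst = as.integer(net$conn_dst - 1L),
       weights = unname(net$weights), biases = unname(net$biases),
       is_input = net$is_input, init_act = net$config$init_act)
}

task_routes <- list(PS = c("PS", "ATT_S"), SP = c("SP", "ATT_P"),
                    PP = "ATT_P", SS = "ATT_S",
                    READ = c("OP", "OS", "PS", "SP", "ATT_P", "ATT_S"))
task_codes <- c(PS = 0L, SP = 1L, PP = 2L, SS = 3L, READ = 4L)

#' Trial schedule for a task
#'
#' Returns the clamping windows, target windows, total steps and active
#' connection set that define one trial of a task. Oral mapping tasks (PS, SP)
#' clamp the input for all eight steps and score the target on the last two;
#' attractor tasks (PP, SS) clamp the pattern for two steps and score the six
#' free-running steps against it; reading clamps orthography for twelve steps
#' and scores both phonological and semantic targets on steps seven to twelve.
#'
#' @param net a `triangle_net` (or a `triangle_config`).
#' @param task one of `"PS"`, `"SP"`, `"PP"`, `"SS"`, `"READ"`.
#' @return A `trial_schedule` list.
#' @export
make_schedule <- function(net, task = c("PS", "SP", "PP", "SS", "READ")) {
  task <- match.arg(task)
  config <- if (inherits(net, "triangle_config")) net else net$config
  ln <- names(config$layer_sizes)
  li <- function(nm) match(nm, ln) - 1L   # 0-based for the C++ core
  active <- config$wiring$route %in% task_routes[[task]]
  ow <- as.integer(config$oral_target_window)
  aw <- as.integer(config$att_target_window)
  rw <- as.integer(config$read_target_window)
  s <- switch(task,
    PS = list(steps = config$steps_oral,
              clamp_layer = c(li("phon"), li("ctx")),
              clamp_from = c(1L, 1L), clamp_to = rep(config$steps_oral, 2),
              clamp_roles = c("phon", "ctx"),
              target_layer = li("sem"), target_from = ow[1], target_to = ow[2],
              target_roles = "sem"),
    SP = list(steps = config$steps_oral,
              clamp_layer = li("sem"), clamp_from = 1L,
              clamp_to = config$steps_oral, clamp_roles = "sem",
              target_layer = li("phon"), target_from = ow[1], target_to = ow[2],
              target_roles = "phon"),
    PP = list(steps = config$steps_oral,
              clamp_layer = li("phon"), clamp_from = config$att_clamp[1],
              clamp_to = config$att_clamp[2], clamp_roles = "phon",
              target_layer = li("phon"), target_from = aw[1], target_to = aw[2],
              target_roles = "phon"),
    SS = list(steps = config$steps_oral,
              clamp_layer = li("sem"), clamp_from = config$att_clamp[1],
              clamp_to = config$att_clamp[2], clamp_roles = "sem",
              target_layer = li("sem"), target_from = aw[1], target_to = aw[2],
              target_roles = "sem"),
    READ = list(steps = config$steps_read,
                clamp_layer = li("orth"), clamp_from = 1L,
                clamp_to = config$steps_read, clamp_roles = "orth",
                target_layer = c(li("phon"), li("sem")),
                target_from = rep(rw[1], 2), target_to = rep(rw[2], 2),
                target_roles = c("phon", "sem")))
  for (f in c("steps", "clamp_layer", "clamp_from", "clamp_to",
              "target_layer", "target_from", "target_to"))
    s[[f]] <- as.integer(s[[f]])
  s$task <- task
  s$active <- active
  class(s) <- "trial_schedule"
  s
}

check_patterns <- function(net, sched, clamps) {
  ln <- net$layer_names
  for (i in seq_along(sched$clamp_layer)) {
    role <- sched$clamp_roles[i]
    if (is.null(clamps[[role]]))
      stop("missing clamp pattern for layer '", role, "'")
    want <- net$layer_sizes[sched$clamp_layer[i] + 1L]
    if (length(clamps[[role]]) != want)
      stop("clamp pattern for '", role, "' has length ",
           length(clamps[[role]]), ", expected ", want)
  }
  lapply(sched$clamp_roles, function(r) as.numeric(clamps[[r]]))
}

#' Run one trial forward
#'
#' Synchronous discrete-time update: each unit's net input at step t is the
#' weighted sum of the previous step's source activations plus its bias,
#' passed through the logistic function; clamped layers are overridden by
#' their input pattern during the clamp window.
#'
#' @param net a `triangle_net`.
#' @param task task name, or a `trial_schedule`.
#' @param clamps named list of input patterns, keyed by clamp role
#'   (e.g. `list(phon = ..., ctx = ...)`).
#' @param contributions if `TRUE`, record per-connection net-input
#'   contributions at every step (needed for division-of-labour measures).
#' @return An `activation_trace`: per-layer activation matrices
#'   (units x steps+1, column 1 the initial state) and, optionally,
#'   per-connection contribution matrices (units x steps).
#' @export
forward_pass <- function(net, task, clamps, contributions = FALSE) {
  sched <- if (inherits(task, "trial_schedule")) task else make_schedule(net, task)
  cp <- check_patterns(net, sched, clamps)
  res <- cpp_forward(net_to_cpp(net), sched, cp, contributions)
  acts <- res$acts
  names(acts) <- net$layer_names
  if (any(!vapply(acts, function(a) all(is.finite(a)), logical(1))))
    stop("non-finite activations in forward pass")
  out <- list(acts = acts, steps = sched$steps, task = sched$task,
              schedule = sched)
  if (contributions) {
    names(res$contrib) <- names(net$weights)
    out$contrib <- res$contrib
  }
  class(out) <- "activation_trace"
  out
}

#' Trial loss over a scored window
#'
#' Sums the per-unit, per-step loss between a layer's activations and a target
#' pattern over the scored steps. This R implementation is the package's
#' reference definition of the training objective.
#'
#' @param trace an `activation_trace` from [forward_pass()].
#' @param layer layer name.
#' @param target target pattern.
#' @param window integer `c(from, to)` steps.
#' @param loss `"cross_entropy"` or `"sse"`.
#' @return A scalar loss.
#' @export
trial_loss <- function(trace, layer, target, window,
                       loss = c("cross_entropy", "sse")) {
  loss <- match.arg(loss)
  if (window[1] < 1 || window[2] > trace$steps)
    stop("scored window outside the trial schedule")
  a <- trace$acts[[layer]][, (window[1] + 1):(window[2] + 1), drop = FALSE]
  if (nrow(a) != length(target)) stop("target length does not match layer size")
  eps <- 1e-10
  total <- 0
  for (j in seq_len(ncol(a))) {
    if (loss == "sse") total <- total + sum((a[, j] - target)^2)
    else {
      p <- pmin(pmax(a[, j], eps), 1 - eps)
      total <- total - sum(target * log(p) + (1 - target) * log(1 - p))
    }
  }
  total
}

#' Backpropagation-through-time gradients for one trial
#'
#' @param net a `triangle_net`.
#' @param task task name or `trial_schedule`.
#' @param clamps named list of clamp patterns (see [forward_pass()]).
#' @param targets named list of target patterns, keyed by target role.
#' @param loss training objective; defaults to the network's configured loss.
#' @return A list with the trial `loss`, per-connection weight gradients `gw`
#'   and per-layer bias gradients `gb`. Frozen parameters get exactly zero.
#' @export
bptt_gradient <- function(net, task, clamps, targets, loss = NULL) {
  sched <- if (inherits(task, "trial_schedule")) task else make_schedule(net, task)
  if (is.null(loss)) loss <- net$config$loss
  cp <- check_patterns(net, sched, clamps)
  tp <- lapply(seq_along(sched$target_layer), function(i) {
    role <- sched$target_roles[i]
    if (is.null(targets[[role]])) stop("missing target pattern for '", role, "'")
    as.numeric(targets[[role]])
  })
  res <- cpp_bptt(net_to_cpp(net), sched, cp, tp, loss)
  gw <- res$gw
  names(gw) <- names(net$weights)
  gb <- res$gb
  names(gb) <- net$layer_names
  for (c in which(net$frozen_conn)) gw[[c]][] <- 0
  for (l in which(net$frozen_bias)) gb[[l]][] <- 0
  list(loss = res$loss, gw = gw, gb = gb)
}

# per-task trainable masks: active, unfrozen connections; biases of their
# non-input destination layers
task_train_masks <- function(net, sched) {
  trainable_conn <- sched$active & !net$frozen_conn
  dst <- unique(net$conn_dst[trainable_conn])
  trainable_bias <- rep(FALSE, length(net$layer_names))
  trainable_bias[dst] <- TRUE
  trainable_bias <- trainable_bias & !net$is_input & !net$frozen_bias
  list(conn = trainable_conn, bias = trainable_bias)
}

cpp_task_spec <- function(net, task) {
  sched <- make_schedule(net, task)
  masks <- task_train_masks(net, sched)
  c(unclass(sched), list(code = task_codes[[task]],
                         trainable_conn = masks$conn,
                         trainable_bias = masks$bias))
}

run_training <- function(net, lexicon, tasks, task_probs, cand, n_trials,
                         seed = NULL, log_every = 1000, enc = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(enc)) enc <- lexicon_encodings(lexicon)
  specs <- lapply(tasks, function(tk) cpp_task_spec(net, tk))
  wf <- lexicon$items$wf[cand]
  cum <- cumsum(wf / sum(wf))
  res <- cpp_train(net_to_cpp(net), specs, cumsum(task_probs),
                   enc$O, enc$P, enc$S, enc$C,
                   as.integer(cand - 1L), cum,
                   as.integer(n_trials), net$config$learning_rate,
                   net$config$loss, as.integer(log_every))
  net$weights <- setNames(res$weights, names(net$weights))
  net$biases <- setNames(lapply(res$biases, as.numeric), net$layer_names)
  log <- data.frame(trial = res$log[, 1], mean_loss = res$log[, 2])
  counts <- setNames(res$task_count, names(task_codes))
  list(net = net, log = log, task_counts = counts[tasks])
}

#' Oral-language training phase
#'
#' Trains the spoken-language mappings: the oral comprehension task (PS), the
#' meaning-naming task (SP) and the two attractor tasks (PP, SS), interleaved
#' at a 40/40/10/10 per cent mixture. Each trial draws a word with replacement,
#' frequency-weighted, from the `ovs` most frequent words. Context units are
#' clamped as input on PS trials for homophone meanings.
#'
#' @param net a `triangle_net`.
#' @param lexicon a `lexicon`.
#' @param ovs oral vocabulary size (number of distinct trained spoken words).
#' @param ove oral vocabulary exposure (total number of oral training trials).
#' @param seed integer seed; fixed seeds give bit-identical results.
#' @param log_every record mean training loss every this many trials.
#' @param enc optional precomputed [lexicon_encodings()].
#' @return A list with the trained `net` (oral connections flagged as trained),
#'   the training `log` and the realized `task_counts`.
#' @export
train_oral <- function(net, lexicon, ovs, ove, seed = NULL, log_every = 1000,
                       enc = NULL) {
  if (ovs > nrow(lexicon$items)) stop("ovs exceeds lexicon size")
  cand <- top_vocabulary(lexicon, ovs)
  out <- run_training(net, lexicon, c("PS", "SP", "PP", "SS"),
                      c(0.4, 0.4, 0.1, 0.1), cand, ove, seed, log_every, enc)
  oral_conn <- net$config$wiring$route %in% c("PS", "SP", "ATT_P", "ATT_S")
  out$net$oral_trained_conn <- out$net$oral_trained_conn | oral_conn
  dst <- unique(out$net$conn_dst[oral_conn])
  ob <- out$net$oral_trained_bias
  ob[dst] <- TRUE
  out$net$oral_trained_bias <- ob & !out$net$is_input
  out
}

#' Freeze every connection trained in the oral phase
#'
#' @param net a `triangle_net` returned by [train_oral()].
#' @return The net with oral-phase weights and biases flagged frozen.
#' @export
freeze_oral <- function(net) {
  net$frozen_conn <- net$frozen_conn | net$oral_trained_conn
  net$frozen_bias <- net$frozen_bias | net$oral_trained_bias
  net
}

#' Reading training phase
#'
#' Trains the mappings from orthography to phonology and semantics. Each trial
#' draws a word frequency-weighted from the whole lexicon, clamps its
#' orthography for twelve steps and scores both targets on steps seven to
#' twelve. Only unfrozen parameters change; with `freeze = TRUE` (default)
#' every oral-phase connection is frozen first, so reading training is
#' identical across oral conditions.
#'
#' @param net a `triangle_net`.
#' @param lexicon a `lexicon`.
#' @param n_trials number of reading trials.
#' @param seed integer seed.
#' @param freeze freeze oral-phase parameters before training.
#' @param log_every record mean training loss every this many trials.
#' @param enc optional precomputed [lexicon_encodings()].
#' @return A list with the trained `net` and the training `log`.
#' @export
train_reading <- function(net, lexicon, n_trials, seed = NULL, freeze = TRUE,
                          log_every = 1000, enc = NULL) {
  if (freeze) net <- freeze_oral(net)
  if (n_trials == 0)
    return(list(net = net, log = data.frame(trial = numeric(0),
                                            mean_loss = numeric(0))))
  cand <- seq_len(nrow(lexicon$items))
  run_training(net, lexicon, "READ", 1, cand, n_trials, seed, log_every, enc)
}
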