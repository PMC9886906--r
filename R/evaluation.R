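#' Summed squared error
#'
#' @param actual,target numeric vectors of equal length.
#' @return `sum((actual - target)^2)`.
#' @export
sse <- function(actual, target) {
  if (length(actual) != length(target))
    stop("actual and target must have equal length")
  sum((actual - target)^2)
}

#' Nearest-phoneme decoding of a phonological output
#'
#' Splits the 200-unit output into 8 slots of 25 features and assigns each
#' slot the nearest inventory phoneme by Euclidean distance. Empty slots are
#' decoded against the explicit all-zero null phoneme. Distance ties are
#' broken by lowest inventory index and flagged.
#'
#' @param output numeric vector of length `8 * 25`.
#' @param inventory phoneme feature matrix (25 x n, null phoneme included).
#' @return A list with `labels` (8 decoded slot labels) and `tie` flag.
#' @export
decode_phonemes <- function(output, inventory) {
  if (ncol(inventory) == 0) stop("empty phoneme inventory")
  if (length(output) != 8 * nrow(inventory))
    stop("output length does not match 8 slots of ", nrow(inventory), " features")
  slots <- matrix(output, nrow = nrow(inventory))
  # squared distances: ||s||^2 - 2 s'I + ||I||^2, columns = inventory entries
  d <- -2 * crossprod(slots, inventory)
  d <- sweep(d, 2, colSums(inventory^2), "+")
  labels <- character(8)
  tie <- FALSE
  for (k in 1:8) {
    j <- which.min(d[k, ])
    if (sum(abs(d[k, ] - d[k, j]) < 1e-12) > 1) tie <- TRUE
    labels[k] <- colnames(inventory)[j]
  }
  list(labels = labels, tie = tie)
}

#' Nearest-word decoding of a semantic output
#'
#' Finds the training-set semantic vector nearest to the output by Euclidean
#' distance. Homophone meanings have disjoint feature sets, so the trial's
#' context-designated meaning is a distinct row. Ties are broken by lowest
#' item index and flagged.
#'
#' @param output numeric semantic output vector.
#' @param sem_matrix semantic encoding matrix (features x items), e.g.
#'   `lexicon_encodings(lex)$S`.
#' @return A list with `item` (the argmin index) and `tie` flag.
#' @export
decode_semantics <- function(output, sem_matrix) {
  if (ncol(sem_matrix) == 0) stop("empty lexicon")
  d <- colSums(sem_matrix^2) - 2 * drop(crossprod(sem_matrix, output))
  j <- which.min(d)
  list(item = j, tie = sum(abs(d - d[j]) < 1e-12) > 1)
}

#' Score a nonword pronunciation
#'
#' A nonword is read correctly if the decoded phoneme slots match any of its
#' acceptable pronunciations (all attested pronunciations of its rime family).
#'
#' @param output phonological output vector.
#' @param acceptable list of acceptable phoneme-label sequences.
#' @param lexicon a `lexicon`.
#' @return Logical flag.
#' @export
score_nonword <- function(output, acceptable, lexicon) {
  if (length(acceptable) == 0) stop("acceptable pronunciation set is empty")
  dec <- decode_phonemes(output, lexicon$inventory)$labels
  for (pron in acceptable) {
    if (identical(dec, phoneme_slots(lexicon, pron))) return(TRUE)
  }
  FALSE
}

read_batch <- function(net, lexicon, O_cols, with_contrib = FALSE) {
  sched <- make_schedule(net, "READ")
  iP <- match("phon", net$layer_names) - 1L
  iS <- match("sem", net$layer_names) - 1L
  labels <- names(net$weights)
  cc <- if (with_contrib)
    as.integer(c(match("h_op->phon", labels), match("h_os2->sem", labels)) - 1L)
  else integer(0)
  res <- cpp_forward_batch(net_to_cpp(net), sched, list(O_cols),
                           c(iP, iS), cc)
  out <- list(phon = res$outputs[[1]], sem = res$outputs[[2]])
  if (with_contrib) {
    out$op_activation <- res$contrib_mean_abs[, 1]
    out$os_activation <- res$contrib_mean_abs[, 2]
  }
  out
}

oral_batch <- function(net, lexicon, task, enc) {
  sched <- make_schedule(net, task)
  out_layer <- if (task == "SP") "phon" else "sem"
  clamp_mats <- if (task == "PS") list(enc$P, enc$C) else list(enc$S)
  res <- cpp_forward_batch(net_to_cpp(net), sched, clamp_mats,
                           match(out_layer, net$layer_names) - 1L, integer(0))
  res$outputs[[1]]
}

#' Evaluate a trained model on words and nonwords
#'
#' Runs every lexical item through the reading trial (and, optionally, the two
#' oral mapping trials), scoring phonological and semantic outputs at the
#' final time step by summed squared error and nearest-neighbour decoding.
#'
#' @param net a trained `triangle_net`.
#' @param lexicon a `lexicon`.
#' @param nonwords optional data frame from [generate_nonwords()] (rows from
#'   both conditions may be bound together).
#' @param oral also evaluate the SP and PS oral tasks.
#' @param condition optional named list (e.g. `ovs`, `ove`, `version`) copied
#'   onto every result row.
#' @param enc optional precomputed [lexicon_encodings()].
#' @return A list with `word_results` (one row per word: `phon_sse`,
#'   `sem_sse`, correctness flags and psycholinguistic covariates),
#'   `accuracy` summaries per task, and `nonword_results`/`nonword_accuracy`
#'   when nonwords are supplied.
#' @export
evaluate_model <- function(net, lexicon, nonwords = NULL, oral = TRUE,
                           condition = NULL, enc = NULL) {
  if (is.null(enc)) enc <- lexicon_encodings(lexicon)
  n <- nrow(lexicon$items)
  rb <- read_batch(net, lexicon, enc$O, with_contrib = TRUE)
  phon_sse <- colSums((rb$phon - enc$P)^2)
  sem_sse <- colSums((rb$sem - enc$S)^2)
  phon_correct <- logical(n)
  sem_correct <- logical(n)
  for (i in seq_len(n)) {
    dec <- decode_phonemes(rb$phon[, i], lexicon$inventory)
    phon_correct[i] <- identical(dec$labels,
                                 phoneme_slots(lexicon, item_phonemes(lexicon, i)))
    # homophone twins share orthography; either shared-form meaning is the
    # written form's meaning, but the designated row must win on sound
    sd <- decode_semantics(rb$sem[, i], enc$S)
    sem_correct[i] <- lexicon$items$letters[sd$item] == lexicon$items$letters[i]
  }
  wr <- data.frame(item = lexicon$items$id,
                   letters = lexicon$items$letters,
                   phon_sse = phon_sse, sem_sse = sem_sse,
                   phon_correct = phon_correct, sem_correct = sem_correct,
                   wf = lexicon$items$wf, log_wf = lexicon$items$log_wf,
                   ons = lexicon$items$ons, rc = lexicon$items$rc,
                   img = lexicon$items$img,
                   is_exception = lexicon$items$is_exception,
                   op_activation = rb$op_activation,
                   os_activation = rb$os_activation,
                   stringsAsFactors = FALSE)
  acc <- list(reading_aloud = mean(phon_correct),
              written_comprehension = mean(sem_correct))
  if (oral) {
    sp_out <- oral_batch(net, lexicon, "SP", enc)
    ps_out <- oral_batch(net, lexicon, "PS", enc)
    sp_correct <- logical(n)
    ps_correct <- logical(n)
    for (i in seq_len(n)) {
      dec <- decode_phonemes(sp_out[, i], lexicon$inventory)
      sp_correct[i] <- identical(dec$labels,
                                 phoneme_slots(lexicon, item_phonemes(lexicon, i)))
      ps_correct[i] <- decode_semantics(ps_out[, i], enc$S)$item == i
    }
    wr$sp_correct <- sp_correct
    wr$ps_correct <- ps_correct
    acc$sp <- mean(sp_correct)
    acc$ps <- mean(ps_correct)
  }
  out <- list(word_results = wr, accuracy = acc)
  if (!is.null(nonwords)) {
    O_nw <- vapply(nonwords$letters,
                   function(w) encode_orthography(lexicon, w),
                   numeric(14 * lexicon$spec$alphabet_size))
    nb <- read_batch(net, lexicon, O_nw)
    ok <- vapply(seq_len(nrow(nonwords)), function(i)
      score_nonword(nb$phon[, i], nonwords$acceptable[[i]], lexicon),
      logical(1))
    target_sse <- vapply(seq_len(nrow(nonwords)), function(i) {
      min(vapply(nonwords$acceptable[[i]], function(pron)
        sse(nb$phon[, i], encode_phonology(lexicon, pron)), numeric(1)))
    }, numeric(1))
    nwr <- data.frame(letters = nonwords$letters,
                      condition = nonwords$condition,
                      correct = ok, phon_sse = target_sse,
                      stringsAsFactors = FALSE)
    out$nonword_results <- nwr
    out$nonword_accuracy <- vapply(split(nwr$correct, nwr$condition), mean,
                                   numeric(1))
  }
  if (!is.null(condition))
    for (nm in names(condition)) {
      out$word_results[[nm]] <- condition[[nm]]
      if (!is.null(out$nonword_results))
        out$nonword_results[[nm]] <- condition[[nm]]
    }
  out
}
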