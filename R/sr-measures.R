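#' Semantic reliance from the consistency effect (EoCSR)
#'
#' Estimates a simulation's semantic reliance the way behavioural work does:
#' items are split into imageability tertiles, and on the low-imageability
#' tertile the phonological error of correctly read words is regressed on rime
#' consistency with log frequency and orthographic neighbourhood size as
#' control variables. The consistency coefficient, sign-reversed, is the SR
#' score: models leaning on the semantic pathway show a larger consistency
#' effect (more error for inconsistent words), hence a larger score.
#'
#' @param results a `word_results` data frame (one simulation) with columns
#'   `phon_sse`, `phon_correct`, `rc`, `log_wf`, `ons`, `img`.
#' @param standardize z-score the dependent variable and predictors before
#'   fitting (the standardized partial coefficient). Use `FALSE` to recover a
#'   planted effect on its raw scale.
#' @param outlier_sd discard items whose error is more than this many standard
#'   deviations from the mean.
#' @return An object of class `sr_estimate`: `estimate`, `se`, `t`, `n_used`.
#' @export
eoc_sr <- function(results, standardize = TRUE, outlier_sd = 2) {
  needed <- c("phon_sse", "phon_correct", "rc", "log_wf", "ons", "img")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0)
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "))
  d <- results[results$phon_correct &
                 complete.cases(results[, c("phon_sse", "rc", "log_wf",
                                            "ons", "img")]), ]
  # imageability tertiles; ties go to the lower tertile
  q <- quantile(d$img, c(1 / 3, 2 / 3))
  d <- d[d$img <= q[1], ]
  keep <- abs(d$phon_sse - mean(d$phon_sse)) <= outlier_sd * sd(d$phon_sse)
  keep[is.na(keep)] <- TRUE
  d <- d[keep, ]
  if (nrow(d) < 10) stop("fewer than 10 usable low-imageability items")
  z <- function(x) if (standardize) (x - mean(x)) / sd(x) else x
  dd <- data.frame(y = z(d$phon_sse), rc = z(d$rc), log_wf = z(d$log_wf),
                   ons = z(d$ons))
  fit <- lm(y ~ rc + log_wf + ons, data = dd)
  cf <- coef(fit)
  if (anyNA(cf)) stop("collinear predictors in the consistency regression")
  se <- sqrt(diag(vcov(fit)))[["rc"]]
  est <- -cf[["rc"]]
  structure(list(estimate = est, se = se, t = est / se, n_used = nrow(d),
                 kind = "EoCSR"), class = "sr_estimate")
}

#' @export
print.sr_estimate <- function(x, ...) {
  cat("<sr_estimate>", x$kind, "=", signif(x$estimate, 4),
      if (!is.null(x$se)) paste0("(SE ", signif(x$se, 3), ", t ",
                                 signif(x$t, 3), ", n ", x$n_used, ")"), "\n")
  invisible(x)
}

#' Mean absolute pathway input into a target layer
#'
#' The activation a pathway delivers is the mean over target-layer units of
#' the absolute net input arriving via the pathway's final connection, taken
#' at the last time step of the trial.
#'
#' @param trace an `activation_trace` from
#'   `forward_pass(..., contributions = TRUE)`.
#' @param pathway one of `"OP"` (via `h_op->phon`), `"OS"` (`h_os2->sem`),
#'   `"SP"` (`h_sp->phon`), `"PS"` (`h_ps->sem`).
#' @return A scalar.
#' @export
pathway_activation <- function(trace, pathway = c("OP", "OS", "SP", "PS")) {
  pathway <- match.arg(pathway)
  conn <- switch(pathway, OP = "h_op->phon", OS = "h_os2->sem",
                 SP = "h_sp->phon", PS = "h_ps->sem")
  if (is.null(trace$contrib))
    stop("trace lacks contributions; run forward_pass(contributions = TRUE)")
  con <- trace$contrib[[conn]]
  if (is.null(con)) stop("unknown pathway connection: ", conn)
  mean(abs(con[, ncol(con)]))
}

#' Semantic reliance from the division of labour (DoLSR)
#'
#' Computes, for each probe word, the mean absolute net input the phonology
#' layer receives from the direct orthography-to-phonology pathway (OP) and
#' the mean absolute net input the semantics layer receives from the
#' orthography-to-semantics pathway (OS), both at the last time step of a
#' reading trial. The scores are averaged across probe items and SR is the
#' ratio OS / (OS + OP).
#'
#' @param net a trained `triangle_net`.
#' @param lexicon a `lexicon`.
#' @param items probe item indices (default: the whole lexicon).
#' @param enc optional precomputed [lexicon_encodings()].
#' @return A scalar in (0, 1) with attributes `os` and `op` (the averaged
#'   pathway activations) and `n_items`.
#' @export
dol_sr <- function(net, lexicon, items = NULL, enc = NULL) {
  if (is.null(enc)) enc <- lexicon_encodings(lexicon)
  if (is.null(items)) items <- seq_len(ncol(enc$O))
  rb <- read_batch(net, lexicon, enc$O[, items, drop = FALSE],
                   with_contrib = TRUE)
  os <- mean(rb$os_activation)
  op <- mean(rb$op_activation)
  if (os + op == 0) stop("both pathway activations are zero")
  structure(os / (os + op), os = os, op = op, n_items = length(items))
}
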