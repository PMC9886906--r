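#' Z-score a numeric vector
#' @param x numeric vector.
#' @return `(x - mean(x)) / sd(x)`; a constant vector maps to all zeros.
#' @export
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Preprocess a results table for analysis
#'
#' Applies the standard cleaning pipeline: drop misread items, drop rows with
#' any missing analysis variable, drop dependent-variable outliers more than
#' `outlier_sd` standard deviations from the mean of the retained rows, and
#' z-score all analysis variables. A table that has already been preprocessed
#' is returned unchanged (the pipeline is applied once).
#'
#' @param table data frame of word-level or simulation-level records.
#' @param dv name of the dependent-variable column.
#' @param covariates names of predictor columns that must be non-missing and
#'   are z-scored along with the dependent variable.
#' @param correct_col optional logical column; rows with `FALSE` are dropped.
#' @param outlier_sd outlier cut in standard deviations.
#' @return The cleaned, scaled data frame, with attributes `n_removed` and
#'   `preprocessed`.
#' @export
preprocess <- function(table, dv, covariates = character(0),
                       correct_col = NULL, outlier_sd = 2) {
  if (isTRUE(attr(table, "preprocessed"))) return(table)
  if (!dv %in% names(table)) stop("dependent variable '", dv, "' not found")
  n0 <- nrow(table)
  if (!is.null(correct_col)) table <- table[table[[correct_col]], , drop = FALSE]
  cols <- c(dv, covariates)
  table <- table[complete.cases(table[, cols, drop = FALSE]), , drop = FALSE]
  y <- table[[dv]]
  table <- table[abs(y - mean(y)) <= outlier_sd * sd(y), , drop = FALSE]
  if (nrow(table) == 0) stop("preprocessing removed every row")
  for (cl in cols) table[[cl]] <- zscore(table[[cl]])
  attr(table, "n_removed") <- n0 - nrow(table)
  attr(table, "preprocessed") <- TRUE
  table
}

#' Fit a linear mixed-effects model with crossed random intercepts
#'
#' Fits `dv ~ fixed + (1 | item) + (1 | version)` via lme4. Coefficients on
#' z-scored variables are standardized; an effect is flagged significant when
#' `|t| > 1.96` and 95% confidence intervals are Wald (`estimate +/- 1.96 SE`).
#'
#' @param table preprocessed data frame.
#' @param fixed character vector of fixed-effect terms (may include `a:b`).
#' @param dv dependent-variable column name.
#' @param random character vector of random-intercept grouping columns.
#' @param reml fit by REML (`TRUE`) or ML (`FALSE`; required for
#'   likelihood-ratio comparison).
#' @return An object of class `lmm_fit` with the `coefficients` table
#'   (estimate, se, t, ci_lower, ci_upper, significant), the fitted `model`,
#'   and a `singular` flag.
#' @export
fit_lmm <- function(table, fixed, dv, random = c("item", "version"),
                    reml = TRUE) {
  if (!all(random %in% names(table)))
    stop("random-effect column(s) missing: ",
         paste(setdiff(random, names(table)), collapse = ", "))
  fml <- as.formula(paste(dv, "~", paste(fixed, collapse = " + "), "+",
                          paste(sprintf("(1 | %s)", random), collapse = " + ")))
  mm <- model.matrix(as.formula(paste(dv, "~", paste(fixed, collapse = " + "))),
                     data = table)
  if (qr(mm)$rank < ncol(mm))
    stop("rank-deficient fixed-effect design (collinear or duplicated predictors)")
  model <- lme4::lmer(fml, data = table, REML = reml)
  cf <- as.data.frame(summary(model)$coefficients)
  names(cf) <- c("estimate", "se", "t")
  cf$ci_lower <- cf$estimate - 1.96 * cf$se
  cf$ci_upper <- cf$estimate + 1.96 * cf$se
  cf$significant <- abs(cf$t) > 1.96
  structure(list(coefficients = cf, model = model, reml = reml,
                 formula = fml, singular = lme4::isSingular(model)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit>", deparse(x$formula), "\n")
  if (x$singular) cat("  (singular random-effects fit)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Both models are refit by maximum likelihood if necessary and compared by
#' the likelihood-ratio chi-square with degrees of freedom equal to the
#' parameter difference.
#'
#' @param base,extended `lmm_fit` objects fitted to the same data, with the
#'   base model's fixed effects a subset of the extended model's.
#' @return A list with `chisq`, `df` and `p`.
#' @export
compare_lmm <- function(base, extended) {
  tb <- attr(stats::terms(stats::formula(base$model, fixed.only = TRUE)),
             "term.labels")
  te <- attr(stats::terms(stats::formula(extended$model, fixed.only = TRUE)),
             "term.labels")
  if (!all(tb %in% te)) stop("models are not nested")
  if (stats::nobs(base$model) != stats::nobs(extended$model))
    stop("models were fitted to different data")
  m0 <- if (base$reml) lme4::refitML(base$model) else base$model
  m1 <- if (extended$reml) lme4::refitML(extended$model) else extended$model
  ll0 <- as.numeric(stats::logLik(m0))
  ll1 <- as.numeric(stats::logLik(m1))
  df <- attr(stats::logLik(m1), "df") - attr(stats::logLik(m0), "df")
  chisq <- max(2 * (ll1 - ll0), 0)
  list(chisq = chisq, df = df,
       p = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_)
}

#' Interaction regression of a semantic-reliance score on OVE and OVS
#'
#' Ordinary least squares with oral vocabulary exposure, oral vocabulary size
#' and their interaction as predictors of a per-simulation SR score. Main
#' effects and the dependent variable are z-scored; the interaction is the
#' product of the two z-scored main effects and is not re-scaled (re-scaling
#' a product distorts the interaction).
#'
#' @param table one row per simulation (condition x version).
#' @param dv SR score column name.
#' @param x1,x2 predictor column names (default `ove`, `ovs`).
#' @return A list with the `coefficients` table, `r2`, `adj_r2` and `model`.
#' @export
ols_interaction <- function(table, dv, x1 = "ove", x2 = "ovs") {
  if (nrow(table) < 10) stop("fewer than 10 simulations")
  d <- data.frame(y = zscore(table[[dv]]),
                  a = zscore(table[[x1]]), b = zscore(table[[x2]]))
  d$ab <- d$a * d$b
  fit <- lm(y ~ a + b + ab, data = d)
  sm <- summary(fit)
  cf <- as.data.frame(sm$coefficients)
  names(cf) <- c("estimate", "se", "t", "p")
  rownames(cf) <- c("(Intercept)", x1, x2, paste0(x1, ":", x2))
  r2 <- if (sd(d$y) == 0) 0 else sm$r.squared
  adj <- if (sd(d$y) == 0) 0 else sm$adj.r.squared
  list(coefficients = cf, r2 = r2, adj_r2 = adj, model = fit)
}

#' Structural regression of reading performance on oral vocabulary via SR
#'
#' Maximum-likelihood path model in which oral vocabulary exposure, size and
#' their interaction predict the semantic-reliance score, which in turn
#' predicts reading-aloud error, with direct OVE/OVS/interaction paths to the
#' error also estimated. The single-indicator latent SR is identified by
#' fixing its loading to 1 and its indicator residual to 0, which is
#' equivalent to treating the SR score as observed; the model is then
#' just-identified and reports CFI = 1, TLI = 1, RMSEA = 0.
#'
#' @param table one row per simulation with `ove`, `ovs`, the SR column and a
#'   reading-error column.
#' @param sr_col SR score column name (`"eoc_sr"` or `"dol_sr"`).
#' @param dv reading-performance column name (mean phonological SSE).
#' @return A `path_fit` (see [fit_path_model()]).
#' @export
structural_model <- function(table, sr_col, dv = "mean_phon_sse") {
  d <- data.frame(ove = zscore(table$ove), ovs = zscore(table$ovs),
                  sr = zscore(table[[sr_col]]), sse = zscore(table[[dv]]))
  d$ove_ovs <- d$ove * d$ovs
  fit_path_model(d, list(sr ~ ove + ovs + ove_ovs,
                         sse ~ sr + ove + ovs + ove_ovs))
}

#' Factorial analysis of SR, imageability and consistency on reading error
#'
#' Mixed model for the three-way interaction between a per-simulation SR
#' score, item imageability and item consistency in predicting phonological
#' error, on the factorial item set formed by the low and high imageability
#' tertiles crossed with regular and exception words. All predictors are
#' z-scored; random intercepts for item and model version.
#'
#' @param word_results pooled word-level results across simulations, with
#'   `ovs`, `ove`, `version` identifying the simulation.
#' @param sr_table per-simulation SR scores (`ovs`, `ove`, `version`,
#'   SR column).
#' @param sr_col which SR column to use.
#' @return A list with the `fit` (`lmm_fit`), the factorial `cell_means`
#'   (model-free averages per imageability x consistency cell), and the
#'   analysed table.
#' @export
factorial_sr_analysis <- function(word_results, sr_table, sr_col = "eoc_sr") {
  d <- merge(word_results, sr_table[, c("ovs", "ove", "version", sr_col)],
             by = c("ovs", "ove", "version"))
  q <- quantile(d$img, c(1 / 3, 2 / 3))
  d$img_class <- ifelse(d$img <= q[1], "low",
                        ifelse(d$img > q[2], "high", "mid"))
  d <- d[d$img_class != "mid", , drop = FALSE]
  d$rc_class <- ifelse(d$is_exception, "inconsistent", "consistent")
  if (any(table(d$img_class, d$rc_class) == 0))
    stop("empty factorial cell (imageability x consistency)")
  d <- d[d$phon_correct, , drop = FALSE]
  cell_means <- aggregate(phon_sse ~ img_class + rc_class, data = d, FUN = mean)
  d$img_z <- zscore(ifelse(d$img_class == "high", 1, 0))
  d$rc_z <- zscore(ifelse(d$rc_class == "consistent", 1, 0))
  d$sr_z <- zscore(d[[sr_col]])
  d$sse_z <- zscore(d$phon_sse)
  fit <- fit_lmm(d, c("img_z * rc_z * sr_z"), "sse_z")
  list(fit = fit, cell_means = cell_means, data = d)
}
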