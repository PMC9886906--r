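#' Specify a simulation grid
#'
#' A grid crosses oral vocabulary sizes, oral exposure counts and model
#' versions (initialisation seeds). Reading training is identical across
#' cells, isolating the effect of oral vocabulary knowledge.
#'
#' @param ovs vector of oral vocabulary sizes.
#' @param ove vector of oral exposure trial counts.
#' @param versions number of model versions (different initial weights).
#' @param reading_trials reading trials per cell (same in every cell).
#' @param nonwords_per_condition nonwords generated per consistency condition.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(ovs = c(100, 200, 300), ove = c(20000, 80000),
                      versions = 2, reading_trials = 100000,
                      nonwords_per_condition = 80) {
  structure(list(ovs = ovs, ove = ove, versions = versions,
                 reading_trials = reading_trials,
                 nonwords_per_condition = nonwords_per_condition),
            class = "grid_spec")
}

# independent per-(cell, stage) seeds derived from the master seed; adding
# cells never perturbs existing ones
cell_seed <- function(base_seed, ovs, ove, version, stage) {
  stage_code <- match(stage, c("init", "oral", "read", "nonword"))
  as.integer((as.numeric(base_seed) * 1000003 + ovs * 7919 +
                ove * 13 + version * 104729 + stage_code * 271) %%
               2147483647)
}

#' Run the full oral-condition x exposure x version grid
#'
#' For each cell: initialise a network, run oral training with the cell's
#' vocabulary size and exposure, freeze the oral-phase weights, run the
#' (identical) reading phase, evaluate on words and nonwords, and compute the
#' two semantic-reliance scores. Cells are computed independently from named
#' seed substreams of `base_seed`.
#'
#' @param lexicon a `lexicon`.
#' @param grid a [grid_spec()].
#' @param config a [triangle_config()]; defaults to `triangle_config(lexicon)`.
#' @param base_seed master integer seed.
#' @param out_dir optional directory for per-cell checkpoint files; completed
#'   cells found there are loaded instead of recomputed.
#' @param verbose print per-cell progress.
#' @return An object of class `grid_results`: `word_results` (pooled, tagged
#'   with `ovs`, `ove`, `version`), `nonword_results`, `sr_table` (one row per
#'   simulation: SR scores, accuracies, mean correct-word error), and a
#'   `manifest`.
#' @export
run_grid <- function(lexicon, grid = grid_spec(), config = NULL,
                     base_seed = 1, out_dir = NULL, verbose = FALSE) {
  if (is.null(config)) config <- triangle_config(lexicon)
  if (max(grid$ovs) > nrow(lexicon$items))
    stop("largest ovs exceeds lexicon size")
  enc <- lexicon_encodings(lexicon)
  nw <- rbind(generate_nonwords(lexicon, grid$nonwords_per_condition,
                                "consistent",
                                seed = cell_seed(base_seed, 0, 0, 0, "nonword")),
              generate_nonwords(lexicon, grid$nonwords_per_condition,
                                "inconsistent",
                                seed = cell_seed(base_seed, 0, 0, 1, "nonword")))
  cells <- expand.grid(version = seq_len(grid$versions), ove = grid$ove,
                       ovs = grid$ovs)
  word_results <- list()
  nonword_results <- list()
  sr_rows <- list()
  timings <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cl <- cells[k, ]
    tag <- sprintf("ovs%d_ove%d_v%d", cl$ovs, cl$ove, cl$version)
    ck <- if (!is.null(out_dir)) file.path(out_dir, paste0("cell_", tag)) else NULL
    if (!is.null(ck) && file.exists(paste0(ck, "_sr.json"))) {
      word_results[[k]] <- read.delim(paste0(ck, "_words.tsv"))
      nonword_results[[k]] <- read.delim(paste0(ck, "_nonwords.tsv"))
      sr_rows[[k]] <- as.data.frame(
        jsonlite::read_json(paste0(ck, "_sr.json"), simplifyVector = TRUE))
      next
    }
    t0 <- proc.time()[3]
    net <- init_network(config, cell_seed(base_seed, cl$ovs, cl$ove,
                                          cl$version, "init"))
    net <- train_oral(net, lexicon, cl$ovs, cl$ove,
                      seed = cell_seed(base_seed, cl$ovs, cl$ove,
                                       cl$version, "oral"), enc = enc)$net
    net <- train_reading(net, lexicon, grid$reading_trials,
                         seed = cell_seed(base_seed, cl$ovs, cl$ove,
                                          cl$version, "read"), enc = enc)$net
    ev <- evaluate_model(net, lexicon, nonwords = nw,
                         condition = list(ovs = cl$ovs, ove = cl$ove,
                                          version = cl$version), enc = enc)
    eoc <- tryCatch(eoc_sr(ev$word_results), error = function(e) NULL)
    dol <- dol_sr(net, lexicon, enc = enc)
    ok <- ev$word_results$phon_correct
    sr_rows[[k]] <- data.frame(
      ovs = cl$ovs, ove = cl$ove, version = cl$version,
      eoc_sr = if (is.null(eoc)) NA_real_ else eoc$estimate,
      eoc_sr_t = if (is.null(eoc)) NA_real_ else eoc$t,
      dol_sr = as.numeric(dol),
      os_activation = attr(dol, "os"), op_activation = attr(dol, "op"),
      acc_reading_aloud = ev$accuracy$reading_aloud,
      acc_written_comprehension = ev$accuracy$written_comprehension,
      acc_sp = ev$accuracy$sp, acc_ps = ev$accuracy$ps,
      nonword_acc_consistent = ev$nonword_accuracy[["consistent"]],
      nonword_acc_inconsistent = ev$nonword_accuracy[["inconsistent"]],
      mean_phon_sse = mean(ev$word_results$phon_sse[ok]))
    word_results[[k]] <- ev$word_results
    nonword_results[[k]] <- ev$nonword_results
    timings[k] <- proc.time()[3] - t0
    if (!is.null(ck)) {
      wr <- ev$word_results
      write.table(wr, paste0(ck, "_words.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.table(ev$nonword_results, paste0(ck, "_nonwords.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      jsonlite::write_json(sr_rows[[k]], paste0(ck, "_sr.json"),
                           dataframe = "columns", digits = NA)
    }
    if (verbose)
      message(sprintf("cell %s: OP acc %.3f, EoCSR %.4f, DoLSR %.4f (%.1fs)",
                      tag, ev$accuracy$reading_aloud,
                      sr_rows[[k]]$eoc_sr, sr_rows[[k]]$dol_sr, timings[k]))
  }
  manifest <- list(base_seed = base_seed, grid = unclass(grid),
                   layer_sizes = as.list(config$layer_sizes),
                   learning_rate = config$learning_rate,
                   loss = config$loss,
                   n_words = nrow(lexicon$items),
                   language_seed = lexicon$spec$seed,
                   package_version = as.character(utils::packageVersion("triread")),
                   timings_s = timings)
  structure(list(word_results = do.call(rbind, word_results),
                 nonword_results = do.call(rbind, nonword_results),
                 sr_table = do.call(rbind, sr_rows),
                 manifest = manifest),
            class = "grid_results")
}

#' @export
print.grid_results <- function(x, ...) {
  cat("<grid_results>", nrow(x$sr_table), "simulations;",
      nrow(x$word_results), "word observations\n")
  print(x$sr_table[, c("ovs", "ove", "version", "eoc_sr", "dol_sr",
                       "acc_reading_aloud")], digits = 4)
  invisible(x)
}

#' Run the full inferential battery on grid results
#'
#' Reproduces the analysis pipeline on simulation output: the pooled
#' mixed-model of phonological error with psycholinguistic predictors, its
#' extension with oral vocabulary exposure and size (with likelihood-ratio
#' comparison), SR score distributions and their correlation, the OVE x OVS
#' interaction regressions, the structural path models, and the factorial
#' SR x imageability x consistency analysis.
#'
#' @param results a `grid_results`.
#' @param reml fit the pooled mixed models by REML (`FALSE` uses ML
#'   throughout; the likelihood-ratio test always refits by ML).
#' @return An object of class `triread_report`.
#' @export
analyze_grid <- function(results, reml = TRUE) {
  wr <- results$word_results
  covs <- c("log_wf", "ons", "rc", "img", "ove", "ovs")
  pre <- preprocess(wr, dv = "phon_sse", covariates = covs,
                    correct_col = "phon_correct")
  base <- fit_lmm(pre, c("log_wf", "ons", "rc", "img", "log_wf:rc"),
                  "phon_sse", reml = reml)
  ext <- fit_lmm(pre, c("log_wf", "ons", "rc", "img", "log_wf:rc",
                        "ove", "ovs"), "phon_sse", reml = reml)
  lrt <- compare_lmm(base, ext)
  st <- results$sr_table
  sr_ok <- !is.na(st$eoc_sr)
  sr_cor <- if (sum(sr_ok) >= 3)
    cor.test(st$eoc_sr[sr_ok], st$dol_sr[sr_ok]) else NULL
  sr_summary <- data.frame(
    measure = c("eoc_sr", "dol_sr"),
    min = c(min(st$eoc_sr, na.rm = TRUE), min(st$dol_sr)),
    max = c(max(st$eoc_sr, na.rm = TRUE), max(st$dol_sr)),
    mean = c(mean(st$eoc_sr, na.rm = TRUE), mean(st$dol_sr)),
    sd = c(sd(st$eoc_sr, na.rm = TRUE), sd(st$dol_sr)))
  interaction_fits <- list(eoc_sr = ols_interaction(st[sr_ok, ], "eoc_sr"),
                           dol_sr = ols_interaction(st, "dol_sr"))
  structural_fits <- list(eoc_sr = structural_model(st[sr_ok, ], "eoc_sr"),
                          dol_sr = structural_model(st, "dol_sr"))
  factorial <- list(
    eoc_sr = factorial_sr_analysis(wr, st[sr_ok, ], "eoc_sr"),
    dol_sr = factorial_sr_analysis(wr, st, "dol_sr"))
  structure(list(lmm_baseline = base, lmm_extended = ext, lrt = lrt,
                 sr_summary = sr_summary, sr_correlation = sr_cor,
                 interaction_fits = interaction_fits,
                 structural_fits = structural_fits,
                 factorial = factorial,
                 n_observations = nrow(pre)),
            class = "triread_report")
}

#' @export
print.triread_report <- function(x, ...) {
  cat("<triread_report>\n\nPooled LMM of phonological SSE (extended model):\n")
  print(round(x$lmm_extended$coefficients, 4))
  cat(sprintf("\nLR test for OVE + OVS: chisq(%d) = %.2f, p = %.3g\n",
              x$lrt$df, x$lrt$chisq, x$lrt$p))
  cat("\nSemantic-reliance scores:\n")
  print(x$sr_summary, digits = 4)
  if (!is.null(x$sr_correlation))
    cat(sprintf("\nEoCSR-DoLSR correlation: r = %.4f, t(%d) = %.2f\n",
                x$sr_correlation$estimate, x$sr_correlation$parameter,
                x$sr_correlation$statistic))
  for (m in names(x$interaction_fits)) {
    f <- x$interaction_fits[[m]]
    cat(sprintf("\nOVE x OVS regression on %s: R^2 = %.3f (adj %.3f)\n",
                m, f$r2, f$adj_r2))
    print(round(f$coefficients, 4))
  }
  invisible(x)
}

#' Write a report's tables to plain-text files
#'
#' @param report a `triread_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(cbind(term = rownames(df), df),
                                    file.path(dir, f), sep = "\t",
                                    row.names = FALSE, quote = FALSE)
  wt(report$lmm_baseline$coefficients, "lmm_baseline.tsv")
  wt(report$lmm_extended$coefficients, "lmm_extended.tsv")
  write.table(report$sr_summary, file.path(dir, "sr_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  for (m in names(report$interaction_fits))
    wt(report$interaction_fits[[m]]$coefficients,
       paste0("interaction_", m, ".tsv"))
  for (m in names(report$structural_fits)) {
    f <- report$structural_fits[[m]]
    write.table(f$paths, file.path(dir, paste0("structural_", m, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(lrt = report$lrt,
         fit_indices = lapply(report$structural_fits, function(f)
           list(chisq = f$chisq, df = f$df, cfi = f$cfi, tli = f$tli,
                rmsea = f$rmsea)),
         n_observations = report$n_observations),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
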