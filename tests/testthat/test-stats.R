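test_that("preprocessing trims, scales and is applied exactly once", {
  set.seed(1)
  d <- data.frame(y = rnorm(1e5), x = rnorm(1e5))
  out <- preprocess(d, dv = "y", covariates = "x")
  frac <- attr(out, "n_removed") / nrow(d)
  p <- 2 * pnorm(-2)                    # expected removal for a Gaussian
  se <- sqrt(p * (1 - p) / nrow(d))
  expect_lt(abs(frac - p), 3 * se)
  expect_lt(abs(mean(out$y)), 1e-10)
  expect_lt(abs(sd(out$y) - 1), 1e-10)
  expect_lt(abs(mean(out$x)), 1e-10)
  expect_lt(abs(sd(out$x) - 1), 1e-10)
  # idempotent: a second pass changes nothing
  out2 <- preprocess(out, dv = "y", covariates = "x")
  expect_identical(out, out2)
  # with no outliers, only misread/missing rows are dropped
  d2 <- data.frame(y = seq(-1, 1, length.out = 100), ok = rep(c(TRUE, FALSE), 50))
  out3 <- preprocess(d2, dv = "y", correct_col = "ok")
  expect_equal(nrow(out3), 50)
})

test_that("the mixed model recovers planted fixed effects", {
  gen <- function(seed, b1 = 0.4, b2 = -0.3) {
    set.seed(seed)
    n_item <- 60; n_ver <- 5
    d <- expand.grid(item = seq_len(n_item), version = seq_len(n_ver))
    x1 <- rnorm(n_item)[d$item]
    d$x1 <- x1
    d$x2 <- rnorm(nrow(d))
    u_i <- rnorm(n_item, 0, 0.3)[d$item]
    u_v <- rnorm(n_ver, 0, 0.2)[d$version]
    d$y <- b1 * d$x1 + b2 * d$x2 + u_i + u_v + rnorm(nrow(d), 0, 0.5)
    d
  }
  d <- gen(1)
  fit <- fit_lmm(d, c("x1", "x2"), "y")
  cf <- fit$coefficients
  expect_lt(abs(cf["x1", "estimate"] - 0.4), 2 * cf["x1", "se"])
  expect_lt(abs(cf["x2", "estimate"] + 0.3), 2 * cf["x2", "se"])
  expect_true(cf["x1", "significant"])
  expect_equal(cf["x1", "ci_upper"] - cf["x1", "estimate"],
               1.96 * cf["x1", "se"])
  # duplicated predictor: flagged as rank deficiency, not silently dropped
  d$x3 <- d$x1
  expect_error(fit_lmm(d, c("x1", "x3"), "y"), "rank-deficient")
})

test_that("nested-model comparison gives a chi-square of the right size", {
  set.seed(2)
  d <- expand.grid(item = 1:40, version = 1:5)
  d$x <- rnorm(nrow(d))
  d$z <- rnorm(nrow(d))
  d$y <- 0.5 * d$x + rnorm(40, 0, 0.3)[d$item] + rnorm(nrow(d))
  base <- fit_lmm(d, "x", "y", reml = FALSE)
  ext <- fit_lmm(d, c("x", "z"), "y", reml = FALSE)
  cmp <- compare_lmm(base, ext)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$chisq, 0)
  # identical models differ by nothing
  cmp0 <- compare_lmm(base, base)
  expect_equal(cmp0$chisq, 0, tolerance = 1e-8)
  expect_equal(cmp0$df, 0)
  # two added fixed effects give two degrees of freedom
  ext2 <- fit_lmm(d, c("x", "z", "x:z"), "y", reml = FALSE)
  expect_equal(compare_lmm(base, ext2)$df, 2)
  # row order is irrelevant
  perm <- sample(nrow(d))
  base_p <- fit_lmm(d[perm, ], "x", "y", reml = FALSE)
  ext_p <- fit_lmm(d[perm, ], c("x", "z"), "y", reml = FALSE)
  expect_equal(compare_lmm(base_p, ext_p)$chisq, cmp$chisq, tolerance = 1e-6)
  expect_error(compare_lmm(ext, fit_lmm(d, "z", "y", reml = FALSE)),
               "not nested")
})

test_that("the interaction regression recovers planted coefficients exactly", {
  set.seed(3)
  d <- expand.grid(ove = c(1, 2, 4, 8), ovs = 1:6, version = 1:3)
  a <- zscore(d$ove); b <- zscore(d$ovs)
  d$sr <- -0.5 * a + 0.3 * b - 0.2 * a * b
  fit <- suppressWarnings(ols_interaction(d, "sr"))
  beta <- fit$coefficients$estimate
  truth <- c(0, -0.5, 0.3, -0.2) / sd(d$sr)
  expect_equal(beta, truth, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # constant score: nothing to explain
  d$flat <- 1
  expect_equal(ols_interaction(d, "flat")$r2, 0)
  expect_error(ols_interaction(d[1:5, ], "sr"), "fewer than 10")
})

test_that("the path-model fitter matches equation-by-equation OLS", {
  set.seed(4)
  n <- 300
  d <- data.frame(ove = rnorm(n), ovs = rnorm(n))
  d$ove_ovs <- d$ove * d$ovs
  d$sr <- 0.5 * d$ove - 0.4 * d$ovs + rnorm(n, 0, 0.6)
  d$sse <- 0.3 * d$sr + 0.2 * d$ove + rnorm(n, 0, 0.5)
  fit <- fit_path_model(d, list(sr ~ ove + ovs + ove_ovs,
                                sse ~ sr + ove + ovs + ove_ovs))
  expect_true(fit$converged)
  ols1 <- coef(lm(sr ~ ove + ovs + ove_ovs, d))[-1]
  ols2 <- coef(lm(sse ~ sr + ove + ovs + ove_ovs, d))[-1]
  p <- fit$paths
  expect_equal(p$estimate[p$to == "sr"], unname(ols1), tolerance = 1e-4)
  expect_equal(p$estimate[p$to == "sse"], unname(ols2), tolerance = 1e-4)
  # just-identified: perfect fit indices by construction
  expect_equal(fit$df, 0)
  expect_equal(fit$chisq, 0, tolerance = 1e-6)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$tli, 1)
  expect_equal(fit$rmsea, 0)
  expect_true(all(fit$close_fit))
})

test_that("the structural model recovers planted paths within two SE", {
  set.seed(5)
  grid <- expand.grid(ove = c(1, 2, 4, 8, 16), ovs = 1:6, version = 1:8)
  a <- zscore(grid$ove); b <- zscore(grid$ovs)
  grid$eoc <- -0.4 * a + 0.3 * b - 0.25 * a * b + rnorm(nrow(grid), 0, 0.5)
  grid$mean_phon_sse <- 0.3 * zscore(grid$eoc) - 0.2 * a +
    rnorm(nrow(grid), 0, 0.4)
  fit <- structural_model(grid, "eoc")
  p <- fit$paths
  pick <- function(to, from) p[p$to == to & p$from == from, ]
  r <- pick("sr", "ove")
  expect_lt(abs(r$estimate - (-0.4 / sd(grid$eoc))), 2 * r$se)
  r2 <- pick("sse", "sr")
  expect_gt(r2$estimate, 0)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
})

test_that("the factorial analysis recovers a planted three-way interaction", {
  set.seed(6)
  n_item <- 80; sims <- expand.grid(ovs = c(1, 2), ove = c(1, 2), version = 1:3)
  sims$eoc_sr <- rnorm(nrow(sims))
  items <- data.frame(item = seq_len(n_item),
                      img = sample(2:8, n_item, replace = TRUE),
                      is_exception = rep(c(FALSE, TRUE), n_item / 2))
  d <- merge(expand.grid(item = items$item, sim = seq_len(nrow(sims))), items)
  d <- cbind(d, sims[d$sim, c("ovs", "ove", "version")])
  sr_row <- sims$eoc_sr[d$sim]
  q <- quantile(items$img, c(1 / 3, 2 / 3))
  img_f <- ifelse(d$img <= q[1], 0, ifelse(d$img > q[2], 1, NA))
  rc_f <- ifelse(d$is_exception, 0, 1)
  d$phon_sse <- 1 + 0.3 * ifelse(is.na(img_f), 0.5, img_f) - 0.2 * rc_f +
    0.25 * ifelse(is.na(img_f), 0.5, img_f) * rc_f * sr_row +
    rnorm(nrow(d), 0, 0.3)
  d$phon_correct <- TRUE
  res <- factorial_sr_analysis(d, sims, "eoc_sr")
  cf <- res$fit$coefficients
  expect_true("img_z:rc_z:sr_z" %in% rownames(cf))
  expect_true(cf["img_z:rc_z:sr_z", "significant"])
  # model-free cell means equal direct averages
  low_cons <- d[d$img <= q[1] & !d$is_exception & d$phon_correct, "phon_sse"]
  cm <- res$cell_means
  expect_equal(cm$phon_sse[cm$img_class == "low" & cm$rc_class == "consistent"],
               mean(low_cons))
})
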