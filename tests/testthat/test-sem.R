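# DWLS engine: degrees-of-freedom bookkeeping, fit indices, difference
# tests, standardisation, and estimator consistency.

one_factor_spec <- function(items, fix_var = TRUE) {
  vars <- tibble::tibble(var = items, n_cat = 2L)
  pt <- dplyr::bind_rows(lapply(items, function(v) dplyr::bind_rows(
    genefactor:::pt_row("lambda", v, "F1", TRUE, 0.8, paste0("l_", v)),
    genefactor:::pt_row("tau", v, 1, TRUE, NA, paste0("t_", v)),
    genefactor:::pt_row("theta_d", v, v, FALSE, 1))))
  pt <- dplyr::bind_rows(pt, genefactor:::pt_row("psi", "F1", "F1",
                                                 !fix_var, 1,
                                                 if (fix_var) "" else "vF"))
  sem_spec(vars, "F1", pt)
}

sim_binary_factor <- function(n, lam_std, tau, seed) {
  set.seed(seed)
  f <- rnorm(n)
  dat <- as.data.frame(lapply(seq_along(lam_std), function(j) {
    as.integer(lam_std[j] * f + sqrt(1 - lam_std[j]^2) * rnorm(n) > tau[j])
  }))
  names(dat) <- paste0("v", seq_along(lam_std))
  dat
}

test_that("df bookkeeping equals the brute-force statistic/parameter count", {
  spec <- one_factor_spec(paste0("v", 1:6))
  # 6 thresholds + 15 correlations - 12 free
  expect_equal(spec$n_stats, 21)
  expect_equal(spec$df, 21 - 12)
  chk <- check_identification(spec)
  expect_equal(chk$df, spec$df)

  over <- one_factor_spec(paste0("v", 1:2))
  expect_error(suppressWarnings(fit_dwls(over, NULL)), "identification")
})

test_that("a saturated model reproduces the statistics with chi2 ~ 0", {
  dat <- sim_binary_factor(800, c(0.6, 0.7), c(0.2, -0.3), seed = 5)
  vars <- tibble::tibble(var = c("v1", "v2"), n_cat = 2L)
  pt <- dplyr::bind_rows(
    genefactor:::pt_row("lambda", "v1", "F1", FALSE, 1),
    genefactor:::pt_row("theta_d", "v1", "v1", FALSE, 0),
    genefactor:::pt_row("lambda", "v2", "F2", FALSE, 1),
    genefactor:::pt_row("theta_d", "v2", "v2", FALSE, 0),
    genefactor:::pt_row("tau", "v1", 1, TRUE, NA, "t1"),
    genefactor:::pt_row("tau", "v2", 1, TRUE, NA, "t2"),
    genefactor:::pt_row("psi", "F1", "F1", FALSE, 1),
    genefactor:::pt_row("psi", "F2", "F2", FALSE, 1),
    genefactor:::pt_row("psi", "F1", "F2", TRUE, 0, "r12"))
  spec <- sem_spec(vars, c("F1", "F2"), pt)
  expect_equal(spec$df, 0)
  fit <- suppressWarnings(fit_dwls(spec, polychoric_matrix(dat), n = 800))
  expect_true(fit$converged)
  expect_equal(fit$chi2, 0)
  expect_lt(fit$chi2_raw, 1e-10)
})

test_that("fit index formulas reproduce printed model summaries", {
  # model chi2/df/n rows with published 3-dp RMSEA values
  rows <- list(
    list(chi2 = 808.683, df = 303, n = 1160, rmsea = 0.038),
    list(chi2 = 878.578, df = 311, n = 1160, rmsea = 0.040),
    list(chi2 = 814.835, df = 313, n = 1160, rmsea = 0.037),
    list(chi2 = 971.144, df = 326, n = 1160, rmsea = 0.041),
    list(chi2 = 1054.311, df = 303, n = 1180, rmsea = 0.046),
    list(chi2 = 1116.822, df = 311, n = 1180, rmsea = 0.047),
    list(chi2 = 1041.822, df = 313, n = 1180, rmsea = 0.044),
    list(chi2 = 1245.856, df = 326, n = 1180, rmsea = 0.049))
  for (r in rows) {
    expect_equal(round(fit_indices(r$chi2, r$df, r$n)$rmsea, 3), r$rmsea)
  }
  # chi2 = df: perfect fit
  fi <- fit_indices(100, 100, 500, baseline_chi2 = 900, baseline_df = 120)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
  expect_error(fit_indices(10, 0, 100), "df = 0")
})

test_that("chi-square difference test: identity, null moments and power", {
  items <- paste0("v", 1:6)
  lam <- c(0.42, 0.43, 0.63, 0.69, 0.29, 0.24)
  tau <- rep(0.4, 6)

  # identical specs -> stat 0, p 1
  dat <- sim_binary_factor(700, lam, tau, seed = 8)
  pm <- polychoric_matrix(dat)
  spec <- one_factor_spec(items)
  f1 <- fit_dwls(spec, pm, n = 700)
  d0 <- chi2_diff_test(f1, f1)
  expect_equal(d0$stat, 0)
  expect_equal(d0$p, 1)

  # null calibration: equality constraints that hold in truth
  eq_spec <- local({
    vars <- tibble::tibble(var = items, n_cat = 2L)
    pt <- dplyr::bind_rows(lapply(seq_along(items), function(j) {
      v <- items[j]
      dplyr::bind_rows(
        genefactor:::pt_row("lambda", v, "F1", TRUE, 0.8,
                            if (j <= 2) "l_eq" else paste0("l_", v)),
        genefactor:::pt_row("tau", v, 1, TRUE, NA, paste0("t_", v)),
        genefactor:::pt_row("theta_d", v, v, FALSE, 1))
    }))
    pt <- dplyr::bind_rows(pt, genefactor:::pt_row("psi", "F1", "F1",
                                                   FALSE, 1))
    sem_spec(vars, "F1", pt)
  })
  lam_eq <- lam; lam_eq[2] <- lam_eq[1]
  set.seed(91)
  stats_null <- replicate(150, {
    dat <- sim_binary_factor(700, lam_eq, tau,
                             seed = sample.int(1e6, 1))
    pm <- polychoric_matrix(dat)
    fr <- fit_dwls(eq_spec, pm, n = 700)
    fu <- fit_dwls(spec, pm, n = 700)
    chi2_diff_test(fr, fu)$stat
  })
  # mean of a chi2(1) variate is 1; allow 10% plus 2 MC standard errors
  expect_lt(abs(mean(stats_null) - 1), 0.1 + 2 * sqrt(2 / 150))

  # sensitivity: a violated equality (Delta lambda ~ 0.3 on the std scale)
  set.seed(92)
  lam_bad <- lam; lam_bad[2] <- lam_bad[1] + 0.3
  rej <- mean(replicate(60, {
    dat <- sim_binary_factor(1160, lam_bad, tau, seed = sample.int(1e6, 1))
    pm <- polychoric_matrix(dat)
    fr <- fit_dwls(eq_spec, pm, n = 1160)
    fu <- fit_dwls(spec, pm, n = 1160)
    chi2_diff_test(fr, fu)$p < 0.05
  }))
  expect_gt(rej, 0.8)

  expect_error(chi2_diff_test(fit_dwls(spec, pm, n = 700),
                              fit_dwls(spec, polychoric_matrix(
                                sim_binary_factor(700, lam, tau, 123)),
                                n = 700)),
               "different sample statistics")
})

test_that("standardisation is idempotent and reflects predictor recoding", {
  cfg <- male_ext_config(n = 20000, beta_cross = 0.197, seed = 44)
  ch <- generate_full_study(cfg)
  frame <- cohort_frame(ch)
  spec <- build_association_spec(cfg$items$item, cfg$snps$snp, sex = "male",
                                 phenotype = "cross", waves = 1,
                                 predictor = "latent")
  pm <- polychoric_matrix(frame[spec$vars$var])
  fit <- fit_dwls(spec, pm, n = nrow(frame))
  sc <- std_coef(fit, "F1", "G")
  # recovery of the injected standardised coefficient at large n
  expect_lt(abs(sc$std_beta - 0.197), 0.02)
  # the model is standardised by construction: standardize() leaves the
  # regression unchanged
  std <- standardize(fit)
  expect_equal(std$est_std[std$type == "regression"],
               fit$estimates[["b_w1"]], tolerance = 1e-8)
  expect_true(sc$ci_low <= sc$std_beta && sc$std_beta <= sc$ci_high)

  # flipping the indicator coding of the predictor negates the coefficient
  flipped <- frame
  for (s in cfg$snps$snp) flipped[[s]] <- 1L - flipped[[s]]
  pm2 <- polychoric_matrix(flipped[spec$vars$var])
  fit2 <- fit_dwls(spec, pm2, n = nrow(flipped))
  expect_equal(fit2$estimates[["b_w1"]], -fit$estimates[["b_w1"]],
               tolerance = 1e-6)
})

test_that("reparameterisation-invariant identification yields identical chi2", {
  # unit-variance vs free-variance-with-shared-loading identification
  dat <- sim_binary_factor(900, c(0.42, 0.43, 0.63, 0.69, 0.29, 0.24),
                           rep(0.4, 6), seed = 13)
  pm <- polychoric_matrix(dat)
  f_unit <- fit_dwls(one_factor_spec(paste0("v", 1:6)), pm, n = 900)

  vars <- tibble::tibble(var = paste0("v", 1:6), n_cat = 2L)
  pt <- dplyr::bind_rows(lapply(paste0("v", 1:6), function(v) {
    dplyr::bind_rows(
      genefactor:::pt_row("lambda", v, "F1", v != "v1", 1,
                          if (v == "v1") "" else paste0("l_", v)),
      genefactor:::pt_row("tau", v, 1, TRUE, NA, paste0("t_", v)),
      genefactor:::pt_row("theta_d", v, v, FALSE, 1))
  }))
  pt <- dplyr::bind_rows(pt, genefactor:::pt_row("psi", "F1", "F1", TRUE,
                                                 0.5, "vF"))
  f_ref <- fit_dwls(sem_spec(vars, "F1", pt), pm, n = 900)
  expect_true(f_unit$converged && f_ref$converged)
  expect_equal(f_unit$chi2_raw, f_ref$chi2_raw, tolerance = 1e-6)
})

test_that("DWLS is consistent on the full cross-sectional structure at large n", {
  cfg <- sim_config(sex = "male", n = 50000, traits = "extraversion",
                    waves = 2,
                    beta_cross = c(extraversion = -0.167, neuroticism = 0),
                    beta_change = c(extraversion = 0.197, neuroticism = 0),
                    seed = 71)
  ch <- generate_full_study(cfg)
  frame <- cohort_frame(ch)
  spec <- build_association_spec(cfg$items$item, cfg$snps$snp, sex = "male",
                                 phenotype = "cross", waves = 2,
                                 predictor = "latent")
  pm <- polychoric_matrix(frame[spec$vars$var])
  fit <- fit_dwls(spec, pm, n = nrow(frame))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["b_w1"]] - (-0.167)), 0.02)
  std <- standardize(fit)
  lam_std <- std$est_std[std$type == "loading"][1:6]
  expect_lt(max(abs(lam_std - cfg$items$lambda_std)), 0.02)
})
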