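test_that("BH-FDR adjustment matches the brute-force step-up definition", {
  bh_brute <- function(p, m = length(p)) {
    # step-up: adj_(i) = min over j >= i of m p_(j) / j, capped at 1
    o <- order(p)
    ranked <- p[o]
    adj <- rev(cummin(rev(m * ranked / seq_along(ranked))))
    pmin(1, adj)[order(o)]
  }
  # published pair: smallest p 0.003 and 0.007 in a family of 12
  fam <- c(0.003, 0.007, runif(10, 0.1, 1))
  adj <- fdr_adjust(fam, family_size = 12)
  expect_equal(adj[1], 0.036)
  expect_equal(adj[2], 0.042)

  expect_equal(fdr_adjust(0.02), 0.02)

  set.seed(5)
  for (r in 1:1000) {
    p <- runif(sample(3:12, 1))
    expect_equal(fdr_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  # partial family: padding with p = 1 equals brute force at family size
  p <- runif(5)
  expect_equal(fdr_adjust(p, family_size = 12),
               bh_brute(c(p, rep(1, 7)), 12)[1:5], tolerance = 1e-12)
  expect_error(fdr_adjust(runif(5), family_size = 3), "family_size")
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("adjusted p-values respect the FDR invariants", {
  set.seed(9)
  p <- runif(12)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("the genetic factor fragment recovers indicator loadings", {
  cfg <- male_ext_config(n = 20000, seed = 3)
  ch <- generate_full_study(cfg)
  sc <- genetic_factor_scores(ch$geno, cfg$snps$snp)
  fit <- attr(sc, "fit")
  std <- standardize(fit)
  lam <- std$est_std[std$type == "loading"]
  expect_lt(max(abs(lam - cfg$snps$lambda_std)), 0.02)
  # scores order with the true genetic factor
  expect_gt(cor(sc$score, ch$truth$G), 0.7)

  expect_warning(build_genetic_factor_spec(c("a", "b")),
                 "under-identification")
  expect_error(genetic_factor_scores(
    dplyr::bind_rows(ch$geno,
                     dplyr::mutate(ch$geno[1, ],
                                   sex = factor("female",
                                                levels = c("male",
                                                           "female")))),
    cfg$snps$snp), "single-sex")
})

test_that("independent SNPs still identify the genetic factor", {
  set.seed(17)
  n <- 20000
  G <- rnorm(n)
  lam <- c(0.6, 0.55, 0.5)
  geno <- tibble::tibble(sample_id = sprintf("s%05d", 1:n),
                         sex = factor("male", levels = c("male", "female")))
  for (j in 1:3) {
    liab <- lam[j] * G + sqrt(1 - lam[j]^2) * rnorm(n)
    geno[[paste0("snp", j)]] <- as.integer(liab > qnorm(0.7))
  }
  sc <- genetic_factor_scores(geno, paste0("snp", 1:3))
  std <- standardize(attr(sc, "fit"))
  expect_lt(max(abs(std$est_std[std$type == "loading"] - lam)), 0.03)
})

test_that("cross-sectional and latent change fits share chi2 and recover effects", {
  cfg <- sim_config(sex = "male", n = 1160, traits = "extraversion",
                    waves = 2,
                    beta_cross = c(extraversion = -0.167, neuroticism = 0),
                    beta_change = c(extraversion = 0.197, neuroticism = 0),
                    seed = 29)
  ch <- generate_full_study(cfg)
  cs <- fit_cross_sectional(ch$geno, ch$items, cfg$items$item,
                            cfg$snps$snp)
  lc <- fit_latent_change(ch$geno, ch$items, cfg$items$item, cfg$snps$snp)
  # identical model in an alternative parameterisation
  expect_equal(cs$fit$chi2_raw, lc$fit$chi2_raw, tolerance = 1e-6)
  expect_equal(cs$fit$chi2, lc$fit$chi2, tolerance = 1e-4)
  expect_equal(nrow(cs$result), 2)
  expect_true(all(c("std_beta", "ci_low", "ci_high", "p") %in%
                    names(lc$result)))
  expect_gte(lc$change$change_var, 0)
  # ci contains the estimate
  expect_true(all(cs$result$ci_low <= cs$result$std_beta &
                    cs$result$std_beta <= cs$result$ci_high))

  # mixed-sex input is a stratification error
  mixed <- ch$geno
  mixed$sex[1] <- "female"
  expect_error(fit_cross_sectional(mixed, ch$items, cfg$items$item,
                                   cfg$snps$snp), "sex-separate")
})

test_that("run_association assembles the FDR family across traits", {
  cfg <- sim_config(sex = "male", n = 900,
                    beta_cross = c(extraversion = -0.3, neuroticism = 0),
                    beta_change = c(extraversion = 0, neuroticism = 0),
                    seed = 37)
  ch <- generate_full_study(cfg)
  traits <- list(extraversion = paste0("e", 1:6),
                 neuroticism = paste0("n", 1:6))
  res <- run_association(ch$geno, ch$items, traits, cfg$snps$snp,
                         family_size = 12)
  expect_equal(nrow(res), 6)
  expect_true(all(res$fdr_p >= res$p - 1e-12))
  expect_setequal(
    res$phenotype,
    c("extraversion_age16", "extraversion_age26", "extraversion_change",
      "neuroticism_age16", "neuroticism_age26", "neuroticism_change"))
})

test_that("extreme-group subgrouping sizes and amplification", {
  cfg <- male_ext_config(n = 1160, beta_cross = -0.3, waves = 2, seed = 41)
  ch <- generate_full_study(cfg)
  eg <- extreme_group_analysis(ch$geno, ch$items, cfg$items$item,
                               cfg$snps$snp)
  expect_equal(eg$n_subgroup, 2 * floor(0.3 * 1160))  # 696

  # The extreme-group coefficient estimates the group contrast on the
  # latent trait.  With hemizygous indicators the genetic factor scores
  # take only 8 values, so the "top/bottom 30%" selection is coarse; the
  # estimator is checked against a truth-based oracle (the sample
  # correlation between the group indicator and the true wave-1 factor in
  # the selected subsample) rather than against the full-sample
  # coefficient.
  set.seed(140)
  diffs <- replicate(15, {
    seed <- sample.int(1e6, 1)
    ch <- generate_full_study(cfg, seed = seed)
    eg <- extreme_group_analysis(ch$geno, ch$items, cfg$items$item,
                                 cfg$snps$snp)
    sc <- eg$scores
    ord <- order(sc$score, sc$sample_id)
    k <- floor(0.3 * nrow(sc))
    ids <- c(sc$sample_id[ord[seq_len(k)]],
             sc$sample_id[ord[seq(nrow(sc) - k + 1, nrow(sc))]])
    grp <- rep(c(0, 1), each = k)
    tru <- ch$truth$E16[match(ids, ch$truth$sample_id)]
    eg$result$std_beta - cor(grp, tru)
  })
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("a null genetic factor gives a null extreme-group contrast", {
  cfg <- male_ext_config(n = 1160, beta_cross = 0, waves = 2, seed = 43)
  ch <- generate_full_study(cfg)
  eg <- extreme_group_analysis(ch$geno, ch$items, cfg$items$item,
                               cfg$snps$snp)
  expect_lt(abs(eg$result$std_beta), 3 * eg$result$se)
  expect_gt(eg$result$p, 0.001)
})
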