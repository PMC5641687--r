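#' Default simulation configuration
#'
#' Assembles the study conditions used throughout the package: three
#' X-linked SNPs (MAFs 0.22-0.30, pairwise dosage correlations 0.52-0.79,
#' latent-factor loadings 0.96-0.99), six binary extraversion and six binary
#' neuroticism items per wave (standardised loadings 0.24-0.90, endorsement
#' 0.17-0.76), cross-wave latent correlations around 0.5-0.6, and
#' standardised genetic effects expressed so that the variance explained
#' equals `beta^2`.  Item thresholds come from the wave-1 endorsement
#' proportions and are held equal across waves (measurement-invariant
#' truth); latent mean change defaults to zero.
#'
#' @param sex `"male"` or `"female"`; selects loadings, thresholds and MAFs.
#' @param n number of samples (defaults: 1160 males, 1180 females).
#' @param traits subset of `c("extraversion", "neuroticism")`.
#' @param waves 1 (wave-1 items only) or 2.
#' @param beta_cross named numeric, standardised effect of the genetic
#'   factor on each wave-1 trait factor.
#' @param beta_change named numeric, standardised effect on the latent
#'   change score of each trait.
#' @param resid_cross_wave_corr residual correlation between the two
#'   administrations of the same item.
#' @param missing_rate MCAR missingness fraction applied to genotype calls
#'   and item responses.
#' @param seed master seed; per-replicate seeds are derived by fixed
#'   increments.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sex = "male", n = NULL,
                       traits = c("extraversion", "neuroticism"),
                       waves = 2,
                       beta_cross = c(extraversion = -0.167,
                                      neuroticism = 0),
                       beta_change = c(extraversion = 0.197,
                                       neuroticism = 0),
                       resid_cross_wave_corr = 0.2,
                       missing_rate = 0,
                       seed = 1L) {
  sex <- match.arg(sex, c("male", "female"))
  traits <- match.arg(traits, several.ok = TRUE)
  stopifnot(waves %in% 1:2)
  if (is.null(n)) n <- if (sex == "male") 1160L else 1180L

  items <- readr::read_csv(
    system.file("extdata", "mpi_item_stats.csv", package = "genefactor"),
    col_types = "ccccdddd", progress = FALSE)
  items <- items[items$sex == sex & items$trait %in% traits, ]
  items$prop_yes <- items$n_yes / (items$n_yes + items$n_no)
  w1 <- items[items$wave == "t1", ]
  # invariant truth: wave-1 loadings/thresholds reused at wave 2
  item_par <- w1[, c("item", "trait", "loading", "prop_yes")]
  names(item_par)[3] <- "lambda_std"
  item_par$tau <- qnorm(1 - item_par$prop_yes)

  snps <- readr::read_csv(
    system.file("extdata", "maoa_snp_stats.csv", package = "genefactor"),
    col_types = "ciccddidiii", progress = FALSE)
  snps <- snps[snps$sex == sex, c("snp", "position", "loading", "maf")]
  names(snps)[3] <- "lambda_std"

  ld <- readr::read_csv(
    system.file("extdata", "maoa_snp_ld.csv", package = "genefactor"),
    col_types = "cccd", progress = FALSE)
  ld <- ld[ld$sex == sex, ]

  fs <- readr::read_csv(
    system.file("extdata", "factor_structure.csv", package = "genefactor"),
    col_types = "cccd", progress = FALSE)
  fs <- fs[fs$sex == sex, ]
  phen <- c("E16", "E26", "N16", "N26")
  R <- diag(1, 4); dimnames(R) <- list(phen, phen)
  for (i in seq_len(nrow(fs))) {
    if (fs$var_a[i] == "G") next
    R[fs$var_a[i], fs$var_b[i]] <- R[fs$var_b[i], fs$var_a[i]] <- fs$value[i]
  }

  cfg <- structure(list(
    sex = sex, n = as.integer(n), traits = traits, waves = waves,
    items = item_par, snps = snps, snp_ld_targets = ld,
    factor_corr = R,
    beta_cross = beta_cross[traits], beta_change = beta_change[traits],
    resid_cross_wave_corr = resid_cross_wave_corr,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (any(abs(cfg$items$lambda_std) >= 1) || any(abs(cfg$snps$lambda_std) >= 1))
    stop("standardised loadings must lie in (-1, 1)", call. = FALSE)
  if (any(!is.finite(cfg$items$tau)))
    stop("thresholds must be finite", call. = FALSE)
  if (any(cfg$beta_cross^2 > 1) || any(cfg$beta_change^2 > 1))
    stop("variance-accounting error: beta^2 must not exceed 1",
         call. = FALSE)
  ev <- eigen(cfg$factor_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("factor correlation matrix is not positive semi-definite",
         call. = FALSE)
  invisible(cfg)
}

# --- maximum-entropy multi-locus haplotype distribution -------------------

# Fit the exponential-family (max-ent) distribution over 2^L haplotypes
# subject to per-locus allele frequencies and pairwise dosage correlations.
fit_haplotype_maxent <- function(mafs, ld_r) {
  L <- length(mafs)
  if (any(mafs <= 0 | mafs >= 1)) {
    stop("degenerate MAF target (must be in (0,1))", call. = FALSE)
  }
  states <- as.matrix(expand.grid(rep(list(0:1), L)))[, L:1, drop = FALSE]
  pairs <- which(upper.tri(diag(L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  m1 <- mafs
  m2 <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- ld_r[i, j]
    lim <- sqrt(mafs[i] * (1 - mafs[i]) * mafs[j] * (1 - mafs[j]))
    m2[p] <- r * lim + mafs[i] * mafs[j]
    hi <- min(mafs[i], mafs[j]); lo <- max(0, mafs[i] + mafs[j] - 1)
    if (m2[p] > hi + 1e-12 || m2[p] < lo - 1e-12) {
      stop(sprintf(
        "infeasible LD target r=%.3f for pair (%d,%d): implied P(1,1)=%.4f outside [%.4f, %.4f]",
        r, i, j, m2[p], lo, hi), call. = FALSE)
    }
  }
  targets <- c(m1, m2)
  feats <- cbind(states,
                 do.call(cbind, lapply(seq_len(nrow(pairs)), function(p) {
                   states[, pairs[p, 1]] * states[, pairs[p, 2]]
                 })))
  dual <- function(th) {
    en <- as.vector(feats %*% th)
    mx <- max(en)
    log(sum(exp(en - mx))) + mx - sum(th * targets)
  }
  dual_gr <- function(th) {
    en <- as.vector(feats %*% th)
    w <- exp(en - max(en)); w <- w / sum(w)
    as.vector(crossprod(feats, w)) - targets
  }
  opt <- optim(rep(0, ncol(feats)), dual, dual_gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  en <- as.vector(feats %*% opt$par)
  f <- exp(en - max(en)); f <- f / sum(f)
  achieved <- as.vector(crossprod(feats, f))
  if (max(abs(achieved - targets)) > 1e-5) {
    bad <- which.max(abs(achieved - targets))
    stop("infeasible MAF/LD combination: moment ", bad,
         " off by ", signif(max(abs(achieved - targets)), 3), call. = FALSE)
  }
  list(freqs = f, states = states)
}

#' Generate X-linked SNP genotypes from target MAF and LD
#'
#' Haplotypes are drawn from the maximum-entropy multi-locus distribution
#' matching the configured allele frequencies and pairwise dosage
#' correlations; males receive one haplotype (dosage 0/1), females two
#' (dosage 0/1/2, random mating).
#'
#' @param config a [sim_config()] (fields `snps`, `snp_ld_targets`, `n`,
#'   `sex`) or a list with `mafs`, `ld_r` (matrix), `n`, `sex`.
#' @param seed overrides `config$seed`.
#' @return genotype tibble ([read_genotypes()] layout).
#' @export
generate_snps <- function(config, seed = NULL) {
  if (inherits(config, "sim_config")) {
    mafs <- config$snps$maf
    ids <- config$snps$snp
    L <- length(mafs)
    ld_r <- diag(1, L); dimnames(ld_r) <- list(ids, ids)
    for (i in seq_len(nrow(config$snp_ld_targets))) {
      a <- config$snp_ld_targets$snp_a[i]; b <- config$snp_ld_targets$snp_b[i]
      ld_r[a, b] <- ld_r[b, a] <- config$snp_ld_targets$r[i]
    }
    n <- config$n; sex <- config$sex
    if (is.null(seed)) seed <- config$seed
  } else {
    mafs <- config$mafs; ld_r <- config$ld_r; n <- config$n
    sex <- config$sex %||% "male"
    ids <- config$ids %||% paste0("snp", seq_along(mafs))
    if (is.null(seed)) seed <- config$seed %||% 1L
  }
  fit <- fit_haplotype_maxent(mafs, ld_r)
  set.seed(seed)
  draw <- function(k) fit$states[sample.int(nrow(fit$states), k,
                                            replace = TRUE,
                                            prob = fit$freqs), , drop = FALSE]
  if (sex == "male") {
    calls <- draw(n)
  } else {
    calls <- draw(n) + draw(n)
  }
  out <- tibble::tibble(sample_id = sprintf("s%05d", seq_len(n)),
                        sex = factor(sex, levels = c("male", "female")))
  for (j in seq_along(ids)) out[[ids[j]]] <- as.integer(calls[, j])
  attr(out, "haplotype_freqs") <- fit$freqs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SNP dosages as categorised indicators of the genetic factor: a liability
# l*G + sqrt(1-l^2)*delta cut at the threshold(s) implied by the MAF
# (Hardy-Weinberg genotype proportions for diploid females)
snp_dosages_from_g <- function(G, cfg) {
  n <- length(G)
  geno <- tibble::tibble(sample_id = sprintf("s%05d", seq_len(n)),
                         sex = factor(cfg$sex, levels = c("male", "female")))
  for (j in seq_len(nrow(cfg$snps))) {
    l <- cfg$snps$lambda_std[j]
    maf <- cfg$snps$maf[j]
    liab <- l * G + sqrt(1 - l^2) * rnorm(n)
    if (cfg$sex == "male") {
      geno[[cfg$snps$snp[j]]] <- as.integer(liab > qnorm(1 - maf))
    } else {
      t1 <- qnorm((1 - maf)^2); t2 <- qnorm(1 - maf^2)
      geno[[cfg$snps$snp[j]]] <- as.integer((liab > t1) + (liab > t2))
    }
  }
  geno
}

# theta-scale item parameters (lambda, tau) for the configured waves
item_theta_pars <- function(cfg) {
  tshort <- c(extraversion = "E", neuroticism = "N")
  ip <- cfg$items
  lam_theta <- ip$lambda_std / sqrt(1 - ip$lambda_std^2)
  tau_theta <- ip$tau * sqrt(lam_theta^2 + 1)
  one_wave <- tibble::tibble(item = ip$item, trait = ip$trait,
                             lambda = lam_theta, tau = tau_theta)
  if (cfg$waves == 2) {
    dplyr::bind_rows(
      dplyr::mutate(one_wave, wave = "t1",
                    factor = paste0(tshort[.data$trait], "16")),
      dplyr::mutate(one_wave, wave = "t2",
                    factor = paste0(tshort[.data$trait], "26")))
  } else {
    dplyr::mutate(one_wave, wave = "t1",
                  factor = paste0(tshort[.data$trait], "16"))
  }
}

#' Generate binary item responses from latent factor scores
#'
#' Liability-threshold measurement model on the theta scale: item `i` is
#' endorsed iff `lambda_i * eta + eps_i > tau_i` with `eps_i` standard
#' normal; repeated items (same `item` value at both waves) get residuals
#' correlated at `resid_cross_wave_corr`.
#'
#' @param latent_scores numeric matrix (samples x factors) with column names
#'   matching `items$factor`.
#' @param items tibble with columns `item`, `factor`, `lambda`, `tau`
#'   (theta-scale loading and threshold) and optionally `wave`.
#' @param resid_cross_wave_corr residual correlation for repeated items.
#' @param seed integer seed.
#' @return tibble `sample_id`, `wave`, one 0/1 column per item.
#' @export
generate_items <- function(latent_scores, items, resid_cross_wave_corr = 0,
                           seed = 1L) {
  set.seed(seed)
  n <- nrow(latent_scores)
  if (!"wave" %in% names(items)) items$wave <- "t1"
  liab <- matrix(NA_real_, n, nrow(items))
  eps <- matrix(NA_real_, n, nrow(items))
  done <- rep(FALSE, nrow(items))
  for (k in seq_len(nrow(items))) {
    if (done[k]) next
    partner <- which(items$item == items$item[k] & seq_len(nrow(items)) != k)
    if (length(partner) == 1 && resid_cross_wave_corr != 0) {
      z1 <- rnorm(n); z2 <- rnorm(n)
      eps[, k] <- z1
      eps[, partner] <- resid_cross_wave_corr * z1 +
        sqrt(1 - resid_cross_wave_corr^2) * z2
      done[c(k, partner)] <- TRUE
    } else {
      eps[, k] <- rnorm(n)
      done[k] <- TRUE
    }
  }
  for (k in seq_len(nrow(items))) {
    liab[, k] <- items$lambda[k] * latent_scores[, items$factor[k]] + eps[, k]
  }
  out <- NULL
  for (wv in unique(items$wave)) {
    idx <- which(items$wave == wv)
    block <- tibble::tibble(sample_id = sprintf("s%05d", seq_len(n)),
                            wave = factor(wv, levels = c("t1", "t2")))
    for (k in idx) {
      block[[items$item[k]]] <- as.integer(liab[, k] > items$tau[k])
    }
    out <- dplyr::bind_rows(out, block)
  }
  out
}

# factor covariance over (G, trait factors) implied by the configured
# cross-wave correlations and injected standardised genetic effects
factor_cov_with_g <- function(cfg) {
  traits <- cfg$traits
  tshort <- c(extraversion = "E", neuroticism = "N")[traits]
  if (cfg$waves == 2) {
    fac <- as.vector(t(outer(tshort, c("16", "26"), paste0)))
  } else {
    fac <- paste0(tshort, "16")
  }
  M <- diag(1, length(fac) + 1)
  nm <- c("G", fac)
  dimnames(M) <- list(nm, nm)
  M[fac, fac] <- cfg$factor_corr[fac, fac]
  for (i in seq_along(traits)) {
    f1 <- paste0(tshort[i], "16")
    bc <- cfg$beta_cross[[traits[i]]]
    M["G", f1] <- M[f1, "G"] <- bc
    if (cfg$waves == 2) {
      f2 <- paste0(tshort[i], "26")
      r12 <- cfg$factor_corr[f1, f2]
      sdd <- sqrt(2 - 2 * r12)
      bd <- cfg$beta_change[[traits[i]]]
      M["G", f2] <- M[f2, "G"] <- bc + bd * sdd
    }
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    stop("implied factor covariance not positive definite; reduce the ",
         "injected effects or factor correlations", call. = FALSE)
  }
  M
}

#' Generate a full synthetic cohort
#'
#' Draws latent factor scores for the genetic factor and the trait factors
#' (wave-2 factor = wave-1 factor + latent change by construction, with the
#' genetic factor regressed on wave-1 levels and on change at the configured
#' standardised coefficients), then SNP dosages as categorised indicators of
#' the genetic factor and binary items from the liability-threshold
#' measurement model with cross-wave correlated residuals.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return object of class `synthetic_cohort`: list with `geno`, `items`,
#'   `truth` (per-sample latent scores) and `config`.
#' @export
generate_full_study <- function(config, seed = NULL) {
  cfg <- validate_sim_config(config)
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)
  n <- cfg$n
  M <- factor_cov_with_g(cfg)
  fac <- colnames(M)
  Z <- matrix(rnorm(n * ncol(M)), n, ncol(M)) %*% chol(M)
  colnames(Z) <- fac

  # SNP dosages: categorised indicators of G (mirrors the analysis model)
  geno <- snp_dosages_from_g(Z[, "G"], cfg)

  # item parameters on the theta scale, thresholds invariant across waves
  tshort <- c(extraversion = "E", neuroticism = "N")
  items_par <- item_theta_pars(cfg)
  items <- generate_items(Z, items_par,
                          resid_cross_wave_corr = cfg$resid_cross_wave_corr,
                          seed = seed + 1L)

  if (cfg$missing_rate > 0) {
    for (s in snp_columns(geno)) {
      drop <- runif(n) < cfg$missing_rate
      geno[[s]][drop] <- NA_integer_
    }
    for (it in item_columns(items)) {
      drop <- runif(nrow(items)) < cfg$missing_rate
      items[[it]][drop] <- NA_integer_
    }
  }

  truth <- tibble::as_tibble(as.data.frame(Z))
  truth$sample_id <- geno$sample_id
  if (cfg$waves == 2) {
    for (tr in cfg$traits) {
      f1 <- paste0(tshort[tr], "16"); f2 <- paste0(tshort[tr], "26")
      truth[[paste0("change_", tshort[tr])]] <- truth[[f2]] - truth[[f1]]
    }
  }
  structure(list(geno = geno, items = items, truth = truth, config = cfg,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d %s samples, %d SNPs, %d items x %d wave(s)\n",
              x$config$n, x$config$sex, nrow(x$config$snps),
              nrow(x$config$items), x$config$waves))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pg <- file.path(dir, "genotypes.csv")
  pi <- file.path(dir, "items.csv")
  pt <- file.path(dir, "truth.csv")
  readr::write_csv(cohort$geno, pg, na = "NA")
  readr::write_csv(cohort$items, pi, na = "NA")
  readr::write_csv(cohort$truth, pt)
  yaml::write_yaml(list(sex = cohort$config$sex, n = cohort$config$n,
                        seed = cohort$seed,
                        beta_cross = as.list(cohort$config$beta_cross),
                        beta_change = as.list(cohort$config$beta_change)),
                   file.path(dir, "truth_config.yaml"))
  invisible(c(pg, pi, pt))
}
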