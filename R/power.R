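# Monte Carlo power analysis: latent genetic factor vs single-SNP
# association approaches, at post hoc and a priori effect sizes.

#' Define a power-analysis scenario
#'
#' @param approach `"latent"` (latent genetic factor predictor) or
#'   `"single_snp"` (one observed dosage column as predictor).
#' @param phenotype `"cross_sectional"` (wave-1 trait factor) or `"change"`
#'   (latent difference score).
#' @param effect_variance fraction of phenotypic variance explained by the
#'   predictor; the injected standardised coefficient is
#'   `sqrt(effect_variance)`.
#' @param n cohort size per replicate (study convention: 1160 males).
#' @param reps Monte Carlo replicates (study convention: 1000).
#' @param alpha two-sided Wald test level.
#' @param snp_id predictor SNP for the single-SNP approach (default: first
#'   configured SNP).
#' @param seed master seed; replicate seeds are derived by fixed increment.
#' @return list of class `power_scenario`.
#' @export
power_scenario <- function(approach = c("latent", "single_snp"),
                           phenotype = c("cross_sectional", "change"),
                           effect_variance, n = 1160, reps = 1000,
                           alpha = 0.05, snp_id = NULL, seed = 1L) {
  approach <- match.arg(approach)
  phenotype <- match.arg(phenotype)
  stopifnot(effect_variance >= 0, effect_variance < 1, reps >= 1)
  structure(list(approach = approach, phenotype = phenotype,
                 effect_variance = effect_variance, n = as.integer(n),
                 reps = as.integer(reps), alpha = alpha, snp_id = snp_id,
                 seed = as.integer(seed)),
            class = "power_scenario")
}

# Default study conditions for the male extraversion power analyses:
# population parameters equal to the observed sample quantities (Table-style
# loadings/thresholds/MAFs, cross effect -0.167, change effect 0.197), with
# the scenario overriding the coefficient under test.  The analysis model is
# the two-wave cross-sectional association model (or its latent-difference
# reparameterisation).
power_template <- function(scenario, template = NULL) {
  if (!is.null(template)) return(template)
  sim_config(sex = "male", n = scenario$n, traits = "extraversion",
             waves = 2,
             beta_cross = c(extraversion = -0.167, neuroticism = 0),
             beta_change = c(extraversion = 0.197, neuroticism = 0),
             seed = scenario$seed)
}

#' Monte Carlo power of the latent genetic association test
#'
#' Per replicate: generate a cohort with the genetic factor explaining
#' `effect_variance` of the phenotype (wave-1 factor, or the latent
#' difference score), estimate the polychoric statistics, fit the latent
#' association model by DWLS, and apply the two-sided Wald test of the
#' genetic coefficient at `alpha`.  Rejections are aggregated over
#' converged replicates.
#'
#' @param scenario a [power_scenario()].
#' @param template a [sim_config()] supplying loadings, thresholds, MAFs
#'   and the background effects; defaults to the male extraversion study
#'   conditions.
#' @return one-row tibble of class `power_result`.
#' @export
run_power <- function(scenario, template = NULL) {
  cfg <- power_template(scenario, template)
  b <- sqrt(scenario$effect_variance)
  if (scenario$phenotype == "cross_sectional") {
    cfg$beta_cross["extraversion"] <- -b  # observed direction; two-sided test
    target <- "b_w1"
  } else {
    cfg$beta_change["extraversion"] <- b
    target <- "b_chg"
  }
  cfg$n <- scenario$n
  spec <- build_association_spec(
    cfg$items$item, cfg$snps$snp, sex = cfg$sex,
    phenotype = if (scenario$phenotype == "change") "change" else "cross",
    waves = cfg$waves, predictor = "latent", invariance = "strict")
  run_power_loop(scenario, cfg, spec, target, generator = function(seed) {
    ch <- generate_full_study(cfg, seed = seed)
    frame <- items_wide(ch$items)
    for (s in cfg$snps$snp) {
      frame[[s]] <- ch$geno[[s]][match(frame$sample_id, ch$geno$sample_id)]
    }
    list(frame = frame, continuous = character())
  })
}

#' Monte Carlo power of the single-SNP association test
#'
#' Same cohort generator family, but the phenotype effect is injected
#' through (and the analysis model regresses the latent trait factor on)
#' one observed standardised SNP dosage, with `effect_variance` defined
#' against the observed dosage variance.
#'
#' @inheritParams run_power
#' @return one-row tibble of class `power_result`.
#' @export
run_single_snp <- function(scenario, template = NULL) {
  if (scenario$phenotype != "cross_sectional") {
    stop("single-SNP power is implemented for the cross-sectional ",
         "phenotype", call. = FALSE)
  }
  cfg <- power_template(scenario, template)
  cfg$waves <- 1
  cfg$n <- scenario$n
  snp_id <- scenario$snp_id %||% cfg$snps$snp[1]
  b <- sqrt(scenario$effect_variance)
  items_par <- item_theta_pars(cfg)
  spec <- build_association_spec(cfg$items$item, "x_snp", sex = cfg$sex,
                                 phenotype = "cross", waves = 1,
                                 predictor = "observed")
  run_power_loop(scenario, cfg, spec, "b_w1", generator = function(seed) {
    set.seed(seed)
    n <- cfg$n
    G <- rnorm(n)
    geno <- snp_dosages_from_g(G, cfg)
    x <- geno[[snp_id]]
    xs <- (x - mean(x)) / stats::sd(x)
    eta <- cbind(E16 = b * xs + sqrt(1 - b^2) * rnorm(n))
    items <- generate_items(eta, items_par, seed = seed + 1L)
    frame <- items_wide(items)
    frame$x_snp <- xs[match(frame$sample_id, geno$sample_id)]
    list(frame = frame, continuous = "x_snp")
  })
}

run_power_loop <- function(scenario, cfg, spec, target, generator) {
  rejections <- 0L; failures <- 0L
  start <- NULL
  for (rep_i in seq_len(scenario$reps)) {
    seed_i <- scenario$seed + 10L * rep_i
    dat <- generator(seed_i)
    res <- tryCatch({
      pm <- polychoric_matrix(dat$frame[spec$vars$var],
                              continuous = dat$continuous)
      fit <- fit_dwls(spec, pm, n = nrow(dat$frame), start = start,
                      compute_chi2 = FALSE)
      if (!fit$converged) stop("non-convergence")
      fit
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    if (is.null(start)) start <- res$estimates
    z <- res$estimates[[target]] / res$se[[target]]
    if (is.finite(z) && 2 * pnorm(-abs(z)) < scenario$alpha) {
      rejections <- rejections + 1L
    }
  }
  eff <- scenario$reps - failures
  pw <- rejections / eff
  out <- tibble::tibble(
    approach = scenario$approach, phenotype = scenario$phenotype,
    effect_variance = scenario$effect_variance,
    snp_id = scenario$snp_id %||% NA_character_,
    n = scenario$n, reps = scenario$reps, alpha = scenario$alpha,
    rejections = rejections, convergence_failures = failures,
    power = pw, mc_se = sqrt(pw * (1 - pw) / eff),
    unreliable = failures > 0.05 * scenario$reps)
  class(out) <- c("power_result", class(out))
  out
}

#' A priori power table: latent vs matched single-SNP approach
#'
#' Sweeps the latent-approach effect sizes (fractions of phenotypic
#' variance explained) and the matched single-SNP effect sizes for the
#' cross-sectional extraversion template, returning one row per scenario.
#'
#' @param effect_variances latent-approach effect sizes (default 1%, 2%,
#'   3%).
#' @param single_snp_effects matched observed-dosage effect sizes (default
#'   0.7%, 1.2%, 1.6%).
#' @param n,reps,alpha,seed passed to [power_scenario()].
#' @param template optional [sim_config()].
#' @return `power_result` tibble with one row per scenario.
#' @export
apriori_table <- function(effect_variances = c(0.01, 0.02, 0.03),
                          single_snp_effects = c(0.007, 0.012, 0.016),
                          n = 1160, reps = 1000, alpha = 0.05, seed = 1L,
                          template = NULL) {
  rows <- list()
  for (k in seq_along(effect_variances)) {
    sc <- power_scenario("latent", "cross_sectional", effect_variances[k],
                         n = n, reps = reps, alpha = alpha,
                         seed = seed + 100000L * k)
    rows[[length(rows) + 1]] <- run_power(sc, template)
  }
  for (k in seq_along(single_snp_effects)) {
    sc <- power_scenario("single_snp", "cross_sectional",
                         single_snp_effects[k], n = n, reps = reps,
                         alpha = alpha, seed = seed + 100000L * (k + 10L))
    rows[[length(rows) + 1]] <- run_single_snp(sc, template)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_result", class(out))
  out
}

#' @importFrom ggplot2 autoplot
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.power_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$effect_variance, y = .data$power,
                               colour = .data$approach)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$power - 2 * .data$mc_se),
      ymax = pmin(1, .data$power + 2 * .data$mc_se))) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.1f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "phenotypic variance explained", y = "power",
                  colour = NULL,
                  title = "Monte Carlo power (bars: +/- 2 MC SE)") +
    ggplot2::theme_minimal()
}
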