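# Latent genetic factor association analyses: cross-sectional and latent
# change models, FDR correction, factor scoring and the extreme-group
# sensitivity analysis.

prepare_analysis_frame <- function(geno, items, trait_items, snps) {
  sexes <- unique(as.character(geno$sex))
  if (length(sexes) > 1) {
    stop("stratification error: analyses are sex-separate; filter the ",
         "genotype table to one sex first", call. = FALSE)
  }
  wide <- items_wide(items)
  keep <- intersect(wide$sample_id, geno$sample_id)
  wide <- wide[match(keep, wide$sample_id), , drop = FALSE]
  g <- geno[match(keep, geno$sample_id), , drop = FALSE]
  for (s in snps) wide[[s]] <- g[[s]]
  list(frame = wide, sex = sexes)
}

#' Cross-sectional latent genetic association model
#'
#' Regresses the wave-1 and wave-2 trait factors simultaneously on the
#' latent genetic factor measured by the SNP indicators, with
#' strict-invariant measurement carried over from the invariance analysis.
#'
#' @param geno single-sex genotype tibble.
#' @param items item tibble (both waves).
#' @param trait_items character vector of item columns for one trait.
#' @param snps SNP column names (3 for the genetic factor).
#' @param trait label used in the result rows.
#' @param invariance `"strict"` or `"strong"`.
#' @return list with `result` (association rows for age-16 and age-26
#'   phenotypes) and `fit` (the `sem_fit`).
#' @export
fit_cross_sectional <- function(geno, items, trait_items, snps,
                                trait = "extraversion",
                                invariance = "strict") {
  pa <- prepare_analysis_frame(geno, items, trait_items, snps)
  spec <- build_association_spec(trait_items, snps, sex = pa$sex,
                                 phenotype = "cross", waves = 2,
                                 predictor = "latent",
                                 invariance = invariance)
  pm <- polychoric_matrix(pa$frame[spec$vars$var])
  fit <- fit_dwls(spec, pm, n = nrow(pa$frame))
  if (!fit$converged) {
    stop("cross-sectional model did not converge (gradient norm ",
         signif(fit$grad_norm, 3), ")", call. = FALSE)
  }
  res <- dplyr::bind_rows(
    dplyr::mutate(std_coef(fit, "F1", "G"),
                  phenotype = paste0(trait, "_age16")),
    dplyr::mutate(std_coef(fit, "F2", "G"),
                  phenotype = paste0(trait, "_age26")))
  res$sex <- pa$sex
  list(result = assoc_result(res), fit = fit)
}

#' Latent difference score association model
#'
#' The wave-2 factor is written as wave-1 factor plus a latent change
#' score (autoregressive path fixed at 1, wave-2 residual variance 0); the
#' change score's mean and variance are estimated and the change score is
#' regressed on the latent genetic factor.
#'
#' @inheritParams fit_cross_sectional
#' @return list with `result` (one association row for the change
#'   phenotype), `change` (tibble with the latent change mean and
#'   variance) and `fit`.
#' @export
fit_latent_change <- function(geno, items, trait_items, snps,
                              trait = "extraversion",
                              invariance = "strict") {
  pa <- prepare_analysis_frame(geno, items, trait_items, snps)
  spec <- build_association_spec(trait_items, snps, sex = pa$sex,
                                 phenotype = "change", waves = 2,
                                 predictor = "latent",
                                 invariance = invariance)
  pm <- polychoric_matrix(pa$frame[spec$vars$var])
  fit <- fit_dwls(spec, pm, n = nrow(pa$frame))
  if (!fit$converged) {
    stop("latent change model did not converge (gradient norm ",
         signif(fit$grad_norm, 3), ")", call. = FALSE)
  }
  res <- dplyr::mutate(std_coef(fit, "D", "G"),
                       phenotype = paste0(trait, "_change"),
                       sex = pa$sex)
  chg <- tibble::tibble(
    trait = trait, sex = pa$sex,
    change_mean = fit$estimates[["dmean"]],
    change_var = max(0, fit$estimates[["dvar"]]) +
      param_value(fit, "beta", "D", "G")^2,
    heywood = fit$heywood)
  list(result = assoc_result(res), change = chg, fit = fit)
}

assoc_result <- function(df) {
  df <- df[, c("phenotype", "sex", "std_beta", "se", "ci_low", "ci_high",
               "p", intersect("fdr_p", names(df)))]
  class(df) <- c("assoc_result", class(df))
  df
}

#' Benjamini-Hochberg FDR adjustment with an explicit family size
#'
#' Step-up adjusted p-values for a declared testing family; when only part
#' of the family is supplied, the remaining tests are treated as
#' non-significant (p = 1), which leaves the step-up adjustment of the
#' supplied values unchanged.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param family_size total number of tests in the family (defaults to
#'   `length(p_values)`); must be at least `length(p_values)`.
#' @return adjusted p-values in the input order.
#' @examples
#' fdr_adjust(c(0.003, 0.007, rep(0.5, 10)))  # 0.036, 0.042, ...
#' @export
fdr_adjust <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  k <- length(p_values)
  if (family_size < k) {
    stop("family_size (", family_size, ") smaller than the number of ",
         "supplied p-values (", k, ")", call. = FALSE)
  }
  padded <- c(p_values, rep(1, family_size - k))
  p.adjust(padded, method = "BH")[seq_len(k)]
}

#' Run the full association analysis for one sex
#'
#' Cross-sectional (age-16 and age-26) and latent-change models per trait,
#' with BH-FDR adjusted p-values over the declared family.
#'
#' @inheritParams fit_cross_sectional
#' @param traits named list mapping trait label to its item columns.
#' @param family_size FDR family size; the study convention is 12
#'   (2 sexes x 2 traits x 3 phenotypes), so a single-sex run of both
#'   traits contributes 6 of 12 tests.
#' @return tibble of association rows with `fdr_p`.
#' @export
run_association <- function(geno, items, traits, snps, family_size = 12,
                            invariance = "strict") {
  rows <- list(); fits <- list(); changes <- list()
  for (tr in names(traits)) {
    cs <- fit_cross_sectional(geno, items, traits[[tr]], snps, trait = tr,
                              invariance = invariance)
    lc <- fit_latent_change(geno, items, traits[[tr]], snps, trait = tr,
                            invariance = invariance)
    rows[[length(rows) + 1]] <- cs$result
    rows[[length(rows) + 1]] <- lc$result
    fits[[paste0(tr, "_cross")]] <- cs$fit
    fits[[paste0(tr, "_change")]] <- lc$fit
    changes[[tr]] <- lc$change
  }
  out <- dplyr::bind_rows(rows)
  out$fdr_p <- fdr_adjust(out$p, family_size = family_size)
  attr(out, "fits") <- fits
  attr(out, "change_estimates") <- dplyr::bind_rows(changes)
  assoc_result(out)
}

#' Posterior-mode factor scores for the latent genetic factor
#'
#' Fits the genetic-factor measurement model to the SNP columns and scores
#' each sample at the posterior mode of `G` given its dosage pattern under
#' the fitted probit measurement model.
#'
#' @param geno single-sex genotype tibble.
#' @param snps SNP column names.
#' @return tibble `sample_id`, `score`; the fitted `sem_fit` is attached as
#'   attribute `fit`.
#' @export
genetic_factor_scores <- function(geno, snps) {
  sexes <- unique(as.character(geno$sex))
  if (length(sexes) > 1) stop("single-sex input required", call. = FALSE)
  gf <- build_genetic_factor_spec(snps, sexes)
  spec <- sem_spec(gf$vars, "G", gf$partable,
                   theta_std_vars = gf$theta_std_vars)
  pm <- polychoric_matrix(geno[snps])
  fit <- fit_dwls(spec, pm, n = nrow(geno), compute_chi2 = FALSE)
  lam <- vapply(snps, function(s) param_value(fit, "lambda", s, "G"),
                numeric(1))
  tau <- lapply(snps, function(s) {
    nc <- gf$vars$n_cat[gf$vars$var == s]
    vapply(seq_len(nc - 1), function(k) {
      fit$estimates[[paste0("gt_", s, "_", k)]]
    }, numeric(1))
  })
  resid_sd <- sqrt(pmax(1 - lam^2, 1e-6))
  # category log-probabilities given g, delta parameterisation
  cat_logp <- function(g, j, cat) {
    cuts <- c(-Inf, tau[[j]], Inf)
    lo <- (cuts[cat + 1] - lam[j] * g) / resid_sd[j]
    hi <- (cuts[cat + 2] - lam[j] * g) / resid_sd[j]
    log(pmax(pnorm(hi) - pnorm(lo), 1e-300))
  }
  X <- as.matrix(geno[snps])
  pat <- apply(X, 1, paste, collapse = "/")
  score_of <- vapply(unique(pat), function(pp) {
    x <- as.integer(strsplit(pp, "/")[[1]])
    if (any(is.na(x))) return(NA_real_)
    optimize(function(g) {
      dnorm(g, log = TRUE) +
        sum(vapply(seq_along(snps), function(j) cat_logp(g, j, x[j]),
                   numeric(1)))
    }, interval = c(-6, 6), maximum = TRUE)$maximum
  }, numeric(1))
  out <- tibble::tibble(sample_id = geno$sample_id,
                        score = score_of[pat])
  attr(out, "fit") <- fit
  out
}

#' Extreme-group sensitivity analysis
#'
#' Scores the latent genetic factor, keeps the top and bottom `fraction` of
#' scores (deterministic tie-break: stable order by sample id), and
#' regresses the latent trait phenotype on the standardised binary group
#' indicator.
#'
#' @inheritParams fit_cross_sectional
#' @param fraction fraction retained at each extreme (study convention
#'   0.30).
#' @param phenotype `"age16"` (wave-1 factor) or `"change"`.
#' @return list with `result` (association row), `n_subgroup`, `fit`.
#' @export
extreme_group_analysis <- function(geno, items, trait_items, snps,
                                   fraction = 0.30,
                                   phenotype = c("age16", "change"),
                                   trait = "extraversion") {
  phenotype <- match.arg(phenotype)
  sc <- genetic_factor_scores(geno, snps)
  sc <- sc[!is.na(sc$score), , drop = FALSE]
  ord <- order(sc$score, sc$sample_id)  # stable tie-break
  k <- floor(fraction * nrow(sc))
  low <- sc$sample_id[ord[seq_len(k)]]
  high <- sc$sample_id[ord[seq(nrow(sc) - k + 1, nrow(sc))]]
  grp <- tibble::tibble(sample_id = c(low, high),
                        g_group = c(rep(0L, length(low)),
                                    rep(1L, length(high))))
  g2 <- geno[match(grp$sample_id, geno$sample_id), , drop = FALSE]
  wide <- items_wide(items)
  wide <- wide[match(grp$sample_id, wide$sample_id), , drop = FALSE]
  x <- grp$g_group
  wide$g_group <- as.numeric(scale(x))
  spec <- build_association_spec(
    trait_items, "g_group", sex = as.character(g2$sex[1]),
    phenotype = if (phenotype == "age16") "cross" else "change",
    waves = if (phenotype == "age16") 1 else 2,
    predictor = "observed")
  pm <- polychoric_matrix(wide[spec$vars$var], continuous = "g_group")
  fit <- fit_dwls(spec, pm, n = nrow(wide), compute_chi2 = FALSE)
  target <- if (phenotype == "age16") "F1" else "D"
  res <- dplyr::mutate(std_coef(fit, target, "PX"),
                       phenotype = paste0(trait, "_", phenotype,
                                          "_extreme_groups"),
                       sex = as.character(g2$sex[1]))
  list(result = assoc_result(res), n_subgroup = nrow(grp), fit = fit,
       scores = sc)
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Latent genetic association tests\n")
  NextMethod()
}

#' @importFrom ggplot2 autoplot
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.assoc_result <- function(object, ...) {
  object$phenotype <- factor(object$phenotype,
                             levels = rev(unique(object$phenotype)))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$std_beta, y = .data$phenotype)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "standardised beta (95% CI)", y = NULL,
                  title = "Latent genetic factor associations") +
    ggplot2::theme_minimal()
}
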