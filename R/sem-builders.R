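# Builders for the model specifications used throughout: invariance
# ladders, latent genetic factor measurement, and the cross-sectional /
# latent-difference association structures.
#
# Conventions (theta parameterisation):
#   * item residual variances fixed at 1 at wave 1; wave-2 residual
#     variances free under configural/strong and re-fixed at 1 under strict;
#   * wave-1 factor variances fixed at 1, factor means 0; wave-2 factor
#     variance and mean free once loadings/thresholds are constrained equal;
#   * repeated items get a free cross-wave residual covariance;
#   * SNP indicators of the genetic factor use the delta (standardised
#     residual) parameterisation, G variance fixed at 1.

wave_suffix <- c(t1 = "_t1", t2 = "_t2")

#' Reshape a long item table to one row per sample
#'
#' @param items item tibble ([read_items()] layout).
#' @return tibble with `sample_id` and `<item>_t1` / `<item>_t2` columns.
#' @export
items_wide <- function(items) {
  its <- item_columns(items)
  long <- tidyr::pivot_longer(items, cols = dplyr::all_of(its),
                              names_to = "item", values_to = "resp")
  long$key <- paste0(long$item, wave_suffix[as.character(long$wave)])
  tidyr::pivot_wider(long[, c("sample_id", "key", "resp")],
                     names_from = "key", values_from = "resp")
}

measurement_rows <- function(items, wave, factor_of, share_waves = FALSE,
                             resid_free = FALSE) {
  out <- list()
  sfx <- wave_suffix[wave]
  for (i in seq_along(items)) {
    it <- items[i]
    v <- paste0(it, sfx)
    lam_lab <- if (share_waves) paste0("l_", it) else paste0("l_", v)
    tau_lab <- if (share_waves) paste0("t_", it) else paste0("t_", v)
    out[[length(out) + 1]] <- pt_row("lambda", v, factor_of[i], TRUE, 0.9,
                                     lam_lab)
    out[[length(out) + 1]] <- pt_row("tau", v, 1, TRUE, NA, tau_lab)
    out[[length(out) + 1]] <- if (resid_free) {
      pt_row("theta_d", v, v, TRUE, 1, paste0("rv_", it))
    } else {
      pt_row("theta_d", v, v, FALSE, 1)
    }
  }
  dplyr::bind_rows(out)
}

resid_cor_rows <- function(items) {
  dplyr::bind_rows(lapply(items, function(it) {
    pt_row("theta_o", paste0(it, "_t1"), paste0(it, "_t2"), TRUE, 0.1,
           paste0("rc_", it))
  }))
}

#' Measurement-invariance ladder specifications
#'
#' Builds the configural, strong and strict two-wave models for binary
#' items.  Configural: free loadings and thresholds per wave, residual
#' variances fixed at 1, factor variances 1 and means 0.  Strong: loadings
#' and thresholds jointly equal across waves (they cannot be separated with
#' binary ratings), wave-2 factor variances, factor means and item residual
#' variances freed.  Strict: wave-2 residual variances re-fixed at 1.  All
#' three include per-item cross-wave residual covariances.
#'
#' @param item_info tibble with columns `item`, `trait`.
#' @param waves must be 2 (single-wave input is an error).
#' @return named list of `sem_spec` objects `configural`, `strong`,
#'   `strict`.
#' @export
build_ladder_specs <- function(item_info, waves = 2) {
  if (!identical(as.integer(waves), 2L)) {
    stop("the invariance ladder needs exactly two waves", call. = FALSE)
  }
  traits <- unique(item_info$trait)
  fac1 <- paste0("f_", traits, "_t1"); fac2 <- paste0("f_", traits, "_t2")
  factors <- c(fac1, fac2)
  vars <- tibble::tibble(
    var = c(paste0(item_info$item, "_t1"), paste0(item_info$item, "_t2")),
    n_cat = 2L)
  fmap1 <- paste0("f_", item_info$trait, "_t1")
  fmap2 <- paste0("f_", item_info$trait, "_t2")

  psi_rows <- function(w2_free) {
    out <- list()
    for (f in factors) {
      if (w2_free && f %in% fac2) {
        out[[length(out) + 1]] <- pt_row("psi", f, f, TRUE, 1,
                                         paste0("fv_", f))
      } else {
        out[[length(out) + 1]] <- pt_row("psi", f, f, FALSE, 1)
      }
    }
    cb <- utils::combn(factors, 2)
    for (k in seq_len(ncol(cb))) {
      out[[length(out) + 1]] <- pt_row("psi", cb[1, k], cb[2, k], TRUE, 0.3,
                                       paste0("pc_", cb[1, k], "_", cb[2, k]))
    }
    dplyr::bind_rows(out)
  }
  mean_rows <- function(w2_free) {
    if (!w2_free) return(NULL)
    dplyr::bind_rows(lapply(fac2, function(f) {
      pt_row("alpha", f, "", TRUE, 0, paste0("fm_", f))
    }))
  }

  mk <- function(share, resid_free, w2_free) {
    pt <- dplyr::bind_rows(
      measurement_rows(item_info$item, "t1", fmap1, share, FALSE),
      measurement_rows(item_info$item, "t2", fmap2, share, resid_free),
      resid_cor_rows(item_info$item),
      psi_rows(w2_free), mean_rows(w2_free))
    sem_spec(vars, factors, pt)
  }
  list(configural = mk(FALSE, FALSE, FALSE),
       strong = mk(TRUE, TRUE, TRUE),
       strict = mk(TRUE, FALSE, TRUE))
}

#' Latent genetic factor measurement fragment
#'
#' One latent factor `G` with variance fixed to 1, measured by binary
#' (male) or three-category ordinal (female) SNP dosage indicators in the
#' delta parameterisation.
#'
#' @param snps character vector of SNP column names.
#' @param sex `"male"` or `"female"` (analyses are sex-separate; a mix is
#'   an error at the data layer).
#' @return list with `vars`, `partable`, `theta_std_vars` for composition
#'   into a full spec.
#' @export
build_genetic_factor_spec <- function(snps, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (length(snps) < 3) {
    warning("under-identification: the genetic factor is scaled by its ",
            "fixed unit variance but has fewer than 3 indicators",
            call. = FALSE)
  }
  n_cat <- if (sex == "male") 2L else 3L
  vars <- tibble::tibble(var = snps, n_cat = n_cat)
  out <- list(pt_row("psi", "G", "G", FALSE, 1))
  for (s in snps) {
    out[[length(out) + 1]] <- pt_row("lambda", s, "G", TRUE, 0.9,
                                     paste0("gl_", s))
    for (k in seq_len(n_cat - 1)) {
      out[[length(out) + 1]] <- pt_row("tau", s, k, TRUE, NA,
                                       paste0("gt_", s, "_", k))
    }
  }
  list(vars = vars, partable = dplyr::bind_rows(out), theta_std_vars = snps)
}

#' Association model specifications
#'
#' Builds the structural models of Figure-1 type: a latent trait factor
#' (one or two waves, strong/strict invariant measurement) regressed on a
#' predictor that is either the latent genetic factor `G` (3 SNP
#' indicators) or a standardised observed column (single SNP dosage or an
#' extreme-group indicator).
#'
#' `phenotype = "cross"` regresses the wave-1 (and, with two waves, the
#' wave-2) factor on the predictor; `"change"` uses the latent difference
#' parameterisation: wave-2 factor = wave-1 factor + change, the
#' autoregressive path fixed at 1 and the wave-2 residual variance at 0,
#' with the change score's mean and variance estimated and the change score
#' regressed on the predictor.
#'
#' @param items character vector of item names (present at both waves for
#'   two-wave phenotypes).
#' @param snps SNP columns measuring `G`, or the single observed predictor
#'   column name when `predictor = "observed"`.
#' @param sex `"male"` or `"female"`.
#' @param phenotype `"cross"` or `"change"`.
#' @param waves 1 or 2 (change requires 2).
#' @param predictor `"latent"` or `"observed"`.
#' @param invariance `"strict"` (wave-2 residual variances fixed at 1) or
#'   `"strong"`.
#' @return a `sem_spec`.
#' @export
build_association_spec <- function(items, snps, sex = "male",
                                   phenotype = c("cross", "change"),
                                   waves = 2,
                                   predictor = c("latent", "observed"),
                                   invariance = c("strict", "strong")) {
  phenotype <- match.arg(phenotype)
  predictor <- match.arg(predictor)
  invariance <- match.arg(invariance)
  if (phenotype == "change" && waves != 2) {
    stop("the latent change phenotype needs two waves", call. = FALSE)
  }
  two <- waves == 2

  if (predictor == "latent") {
    gf <- build_genetic_factor_spec(snps, sex)
    pred_fac <- "G"
    pred_vars <- gf$vars; pred_pt <- gf$partable
    theta_std <- gf$theta_std_vars
  } else {
    if (length(snps) != 1) {
      stop("an observed predictor must be a single column", call. = FALSE)
    }
    pred_fac <- "PX"
    pred_vars <- tibble::tibble(var = snps, n_cat = 0L)
    pred_pt <- dplyr::bind_rows(
      pt_row("psi", "PX", "PX", FALSE, 1),
      pt_row("lambda", snps, "PX", FALSE, 1),
      pt_row("theta_d", snps, snps, FALSE, 0))
    theta_std <- character()
  }

  vars <- tibble::tibble(var = paste0(items, "_t1"), n_cat = 2L)
  if (two) {
    vars <- dplyr::bind_rows(vars,
                             tibble::tibble(var = paste0(items, "_t2"),
                                            n_cat = 2L))
  }
  vars <- dplyr::bind_rows(vars, pred_vars)

  share <- two  # equality of loadings/thresholds only meaningful with 2 waves
  meas <- measurement_rows(items, "t1", rep("F1", length(items)), share,
                           FALSE)
  pt <- list(meas)
  if (two) {
    pt[[length(pt) + 1]] <- measurement_rows(
      items, "t2", rep("F2", length(items)), share,
      resid_free = (invariance == "strong"))
    pt[[length(pt) + 1]] <- resid_cor_rows(items)
  }
  pt[[length(pt) + 1]] <- pred_pt

  if (phenotype == "cross") {
    factors <- c(pred_fac, "F1", if (two) "F2")
    pt[[length(pt) + 1]] <- pt_row("beta", "F1", pred_fac, TRUE, 0, "b_w1")
    if (two) {
      pt[[length(pt) + 1]] <- pt_row("beta", "F2", pred_fac, TRUE, 0, "b_w2")
      pt[[length(pt) + 1]] <- pt_row("psi", "F2", "F1", TRUE, 0.5, "rcov_12")
      pt[[length(pt) + 1]] <- pt_row("psi", "F2", "F2", TRUE, 1, "fv_w2")
      pt[[length(pt) + 1]] <- pt_row("alpha", "F2", "", TRUE, 0, "fm_w2")
    }
    std_total <- "F1"
  } else {
    factors <- c(pred_fac, "F1", "D", "F2")
    pt[[length(pt) + 1]] <- pt_row("beta", "F1", pred_fac, TRUE, 0, "b_w1")
    pt[[length(pt) + 1]] <- pt_row("beta", "D", pred_fac, TRUE, 0, "b_chg")
    pt[[length(pt) + 1]] <- pt_row("psi", "D", "F1", TRUE, -0.2, "dcov")
    pt[[length(pt) + 1]] <- pt_row("psi", "D", "D", TRUE, 0.6, "dvar")
    pt[[length(pt) + 1]] <- pt_row("alpha", "D", "", TRUE, 0, "dmean")
    pt[[length(pt) + 1]] <- pt_row("beta", "F2", "F1", FALSE, 1)
    pt[[length(pt) + 1]] <- pt_row("beta", "F2", "D", FALSE, 1)
    pt[[length(pt) + 1]] <- pt_row("psi", "F2", "F2", FALSE, 0)
    std_total <- "F1"
  }

  sem_spec(vars, factors, dplyr::bind_rows(pt), std_total = std_total,
           theta_std_vars = theta_std)
}
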