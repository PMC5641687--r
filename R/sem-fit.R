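# Diagonally weighted least squares estimation of threshold-structure
# models, with mean- and variance-adjusted test statistics.
#
# The discrepancy is F(theta) = sum_k w_k (s_k - sigma_k(theta))^2 with
# s the stacked standardised thresholds and polychoric correlations and
# w_k = 1/avar_k the inverse asymptotic variances from the first stage.
# T_raw = F at the minimum.  With U = W - W J H^{-1} J' W (J the Jacobian
# of sigma, H = J'WJ) and Gamma = diag(avar), the adjustment constants are
# a = tr(U Gamma) and b = tr((U Gamma)^2); the reported statistic is the
# scaled-and-shifted  T = sqrt(df/b) (T_raw - a) + df  on the model df, and
# the mean-scaled variant T_raw/(a/df) is kept alongside.  Standard errors
# are sqrt(diag(H^{-1})), the sandwich form under the working assumption
# Gamma = W^{-1} (diagonal weight information only).

assemble_stats <- function(spec, pm) {
  vars <- spec$vars$var
  missing <- setdiff(vars, colnames(pm$rho))
  if (length(missing) > 0) {
    stop("statistics missing for variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  s_tau <- c(); a_tau <- c()
  for (j in seq_along(vars)) {
    nc <- spec$vars$n_cat[j]
    if (nc < 2) next
    tj <- pm$thresholds[[vars[j]]]
    if (is.null(tj) || length(tj) != nc - 1) {
      stop("threshold count mismatch for ", vars[j], call. = FALSE)
    }
    s_tau <- c(s_tau, tj)
    a_tau <- c(a_tau, pm$tau_avar[[vars[j]]])
  }
  pairs <- stat_pairs(length(vars))
  i1 <- match(vars[pairs[, 1]], colnames(pm$rho))
  i2 <- match(vars[pairs[, 2]], colnames(pm$rho))
  s_rho <- pm$rho[cbind(i1, i2)]
  a_rho <- pm$avar[cbind(i1, i2)]
  # full asymptotic covariance of the statistics from influence values
  Gamma <- NULL
  if (!is.null(pm$influence)) {
    tau_cols <- character()
    for (j in seq_along(vars)) {
      nc <- spec$vars$n_cat[j]
      if (nc < 2) next
      tau_cols <- c(tau_cols, paste0("tau_", vars[j], "_", seq_len(nc - 1)))
    }
    av <- colnames(pm$rho)
    rho_cols <- ifelse(match(vars[pairs[, 1]], av) <
                         match(vars[pairs[, 2]], av),
                       paste0("rho_", vars[pairs[, 1]], ".",
                              vars[pairs[, 2]]),
                       paste0("rho_", vars[pairs[, 2]], ".",
                              vars[pairs[, 1]]))
    cols <- c(tau_cols, rho_cols)
    if (all(cols %in% colnames(pm$influence))) {
      IF <- pm$influence[, cols, drop = FALSE]
      IFc <- sweep(IF, 2, colMeans(IF))
      Gamma <- crossprod(IFc) / nrow(IF)^2
    }
  }
  list(s = c(s_tau, s_rho), avar = c(a_tau, a_rho),
       n_tau = length(s_tau), n_rho = length(s_rho), Gamma = Gamma)
}

num_jacobian <- function(fn, th, eps = 1e-5) {
  f0 <- fn(th)
  J <- matrix(0, length(f0), length(th))
  for (j in seq_along(th)) {
    h <- eps * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

#' Fit a model by diagonally weighted least squares
#'
#' Minimises the inverse-asymptotic-variance weighted discrepancy between
#' model-implied and estimated thresholds/correlations.  Optimisation is
#' damped Gauss-Newton from the supplied or default starting values, with a
#' quasi-Newton (BFGS) fallback and up to three jittered restarts on
#' non-convergence (gradient norm criterion 1e-6 on the per-observation
#' discrepancy scale).  Residual variances forced below zero by the
#' optimiser (Heywood cases) are floored at 1e-4 and flagged.
#'
#' @param spec a [sem_spec()].
#' @param pm a [polychoric_matrix()] holding the first-stage statistics.
#' @param n sample size for test statistics; defaults to the analytic-sample
#'   (median pairwise) n recorded in `pm`.
#' @param start optional named starting values.
#' @param compute_chi2 set `FALSE` to skip the adjustment constants (used
#'   inside Monte Carlo loops that only need the Wald test).
#' @return object of class `sem_fit`.
#' @export
fit_dwls <- function(spec, pm, n = NULL, start = NULL, compute_chi2 = TRUE) {
  check_identification(spec)
  comp <- compile_spec(spec)
  st <- assemble_stats(spec, pm)
  if (is.null(n)) n <- pm$n
  s <- st$s; w <- 1 / st$avar
  q <- length(s); pfree <- length(comp$labels)

  th0 <- start_values(spec)
  if (!is.null(start)) th0[names(start)] <- start
  # data-informed threshold starts (average over equality-constrained slots)
  pt <- spec$partable
  tau_rows <- which(pt$mat == "tau" & pt$free)
  if (length(tau_rows) > 0) {
    key_stat <- paste(spec$vars$var[comp$tau_stat_var], comp$tau_stat_idx)
    for (lb in unique(pt$label[tau_rows])) {
      rows <- tau_rows[pt$label[tau_rows] == lb]
      ks <- paste(pt$row[rows], pt$col[rows])
      vals <- s[match(ks, key_stat)]
      if (all(is.finite(vals))) th0[lb] <- mean(vals)
    }
  }

  fn <- function(th) {
    sig <- comp$implied(th)
    sum(w * (s - sig)^2) / n
  }
  grad <- function(th) {
    J <- num_jacobian(comp$implied, th)
    r <- s - comp$implied(th)
    as.vector(-2 * crossprod(J, w * r)) / n
  }

  gauss_newton <- function(th) {
    conv <- FALSE; gnorm <- Inf
    f_cur <- fn(th)
    for (it in seq_len(60)) {
      J <- num_jacobian(comp$implied, th)
      r <- s - comp$implied(th)
      g <- -2 * as.vector(crossprod(J, w * r)) / n
      gnorm <- sqrt(sum(g^2))
      if (!is.finite(gnorm)) break
      if (gnorm < 1e-6) { conv <- TRUE; break }
      H <- crossprod(J * sqrt(w))
      step <- tryCatch(solve(H + diag(1e-9, pfree),
                             as.vector(crossprod(J, w * r))),
                       error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1; improved <- FALSE
      for (hh in seq_len(12)) {
        f_new <- fn(th + lam * step)
        if (is.finite(f_new) && f_new <= f_cur + 1e-12) {
          th <- th + lam * step; f_cur <- f_new; improved <- TRUE; break
        }
        lam <- lam / 2
      }
      if (!improved) break
    }
    list(th = th, f = f_cur, converged = conv, gnorm = gnorm)
  }

  run <- gauss_newton(th0)
  attempt <- 0
  while (!run$converged && attempt < 3) {
    attempt <- attempt + 1
    jit <- if (attempt == 1) th0 else
      th0 + stats::rnorm(pfree, 0, 0.1 * attempt)
    opt <- tryCatch(
      optim(jit, fn, grad, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    cand <- gauss_newton(opt$par)
    if (cand$converged || cand$f < run$f) run <- cand
    if (run$converged) break
  }
  th <- run$th

  det <- comp$implied(th, detail = TRUE)
  J <- num_jacobian(comp$implied, th)
  r <- s - det$stats
  H <- crossprod(J * sqrt(w))
  Hinv <- tryCatch(solve(H), error = function(e) {
    solve(H + diag(1e-8, pfree))
  })
  WJ <- J * w
  # sandwich covariance with the full first-stage covariance Gamma;
  # falls back to the diagonal working form Gamma = W^{-1} when influence
  # values are unavailable
  V <- if (!is.null(st$Gamma)) {
    Hinv %*% crossprod(WJ, st$Gamma %*% WJ) %*% Hinv
  } else {
    Hinv
  }
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(th) <- comp$labels
  T_raw <- sum(w * r^2)
  df <- q - pfree

  a <- b <- chi2 <- chi2_scaled <- NA_real_
  baseline <- NULL
  if (compute_chi2) {
    if (df > 0) {
      U <- diag(w) - WJ %*% Hinv %*% t(WJ)
      UG <- if (!is.null(st$Gamma)) U %*% st$Gamma else
        sweep(U, 2, st$avar, "*")
      a <- sum(diag(UG))
      b <- sum(UG * t(UG))
      chi2_scaled <- T_raw / (a / df)
      chi2 <- sqrt(df / b) * (T_raw - a) + df
      chi2 <- max(chi2, 0)
    } else {
      chi2 <- chi2_scaled <- 0; a <- 0; b <- 0
    }
    # independence baseline: saturated thresholds, zero correlations
    rho_idx <- st$n_tau + seq_len(st$n_rho)
    T_b <- sum(w[rho_idx] * s[rho_idx]^2)
    df_b <- st$n_rho
    if (!is.null(st$Gamma)) {
      WG_b <- st$Gamma[rho_idx, rho_idx, drop = FALSE] * w[rho_idx]
      a_b <- sum(diag(WG_b))
      b_b <- sum(WG_b * t(WG_b))
      T_b <- max(0, sqrt(df_b / b_b) * (T_b - a_b) + df_b)
    }
    baseline <- list(chi2 = T_b, df = df_b)
  }

  fi <- if (compute_chi2 && df > 0) {
    fit_indices(chi2, df, n, baseline$chi2, baseline$df)
  } else list(rmsea = NA_real_, cfi = NA_real_, tli = NA_real_,
              tli_gt1 = NA)

  structure(list(
    estimates = th, se = se, spec = spec, n = n,
    chi2 = chi2, chi2_scaled = chi2_scaled, chi2_raw = T_raw, df = df,
    scale_factors = c(a = a, b = b),
    baseline = baseline,
    rmsea = fi$rmsea, cfi = fi$cfi, tli = fi$tli, tli_gt1 = fi$tli_gt1,
    converged = run$converged, grad_norm = run$gnorm,
    heywood = det$heywood,
    implied = det, sample_stats = st, acov = V),
    class = "sem_fit")
}

#' Global fit indices from chi-square statistics
#'
#' `rmsea = sqrt(max(0, (chi2 - df) / (df (n - 1))))`;
#' `cfi = 1 - max(0, chi2 - df) / max(0, chi2_b - df_b, chi2 - df)`;
#' `tli = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)`.
#' TLI is reported untruncated with a flag when it exceeds 1.
#'
#' @param chi2,df model test statistic and degrees of freedom (`df > 0`).
#' @param n sample size.
#' @param baseline_chi2,baseline_df independence-baseline statistic and df.
#' @return list with `rmsea`, `cfi`, `tli`, `tli_gt1`.
#' @examples
#' fit_indices(808.683, 303, 1160, 5000, 325)$rmsea  # 0.038 to 3 dp
#' @export
fit_indices <- function(chi2, df, n, baseline_chi2 = NA, baseline_df = NA) {
  if (df <= 0) stop("fit indices undefined at df = 0", call. = FALSE)
  rmsea <- sqrt(max(0, (chi2 - df) / (df * (n - 1))))
  cfi <- tli <- NA_real_
  if (is.finite(baseline_chi2) && is.finite(baseline_df) && baseline_df > 0) {
    cfi <- 1 - max(0, chi2 - df) /
      max(0, baseline_chi2 - baseline_df, chi2 - df)
    rb <- baseline_chi2 / baseline_df
    tli <- (rb - chi2 / df) / (rb - 1)
  }
  list(rmsea = rmsea, cfi = cfi, tli = tli,
       tli_gt1 = is.finite(tli) && tli > 1)
}

#' Scaled chi-square difference test for nested DWLS fits
#'
#' Satorra-Bentler-type difference of the raw discrepancy statistics,
#' rescaled by the difference of the trace adjustment constants:
#' `c_d = (a_r - a_f) / (df_r - df_f)`, `stat = (T_r - T_f)/c_d`.
#'
#' @param restricted,free `sem_fit` objects on the same sample statistics,
#'   the restricted model nested in the free one.
#' @return list with `stat`, `df`, `p`, `scale`.
#' @export
chi2_diff_test <- function(restricted, free) {
  if (length(restricted$sample_stats$s) != length(free$sample_stats$s) ||
      max(abs(restricted$sample_stats$s - free$sample_stats$s)) > 1e-12) {
    stop("nesting error: the two fits use different sample statistics",
         call. = FALSE)
  }
  df_diff <- restricted$df - free$df
  if (df_diff < 0) {
    stop("nesting error: restricted model has fewer degrees of freedom ",
         "than the free model", call. = FALSE)
  }
  if (df_diff == 0) {
    return(list(stat = 0, df = 0L, p = 1, scale = 1))
  }
  cd <- (restricted$scale_factors[["a"]] - free$scale_factors[["a"]]) /
    df_diff
  if (!is.finite(cd) || cd <= 0) {
    cd <- restricted$scale_factors[["a"]] / restricted$df
  }
  stat <- max(0, (restricted$chi2_raw - free$chi2_raw) / cd)
  list(stat = stat, df = as.integer(df_diff),
       p = pchisq(stat, df_diff, lower.tail = FALSE), scale = cd)
}

param_value <- function(fit, mat, row, col) {
  pt <- fit$spec$partable
  i <- which(pt$mat == mat & pt$row == row & pt$col == as.character(col))
  if (length(i) == 0) return(0)
  if (pt$free[i[1]]) fit$estimates[[pt$label[i[1]]]] else pt$value[i[1]]
}

#' Standardised coefficients of a fitted model
#'
#' Rescales loadings and regressions by the implied latent and liability
#' standard deviations.  For regression coefficients a delta-method standard
#' error propagated through the implied covariance structure is included.
#'
#' @param fit a `sem_fit`.
#' @return tibble with `type`, `lhs`, `rhs`, `est_std`, `se_std` (regressions
#'   only).
#' @export
standardize <- function(fit) {
  if (!fit$converged) stop("cannot standardise a non-converged fit",
                           call. = FALSE)
  spec <- fit$spec
  pt <- spec$partable
  det <- fit$implied
  fac <- spec$factors
  sdF <- sqrt(diag(det$Phi))
  if (any(sdF <= 0)) stop("zero implied factor variance", call. = FALSE)
  sdv <- det$sd
  out <- list()
  for (i in which(pt$mat == "lambda")) {
    vi <- match(pt$row[i], spec$vars$var); fj <- match(pt$col[i], fac)
    est <- if (pt$free[i]) fit$estimates[[pt$label[i]]] else pt$value[i]
    out[[length(out) + 1]] <- tibble::tibble(
      type = "loading", lhs = pt$row[i], rhs = pt$col[i],
      est_std = est * sdF[fj] / sdv[vi], se_std = NA_real_)
  }
  for (i in which(pt$mat == "beta")) {
    fo <- match(pt$row[i], fac); fp <- match(pt$col[i], fac)
    est <- if (pt$free[i]) fit$estimates[[pt$label[i]]] else pt$value[i]
    se <- if (pt$free[i]) {
      std_coef_se(fit, pt$row[i], pt$col[i])
    } else NA_real_
    out[[length(out) + 1]] <- tibble::tibble(
      type = "regression", lhs = pt$row[i], rhs = pt$col[i],
      est_std = est * sdF[fp] / sdF[fo], se_std = se)
  }
  dplyr::bind_rows(out)
}

# delta-method SE of a standardised regression coefficient
std_coef_se <- function(fit, outcome, predictor) {
  comp <- compile_spec(fit$spec)
  fac <- fit$spec$factors
  fo <- match(outcome, fac); fp <- match(predictor, fac)
  pt <- fit$spec$partable
  i <- which(pt$mat == "beta" & pt$row == outcome &
               pt$col == as.character(predictor) & pt$free)
  if (length(i) == 0) return(NA_real_)
  lab <- pt$label[i[1]]
  f <- function(th) {
    d <- comp$implied(th, detail = TRUE)
    th[[lab]] * sqrt(d$Phi[fp, fp] / d$Phi[fo, fo])
  }
  th <- fit$estimates
  g <- numeric(length(th))
  for (j in seq_along(th)) {
    h <- 1e-5 * max(1, abs(th[j]))
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    g[j] <- (f(tp) - f(tm)) / (2 * h)
  }
  sqrt(max(0, as.numeric(t(g) %*% fit$acov %*% g)))
}

#' Standardised regression coefficient with Wald inference
#'
#' @param fit a `sem_fit`.
#' @param outcome,predictor factor names of the regression.
#' @return one-row tibble with `std_beta`, `se`, `ci_low`, `ci_high`, `p`
#'   (two-sided Wald, 95% interval).
#' @export
std_coef <- function(fit, outcome, predictor) {
  det <- fit$implied
  fac <- fit$spec$factors
  fo <- match(outcome, fac); fp <- match(predictor, fac)
  est <- param_value(fit, "beta", outcome, predictor) *
    sqrt(det$Phi[fp, fp] / det$Phi[fo, fo])
  se <- std_coef_se(fit, outcome, predictor)
  z <- est / se
  tibble::tibble(std_beta = est, se = se,
                 ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                 p = 2 * pnorm(-abs(z)))
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("DWLS fit: chi2(%d) = %.3f, RMSEA = %.3f, CFI = %.3f, TLI = %.3f (n = %d)%s\n",
              x$df, x$chi2, x$rmsea, x$cfi, x$tli, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
#' @exportS3Method generics::tidy
tidy.sem_fit <- function(x, ...) {
  z <- x$estimates / x$se
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates),
                 std.error = unname(x$se), statistic = unname(z),
                 p.value = unname(2 * pnorm(-abs(z))))
}

#' @importFrom generics glance
#' @export
#' @exportS3Method generics::glance
glance.sem_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, rmsea = x$rmsea, cfi = x$cfi,
                 tli = x$tli, n = x$n, converged = x$converged,
                 heywood = x$heywood)
}
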