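# Declarative specification of threshold-structure factor/structural models.
#
# A model is a parameter table over matrices
#   lambda  : loading (var x factor)
#   tau     : threshold (var, index)
#   theta_d : residual variance (var); theta parameterisation fixes these at 1
#   theta_o : residual covariance (var pair), e.g. cross-wave repeated items
#   psi     : factor (residual) variance/covariance
#   beta    : regression (outcome factor on predictor factor)
#   alpha   : factor intercept (latent mean)
# Equality constraints are expressed by sharing a label; `free = FALSE` rows
# are fixed at `value`.  Two convenience devices:
#   * `std_total` factors get residual variance 1 - explained variance, so
#     their total variance is 1 and regressions on them are standardised;
#   * `theta_std_vars` get residual variance 1 - explained liability
#     variance (delta parameterisation), used for the SNP indicators of the
#     genetic factor where no cross-wave residual constraints are needed.

pt_row <- function(mat, row, col = "", free = TRUE, value = NA_real_,
                   label = "") {
  tibble::tibble(mat = mat, row = row, col = as.character(col),
                 free = free, value = value, label = label)
}

#' Construct a SEM model specification
#'
#' @param vars tibble with columns `var` (observed variable name, in the
#'   order statistics are assembled) and `n_cat` (number of ordered
#'   categories; 0 marks a standardised continuous predictor).
#' @param factors character vector of latent variable names in causal order
#'   (predictors before outcomes).
#' @param partable tibble of parameter rows (see [pt_row()]).
#' @param std_total factors whose residual variance is set to
#'   `1 - explained` so that their total variance is 1.
#' @param theta_std_vars observed variables whose residual variance is set
#'   to `1 - explained liability variance` (delta parameterisation).
#' @return object of class `sem_spec`.
#' @keywords internal
#' @export
sem_spec <- function(vars, factors, partable, std_total = character(),
                     theta_std_vars = character()) {
  spec <- structure(list(vars = vars, factors = factors, partable = partable,
                         std_total = std_total,
                         theta_std_vars = theta_std_vars),
                    class = "sem_spec")
  spec$n_stats <- n_statistics(spec)
  spec$free_labels <- unique(partable$label[partable$free])
  spec$df <- spec$n_stats - length(spec$free_labels)
  spec
}

n_statistics <- function(spec) {
  ncat <- spec$vars$n_cat
  sum(pmax(ncat - 1, 0)) + choose(nrow(spec$vars), 2)
}

#' Identification bookkeeping for a model specification
#'
#' Checks that the degrees of freedom (number of first-stage statistics
#' minus free parameters) are non-negative and that every factor's scale is
#' set, and warns when a factor has fewer than three indicators.
#'
#' @param spec a `sem_spec`.
#' @return list with `n_stats`, `n_free`, `df`, invisibly; errors if the
#'   model is under-identified by counting.
#' @export
check_identification <- function(spec) {
  pt <- spec$partable
  n_free <- length(spec$free_labels)
  df <- spec$n_stats - n_free
  if (df < 0) {
    stop("identification error: ", n_free, " free parameters exceed ",
         spec$n_stats, " sample statistics", call. = FALSE)
  }
  lam <- pt[pt$mat == "lambda", ]
  for (f in spec$factors) {
    own <- lam$label[lam$col == f & lam$free]
    # equality of a loading with another factor's loading also sets the scale
    shared <- any(own %in% lam$label[lam$col != f & lam$free])
    scaled <- f %in% spec$std_total ||
      any(pt$mat == "psi" & pt$row == f & pt$col == f & !pt$free) ||
      any(pt$mat == "lambda" & pt$col == f & !pt$free & pt$value != 0) ||
      any(pt$mat == "beta" & pt$row == f & !pt$free) ||
      # a phantom factor (no indicators) sending a fixed non-zero path is
      # scaled through its recipient (latent difference construction)
      any(pt$mat == "beta" & pt$col == f & !pt$free & pt$value != 0) ||
      shared
    if (!scaled) {
      stop("identification error: no scale set for factor ", f,
           call. = FALSE)
    }
    n_ind <- sum(pt$mat == "lambda" & pt$col == f & pt$free)
    if (n_ind > 0 && n_ind < 3) {
      warning("factor ", f, " has fewer than 3 indicators; identification ",
              "relies on the surrounding model", call. = FALSE)
    }
  }
  invisible(list(n_stats = spec$n_stats, n_free = n_free, df = df))
}

# Pair ordering of the correlation statistics: (1,2), (1,3), ..., (p-1,p)
stat_pairs <- function(p) {
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Compile a spec into a fast implied-statistics function.
compile_spec <- function(spec) {
  vars <- spec$vars$var
  ncat <- spec$vars$n_cat
  p <- length(vars); m <- length(spec$factors)
  fac <- spec$factors
  pt <- spec$partable
  labels <- spec$free_labels
  labidx <- match(pt$label, labels)

  vi <- function(v) match(v, vars)
  fi <- function(f) match(f, fac)

  # templates
  Lam <- matrix(0, p, m); Th <- matrix(0, p, p)
  Psi <- matrix(0, m, m); B <- matrix(0, m, m); Al <- rep(0, m)
  tau_slots <- list()
  for (j in seq_len(p)) {
    if (ncat[j] >= 2) tau_slots[[vars[j]]] <- rep(NA_real_, ncat[j] - 1)
  }

  sel <- function(mm) which(pt$mat == mm)
  mk <- function(rows, pos_fun) {
    list(pos = vapply(rows, pos_fun, numeric(1)),
         free = pt$free[rows], value = pt$value[rows],
         lab = labidx[rows])
  }
  iL <- mk(sel("lambda"), function(r) vi(pt$row[r]) + (fi(pt$col[r]) - 1) * p)
  iT <- mk(sel("theta_d"), function(r) vi(pt$row[r]) + (vi(pt$row[r]) - 1) * p)
  iTo <- sel("theta_o")
  iTo_pos1 <- vapply(iTo, function(r) vi(pt$row[r]) + (vi(pt$col[r]) - 1) * p,
                     numeric(1))
  iTo_pos2 <- vapply(iTo, function(r) vi(pt$col[r]) + (vi(pt$row[r]) - 1) * p,
                     numeric(1))
  iTo_free <- pt$free[iTo]; iTo_val <- pt$value[iTo]; iTo_lab <- labidx[iTo]
  iP <- sel("psi")
  iP_pos1 <- vapply(iP, function(r) fi(pt$row[r]) + (fi(pt$col[r]) - 1) * m,
                    numeric(1))
  iP_pos2 <- vapply(iP, function(r) fi(pt$col[r]) + (fi(pt$row[r]) - 1) * m,
                    numeric(1))
  iP_free <- pt$free[iP]; iP_val <- pt$value[iP]; iP_lab <- labidx[iP]
  iB <- mk(sel("beta"), function(r) fi(pt$row[r]) + (fi(pt$col[r]) - 1) * m)
  iA <- mk(sel("alpha"), function(r) fi(pt$row[r]))
  tau_rows <- sel("tau")
  tau_var <- match(pt$row[tau_rows], vars)
  tau_idx <- as.integer(pt$col[tau_rows])
  tau_free <- pt$free[tau_rows]; tau_val <- pt$value[tau_rows]
  tau_lab <- labidx[tau_rows]

  std_tot <- match(spec$std_total, fac)
  th_std <- match(intersect(spec$theta_std_vars, vars), vars)
  has_beta <- length(iB$pos) > 0
  pairs <- stat_pairs(p)
  cat_vars <- which(ncat >= 2)
  # threshold stat layout: per categorical var in order, idx ascending
  tau_stat_var <- rep(cat_vars, times = pmax(ncat[cat_vars] - 1, 0))
  tau_stat_idx <- unlist(lapply(cat_vars, function(j) seq_len(ncat[j] - 1)),
                         use.names = FALSE)
  n_tau <- length(tau_stat_var)

  fill <- function(M, ix, th) {
    v <- ix$value
    if (any(ix$free)) v[ix$free] <- th[ix$lab[ix$free]]
    M[ix$pos] <- v
    M
  }

  implied <- function(th, detail = FALSE) {
    Lamc <- fill(Lam, iL, th)
    Thc <- fill(Th, iT, th)
    if (length(iTo_pos1)) {
      v <- iTo_val; if (any(iTo_free)) v[iTo_free] <- th[iTo_lab[iTo_free]]
      Thc[iTo_pos1] <- v; Thc[iTo_pos2] <- v
    }
    Psic <- Psi
    if (length(iP_pos1)) {
      v <- iP_val; if (any(iP_free)) v[iP_free] <- th[iP_lab[iP_free]]
      Psic[iP_pos1] <- v; Psic[iP_pos2] <- v
    }
    Bc <- if (has_beta) fill(B, iB, th) else B
    Alc <- fill_vec(Al, iA, th)
    heywood <- FALSE

    # latent covariance / means, processing factors in causal order
    Phi <- matrix(0, m, m); mu_f <- numeric(m)
    for (f in seq_len(m)) {
      preds <- if (has_beta) which(Bc[f, ] != 0) else integer(0)
      if (length(preds) == 0) {
        Phi[f, f] <- if (f %in% std_tot) 1 else Psic[f, f]
        if (f > 1) {
          Phi[f, seq_len(f - 1)] <- Phi[seq_len(f - 1), f] <-
            Psic[f, seq_len(f - 1)]
        }
        mu_f[f] <- Alc[f]
      } else {
        b <- Bc[f, preds]
        expl <- sum(b * (Phi[preds, preds, drop = FALSE] %*% b))
        psff <- if (f %in% std_tot) 1 - expl else Psic[f, f]
        if (psff < 0) {
          heywood <- TRUE
          # std_total keeps the unit total smoothly (residual may be
          # negative during optimisation); free variances are floored
          if (!(f %in% std_tot)) psff <- 1e-4
        }
        if (f > 1) {
          g <- seq_len(f - 1)
          cv <- as.vector(b %*% Phi[preds, g, drop = FALSE]) + Psic[f, g]
          Phi[f, g] <- Phi[g, f] <- cv
        }
        Phi[f, f] <- expl + psff
        mu_f[f] <- sum(b * mu_f[preds]) + Alc[f]
      }
    }

    LP <- Lamc %*% Phi
    Sig <- LP %*% t(Lamc) + Thc
    # residual-variance conventions
    d <- diag(Sig)
    if (length(th_std)) {
      # delta parameterisation: total liability variance is 1 by
      # construction; a communality above 1 is flagged but not clipped,
      # keeping the objective smooth near the boundary
      comm <- rowSums(LP[th_std, , drop = FALSE] * Lamc[th_std, , drop = FALSE])
      if (any(comm > 1)) heywood <- TRUE
      d[th_std] <- 1
      Sig[cbind(th_std, th_std)] <- 1
    }
    if (any(d <= 0)) { d[d <= 0] <- 1e-4; heywood <- TRUE }
    sdv <- sqrt(d)
    mu <- as.vector(Lamc %*% mu_f)

    tauc <- rep(NA_real_, length(tau_var))
    v <- tau_val; if (any(tau_free)) v[tau_free] <- th[tau_lab[tau_free]]
    tauc <- v
    # map parameter rows onto stat layout
    tau_out <- numeric(n_tau)
    key_stat <- tau_stat_var * 10 + tau_stat_idx
    key_par <- tau_var * 10 + tau_idx
    tau_out <- tauc[match(key_stat, key_par)]
    tau_std <- (tau_out - mu[tau_stat_var]) / sdv[tau_stat_var]

    rho <- Sig[pairs] / (sdv[pairs[, 1]] * sdv[pairs[, 2]])
    if (detail) {
      list(stats = c(tau_std, rho), Phi = Phi, mu_f = mu_f, Sigma = Sig,
           sd = sdv, Lambda = Lamc, heywood = heywood)
    } else {
      c(tau_std, rho)
    }
  }

  list(implied = implied, labels = labels, p = p, pairs = pairs,
       n_tau = n_tau, tau_stat_var = tau_stat_var,
       tau_stat_idx = tau_stat_idx, cat_vars = cat_vars)
}

fill_vec <- function(v0, ix, th) {
  v <- ix$value
  if (any(ix$free)) v[ix$free] <- th[ix$lab[ix$free]]
  v0[ix$pos] <- v
  v0
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf("SEM spec: %d observed variables, %d factors, %d statistics, %d free parameters (df = %d)\n",
              nrow(x$vars), length(x$factors), x$n_stats,
              length(x$free_labels), x$df))
  invisible(x)
}

# starting values: `value` column for free rows, with sensible defaults
start_values <- function(spec, sample_tau = NULL) {
  pt <- spec$partable
  th <- stats::setNames(rep(NA_real_, length(spec$free_labels)),
                        spec$free_labels)
  for (i in which(pt$free)) {
    if (is.na(th[pt$label[i]]) && !is.na(pt$value[i])) {
      th[pt$label[i]] <- pt$value[i]
    }
  }
  defaults <- c(lambda = 0.7, tau = 0, theta_d = 1, theta_o = 0.1,
                psi = 0.5, beta = 0, alpha = 0)
  for (i in which(pt$free)) {
    if (is.na(th[pt$label[i]])) th[pt$label[i]] <- defaults[[pt$mat[i]]]
  }
  th
}
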