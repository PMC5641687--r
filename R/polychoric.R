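#' Normal-scale thresholds from category proportions
#'
#' Maps the marginal distribution of an ordinal variable to strictly
#' increasing thresholds on the standard-normal liability scale:
#' `tau_j = qnorm(P(category <= j))` for `j = 1, ..., K-1`.  Binary items and
#' hemizygous (male) SNP dosages get one threshold; three-category (female)
#' SNP dosages get two.
#'
#' @param p numeric vector of category proportions, strictly positive and
#'   summing to 1 (a tolerance of 1e-8 is allowed).
#' @return numeric vector of `length(p) - 1` thresholds.
#' @examples
#' estimate_thresholds(c(0.694, 0.306))     # ~ 0.507
#' estimate_thresholds(c(0.49, 0.39, 0.12)) # two thresholds
#' @export
estimate_thresholds <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("category proportions must be finite and non-negative", call. = FALSE)
  }
  if (any(p == 0)) {
    stop("zero-count category: collapse adjacent categories before ",
         "threshold estimation", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop("category proportions must sum to 1", call. = FALSE)
  }
  qnorm(cumsum(p)[-length(p)])
}

# thresholds + proportions from an observed integer-coded column (0-based or
# factor-like); returns list(tau, p, n)
thresholds_from_column <- function(x) {
  x <- x[!is.na(x)]
  lev <- sort(unique(x))
  if (length(lev) < 2) {
    stop("variable has a single observed category", call. = FALSE)
  }
  cnt <- as.numeric(table(factor(x, levels = lev)))
  p <- cnt / sum(cnt)
  list(tau = estimate_thresholds(p), p = p, n = length(x), levels = lev)
}

# Sandwich asymptotic variance of the two-stage polychoric estimator.
# The estimator is a Z-estimator with moment equations for the thresholds
# (matching cumulative margins) and the profile likelihood score for rho;
# avar comes from A^{-1} B A^{-T} / n with numeric derivatives of the
# bivariate-normal cell probabilities.  The per-cell influence values of
# rho-hat (row 1 of A^{-1} psi) are returned as well; they are the basis of
# the full asymptotic covariance matrix of all pairwise estimates.
polychoric_avar <- function(tab, a, b, rho) {
  n <- sum(tab)
  R <- nrow(tab); C <- ncol(tab)
  npar <- 1L + (R - 1L) + (C - 1L)
  eps <- 1e-5
  cellp <- function(rho., a., b.) bvn_cell_probs(a., b., rho.)
  P <- cellp(rho, a, b)
  dP <- vector("list", npar)
  shift <- function(k, d) {
    r2 <- rho; a2 <- a; b2 <- b
    if (k == 1) r2 <- r2 + d
    else if (k <= R) a2[k - 1] <- a2[k - 1] + d
    else b2[k - R] <- b2[k - R] + d
    cellp(r2, a2, b2)
  }
  for (k in seq_len(npar)) {
    dP[[k]] <- (shift(k, eps) - shift(k, -eps)) / (2 * eps)
  }
  # estimating functions evaluated per cell
  psi <- matrix(0, R * C, npar)
  psi[, 1] <- as.vector(dP[[1]] / P)
  for (r in seq_len(R - 1)) {
    Fr <- sum(P[seq_len(r), ])
    psi[, 1 + r] <- as.vector(matrix(rep(as.numeric(seq_len(R) <= r), C),
                                     R, C)) - Fr
  }
  for (cc in seq_len(C - 1)) {
    Fc <- sum(P[, seq_len(cc)])
    psi[, R + cc] <- as.vector(matrix(rep(as.numeric(seq_len(C) <= cc),
                                          each = R), R, C)) - Fc
  }
  w <- as.vector(P)
  B <- crossprod(psi * sqrt(w))
  A <- matrix(0, npar, npar)
  for (k in seq_len(npar)) {
    A[1, k] <- sum(dP[[1]] * dP[[k]] / P)  # information identity row for rho
  }
  for (r in seq_len(R - 1)) A[1 + r, 1 + r] <- dnorm(a[r])
  for (cc in seq_len(C - 1)) A[R + cc, R + cc] <- dnorm(b[cc])
  res <- tryCatch({
    Ainv <- solve(A)
    list(avar = (Ainv %*% B %*% t(Ainv))[1, 1] / n,
         cell_if = matrix(as.vector(psi %*% Ainv[1, ]), R, C))
  }, error = function(e) NULL)
  if (is.null(res) || !is.finite(res$avar) || res$avar <= 0) {
    res <- list(avar = (1 - rho^2)^2 / n, cell_if = matrix(0, R, C))
  }
  res
}

# core two-stage ML for an R x C table; returns rho, se, avar, thresholds
polychoric_table <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  n <- sum(tab)
  a <- estimate_thresholds(rowSums(tab) / n)
  b <- estimate_thresholds(colSums(tab) / n)
  opt <- optimize(function(r) bvn_table_loglik(tab, a, b, r),
                  interval = c(-0.999, 0.999), maximum = TRUE, tol = 1e-9)
  rho <- opt$maximum
  boundary <- FALSE
  if (abs(rho) > 0.9985 || any(tab == 0)) {
    # empty cells push the MLE to the boundary; report the clipped estimate
    ll_hi <- bvn_table_loglik(tab, a, b, 0.999)
    ll_lo <- bvn_table_loglik(tab, a, b, -0.999)
    if (max(ll_hi, ll_lo) > opt$objective) {
      rho <- if (ll_hi >= ll_lo) 0.999 else -0.999
    }
    if (abs(rho) > 0.9985) boundary <- TRUE
  }
  av <- polychoric_avar(tab, a, b, rho)
  list(rho = rho, se = sqrt(av$avar), avar = av$avar, row_tau = a,
       col_tau = b, n = n, boundary = boundary, cell_if = av$cell_if)
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Two-stage maximum likelihood: thresholds from the margins, then the
#' correlation of the underlying bivariate-normal liabilities by
#' one-dimensional likelihood maximisation.  The standard error comes from a
#' sandwich (Z-estimator) formula that accounts for first-stage threshold
#' estimation.
#'
#' @param tab 2x2 matrix of counts; rows and columns ordered low, high.
#' @return list with `rho`, `se`, `avar`, `row_tau`, `col_tau`, `n` and a
#'   `boundary` flag (`TRUE` when an empty cell drives the estimate to the
#'   +/-0.999 clipping bound).
#' @examples
#' tetrachoric(matrix(c(40, 10, 10, 40), 2, 2))
#' @export
tetrachoric <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tetrachoric() needs a 2x2 table",
                                      call. = FALSE)
  polychoric_table(tab)
}

#' Polychoric correlation of an R x C table
#'
#' Generalises [tetrachoric()] to ordinal variables with more than two
#' categories (here: three-category female SNP dosages).  A 2x2 input
#' reduces exactly to the tetrachoric estimate.
#'
#' @param tab matrix of counts with ordered rows and columns.
#' @return same structure as [tetrachoric()].
#' @export
polychoric_pair <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("polychoric_pair() needs at least 2 categories per margin",
         call. = FALSE)
  }
  polychoric_table(tab)
}

# Two-step polyserial-type correlation between an (approximately
# standardised) observed numeric predictor and an ordinal variable:
# rho = r_pearson * sd(y) / sum(dnorm(tau)).  First-order consistent for the
# liability-scale correlation; used for observed-dosage and group predictors.
polyserial_approx <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  th <- thresholds_from_column(y)
  yx <- match(y, th$levels) - 1
  r <- suppressWarnings(cor(x, yx))
  if (!is.finite(r)) r <- 0
  sdy <- sqrt(mean((yx - mean(yx))^2))
  scal <- sdy / sum(dnorm(th$tau))
  rho <- max(-0.999, min(0.999, r * scal))
  n <- length(x)
  avar <- scal^2 * (1 - rho^2)^2 / n
  # influence of the dominant (Pearson) component, per complete case
  xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  ys <- (yx - mean(yx)) / sdy
  if_vals <- scal * (xs * ys - r / 2 * (xs^2 + ys^2))
  list(rho = rho, se = sqrt(avar), avar = avar, n = n,
       boundary = abs(rho) > 0.9985, if_vals = if_vals)
}

#' Pairwise polychoric correlation matrix with asymptotic variances
#'
#' Assembles the first-stage statistics for the DWLS model fitting engine:
#' thresholds per variable, pairwise-complete polychoric/tetrachoric
#' correlations, and the asymptotic variance of every estimate.  Columns
#' listed in `continuous` are treated as standardised observed predictors
#' (no thresholds; correlations with ordinal columns use a two-step
#' polyserial approximation).
#'
#' An indefinite raw matrix is smoothed by clipping eigenvalues at 1e-6 and
#' rescaling to unit diagonal; the `smoothed` flag records this.
#'
#' @param data data frame of integer-coded ordinal columns (0-based
#'   categories, `NA` for missing) plus any `continuous` columns.
#' @param continuous character vector of column names to treat as observed
#'   numeric predictors.
#' In addition to the estimates, the per-observation influence values of
#' every statistic are stored (`influence`); their empirical covariance is
#' the full asymptotic covariance matrix Gamma of the first-stage
#' statistics, which the DWLS engine uses for sandwich standard errors and
#' the mean/variance adjustment of the test statistic.
#'
#' @return object of class `polychoric_matrix`: list with `rho`, `avar`,
#'   `n_pairwise` (matrices), `thresholds`, `tau_avar`, `tau_n` (lists),
#'   `n` (median pairwise n), `influence` (samples x statistics matrix),
#'   `smoothed`, `boundary_pairs`.
#' @export
polychoric_matrix <- function(data, continuous = character()) {
  data <- as.data.frame(data)
  vars <- names(data)
  if (length(vars) < 2) stop("need at least 2 variables", call. = FALSE)
  p <- length(vars)
  is_cont <- vars %in% continuous

  degenerate <- vars[!is_cont & vapply(vars, function(v) {
    length(unique(data[[v]][!is.na(data[[v]])])) < 2
  }, logical(1))]
  if (length(degenerate) > 0) {
    stop("variables with a single observed category: ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  }

  nobs <- nrow(data)
  infl <- list()
  thresholds <- tau_avar <- tau_n <- stats::setNames(vector("list", p), vars)
  levels_ <- stats::setNames(vector("list", p), vars)
  for (j in seq_len(p)) {
    if (is_cont[j]) next
    th <- thresholds_from_column(data[[j]])
    thresholds[[j]] <- th$tau
    # avar of tau_k = qnorm(cumulative proportion): delta method
    cum <- cumsum(th$p)[-length(th$p)]
    tau_avar[[j]] <- cum * (1 - cum) / (th$n * dnorm(th$tau)^2)
    tau_n[[j]] <- th$n
    levels_[[j]] <- th$levels
    ok <- !is.na(data[[j]])
    xcat <- match(data[[j]], th$levels)
    for (k in seq_along(th$tau)) {
      col <- numeric(nobs)
      col[ok] <- (as.numeric(xcat[ok] <= k) - cum[k]) / dnorm(th$tau[k]) *
        (nobs / th$n)
      infl[[paste0("tau_", vars[j], "_", k)]] <- col
    }
  }

  rho <- diag(1, p); avar <- matrix(NA_real_, p, p); npw <- matrix(0L, p, p)
  boundary_pairs <- character()
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      xj <- data[[j]]; xk <- data[[k]]
      ok <- !is.na(xj) & !is.na(xk)
      if (sum(ok) < 10) stop("fewer than 10 complete pairs for ",
                             vars[j], " / ", vars[k], call. = FALSE)
      if_col <- numeric(nobs)
      if (is_cont[j] && is_cont[k]) {
        r <- cor(xj[ok], xk[ok])
        est <- list(rho = r, avar = (1 - r^2)^2 / sum(ok), boundary = FALSE)
        xs <- scale(xj[ok])[, 1]; ys <- scale(xk[ok])[, 1]
        if_col[ok] <- (xs * ys - r / 2 * (xs^2 + ys^2)) * (nobs / sum(ok))
      } else if (is_cont[j]) {
        est <- polyserial_approx(xj[ok], xk[ok])
        if_col[ok] <- est$if_vals * (nobs / sum(ok))
      } else if (is_cont[k]) {
        est <- polyserial_approx(xk[ok], xj[ok])
        if_col[ok] <- est$if_vals * (nobs / sum(ok))
      } else {
        ci <- match(xj[ok], levels_[[j]])
        cj <- match(xk[ok], levels_[[k]])
        R_ <- length(levels_[[j]]); C_ <- length(levels_[[k]])
        tab <- matrix(tabulate((cj - 1L) * R_ + ci, R_ * C_), R_, C_)
        est <- polychoric_table(tab)
        if_col[ok] <- est$cell_if[cbind(ci, cj)] * (nobs / sum(ok))
      }
      infl[[paste0("rho_", vars[j], ".", vars[k])]] <- if_col
      rho[j, k] <- rho[k, j] <- est$rho
      avar[j, k] <- avar[k, j] <- est$avar
      npw[j, k] <- npw[k, j] <- sum(ok)
      if (isTRUE(est$boundary)) {
        boundary_pairs <- c(boundary_pairs, paste(vars[j], vars[k], sep = ":"))
      }
    }
  }
  dimnames(rho) <- dimnames(avar) <- dimnames(npw) <- list(vars, vars)

  smoothed <- FALSE
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(S))
    rho_s <- S / tcrossprod(d)
    diag(rho_s) <- 1
    dimnames(rho_s) <- dimnames(rho)
    rho <- rho_s
    smoothed <- TRUE
  }

  infl_mat <- do.call(cbind, infl)
  structure(list(rho = rho, avar = avar, n_pairwise = npw,
                 thresholds = thresholds, tau_avar = tau_avar, tau_n = tau_n,
                 n = stats::median(npw[upper.tri(npw)]),
                 continuous = vars[is_cont], influence = infl_mat,
                 smoothed = smoothed, boundary_pairs = boundary_pairs),
            class = "polychoric_matrix")
}

#' @export
print.polychoric_matrix <- function(x, ...) {
  cat("Polychoric correlation matrix (", ncol(x$rho), " variables, median n ",
      x$n, ")\n", sep = "")
  if (x$smoothed) cat("  [indefinite raw matrix smoothed]\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Export a polychoric matrix as tab-separated text
#'
#' @param x a `polychoric_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_polychoric <- function(x, path) {
  df <- as.data.frame(x$rho)
  df <- cbind(variable = rownames(x$rho), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
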