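test_that("threshold estimation inverts the normal CDF exactly", {
  expect_equal(estimate_thresholds(c(0.5, 0.5)), 0)
  expect_equal(estimate_thresholds(c(0.694, 0.306)), qnorm(0.694))
  expect_equal(round(estimate_thresholds(c(0.694, 0.306)), 3), 0.507)
  expect_equal(round(estimate_thresholds(c(0.025, 0.975)), 3), -1.960)
  # round-trip to machine precision
  for (p in c(0.01, 0.17, 0.5, 0.76, 0.99)) {
    tau <- estimate_thresholds(c(1 - p, p))
    expect_equal(pnorm(tau, lower.tail = FALSE), p, tolerance = 1e-12)
  }
  expect_error(estimate_thresholds(c(0, 1)), "collapse")
  expect_error(estimate_thresholds(c(0.4, 0.4)), "sum to 1")
})

test_that("tetrachoric recovers the arcsine closed form and independence", {
  # zero thresholds, rho = 0.5: P11 = 1/4 + asin(0.5)/(2 pi)
  p11 <- 1 / 4 + asin(0.5) / (2 * pi)
  tab <- matrix(round(4e5 * c(p11, 0.5 - p11, 0.5 - p11, p11)), 2, 2)
  expect_equal(tetrachoric(tab)$rho, 0.5, tolerance = 5e-3)

  indep <- matrix(c(120, 80, 240, 160), 2, 2)  # cross-product ratio 1
  expect_equal(tetrachoric(indep)$rho, 0, tolerance = 1e-6)
})

test_that("tetrachoric agrees with a brute-force grid-search ML oracle", {
  set.seed(11)
  grid <- seq(-0.999, 0.999, by = 0.001)
  for (k in 1:20) {
    tab <- bvn_table(runif(1, -1, 1), runif(1, -1, 1), runif(1, -0.9, 0.9),
                     n = 2000)
    tab <- tab + 1  # keep margins positive
    est <- tetrachoric(tab)$rho
    a <- genefactor:::estimate_thresholds(rowSums(tab) / sum(tab))
    b <- genefactor:::estimate_thresholds(colSums(tab) / sum(tab))
    ll <- vapply(grid, function(r) {
      genefactor:::bvn_table_loglik(tab, a, b, r)
    }, numeric(1))
    expect_lt(abs(est - grid[which.max(ll)]), 0.002)
  }
})

test_that("empty cells yield a clipped boundary estimate with a flag", {
  tab <- matrix(c(50, 0, 0, 50), 2, 2)
  est <- tetrachoric(tab)
  expect_true(est$boundary)
  expect_equal(abs(est$rho), 0.999)
})

test_that("polychoric reduces to tetrachoric for 2x2 and respects reflection", {
  tab <- bvn_table(0.3, -0.4, 0.45, n = 5000) + 1
  expect_equal(polychoric_pair(tab)$rho, tetrachoric(tab)$rho,
               tolerance = 1e-10)
  # reversed category order negates the estimate
  rev_tab <- tab[2:1, ]
  expect_equal(polychoric_pair(rev_tab)$rho, -polychoric_pair(tab)$rho,
               tolerance = 1e-6)
})

test_that("3-category polychoric recovers the generating correlation", {
  set.seed(21)
  n <- 50000
  rho <- 0.4
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  y1 <- cut(z1, c(-Inf, -0.5, 0.8, Inf), labels = FALSE)
  y2 <- as.integer(z2 > 0.2)
  tab <- table(y1, y2)
  expect_equal(polychoric_pair(tab)$rho, rho, tolerance = 0.02)
})

test_that("tetrachoric is consistent across the correlation range", {
  set.seed(31)
  n <- 50000
  for (rho in c(-0.8, -0.3, 0, 0.3, 0.8)) {
    tab <- bvn_table(0.2, -0.3, rho, n = n)
    tab[tab == 0] <- 1
    expect_lt(abs(tetrachoric(tab)$rho - rho), 0.01)
  }
})

test_that("sandwich asymptotic variance tracks the empirical sampling variance", {
  set.seed(41)
  n <- 1000; rho <- 0.45; tau1 <- 0.3; tau2 <- -0.2
  p11 <- genefactor:::bvn_upper(tau1, tau2, rho)
  p1 <- pnorm(tau1, lower.tail = FALSE); p2 <- pnorm(tau2, lower.tail = FALSE)
  probs <- c(1 - p1 - p2 + p11, p2 - p11, p1 - p11, p11)
  ests <- avars <- numeric(2000)
  for (r in seq_len(2000)) {
    cnt <- matrix(rmultinom(1, n, probs), 2, 2)
    if (any(rowSums(cnt) == 0) || any(colSums(cnt) == 0)) next
    tt <- tetrachoric(cnt)
    ests[r] <- tt$rho; avars[r] <- tt$avar
  }
  ok <- avars > 0
  rel_err <- abs(mean(avars[ok]) - var(ests[ok])) / var(ests[ok])
  expect_lt(rel_err, 0.15)
})

test_that("polychoric matrix assembles pairwise estimates near the truth", {
  set.seed(51)
  n <- 5000
  # one factor, 6 binary items + 3 near-deterministic binary indicators
  lam <- c(0.42, 0.43, 0.63, 0.69, 0.29, 0.24, 0.95, 0.95, 0.95)
  tau <- c(0.5, 0.4, 0.5, 0.95, 0.45, 0.45, 0.52, 0.7, 0.52)
  f <- rnorm(n)
  dat <- as.data.frame(lapply(seq_along(lam), function(j) {
    as.integer(lam[j] * f + sqrt(1 - lam[j]^2) * rnorm(n) > tau[j])
  }))
  names(dat) <- paste0("v", seq_along(lam))
  pm <- polychoric_matrix(dat)
  truth <- tcrossprod(lam); diag(truth) <- 1
  expect_lt(max(abs(pm$rho - truth)), 0.04)
  expect_false(pm$smoothed)
})

test_that("duplicated columns flag the boundary and indefinite matrices are smoothed", {
  set.seed(61)
  x <- as.integer(rnorm(500) > 0)
  dat <- data.frame(a = x, b = x,
                    c = as.integer(rnorm(500) > 0.3))
  pm <- suppressWarnings(polychoric_matrix(dat))
  expect_equal(abs(pm$rho["a", "b"]), 0.999)
  expect_true(any(grepl("a:b", pm$boundary_pairs)))

  # pairwise deletion on disjoint subsets can produce an indefinite raw
  # matrix: x=y, y=z, but x = 1-z
  m <- 40
  base <- rep(c(0L, 1L), m / 2)
  blk <- function(xx, yy, zz) data.frame(x = xx, y = yy, z = zz)
  dat2 <- rbind(blk(base, base, NA), blk(NA, base, base),
                blk(base, NA, 1L - base))
  pm2 <- suppressWarnings(polychoric_matrix(dat2))
  expect_true(pm2$smoothed)
  expect_gte(min(eigen(pm2$rho, symmetric = TRUE)$values), 0)

  expect_error(polychoric_matrix(data.frame(one = rep(1L, 20),
                                            two = c(rep(0L, 10),
                                                    rep(1L, 10)))),
               "single observed category")
})
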