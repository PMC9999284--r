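test_that("threshold estimation matches normal quantiles of cumulants", {
  expect_equal(as.numeric(estimate_thresholds(c(50, 50))), 0)
  expect_equal(as.numeric(estimate_thresholds(c(25, 25, 25, 25))),
               qnorm(c(0.25, 0.5, 0.75)))
  deg <- estimate_thresholds(c(100, 0, 0, 0))
  expect_equal(as.numeric(deg), c(Inf, Inf, Inf))
  expect_true(attr(deg, "collapsed"))
  expect_error(estimate_thresholds(c(0, 0, 0)), "zero")
  # composing with the normal CDF reproduces the cumulative proportions
  counts <- c(13, 41, 7, 29)
  tau <- as.numeric(estimate_thresholds(counts))
  expect_equal(pnorm(tau), cumsum(counts)[1:3] / sum(counts),
               tolerance = 1e-14)
})

test_that("polychoric ML recovers rho from bivariate-normal cuts", {
  # independence: an exact outer-product table gives rho ~ 0
  marg <- c(400, 300, 200, 100)
  tab <- outer(marg, marg) / sum(marg)
  fit <- estimate_polychoric(round(tab))
  expect_lt(abs(fit$rho), 0.02)
  # simulation oracle at rho = 0.5
  set.seed(11)
  z1 <- rnorm(100000); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(100000)
  fit2 <- estimate_polychoric(cut_table(z1, z2))
  expect_lt(abs(fit2$rho - 0.5), 3 * sqrt(fit2$rho_var))
  # perfectly concordant diagonal hits the clamp
  fit3 <- suppressWarnings(estimate_polychoric(diag(c(30, 40, 30, 20))))
  expect_equal(fit3$rho, 0.999)
})

test_that("polychoric estimation is symmetric under table transpose", {
  set.seed(3)
  z1 <- rnorm(4000); z2 <- 0.6 * z1 + 0.8 * rnorm(4000)
  tab <- cut_table(z1, z2, c(-0.5, 0.5), c(-1, 0, 1))
  f1 <- estimate_polychoric(tab)
  f2 <- estimate_polychoric(t(tab))
  expect_equal(f1$rho, f2$rho, tolerance = 1e-7)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-7)
})

test_that("degenerate tables raise structured errors", {
  expect_error(estimate_polychoric(matrix(c(5, 5, 0, 0), 2, byrow = TRUE)),
               "degenerate")
})

test_that("normality test df follows r*c - r - c", {
  set.seed(5)
  z1 <- rnorm(2000); z2 <- 0.4 * z1 + rnorm(2000)
  expect_equal(bivariate_normality_test(cut_table(z1, z2))$df, 8)
})

test_that("pairwise matrix reflects the generating factor structure", {
  # null loadings: off-diagonals near zero
  cfg <- synthetic_config(10000, 4, 1, loadings = rep(0, 4), seed = 17)
  dat <- generate_cohort(cfg)
  smp <- polychoric_matrix(dat)
  expect_lt(max(abs(smp$rho[lower.tri(smp$rho)])), 0.03)
  # one-factor: every off-diagonal near lambda^2/(lambda^2 + psi) = 0.64
  cfg2 <- synthetic_config(50000, 4, 1, loadings = rep(0.8, 4),
                           unique_variances = 0.36, seed = 18)
  smp2 <- polychoric_matrix(generate_cohort(cfg2))
  off <- smp2$rho[lower.tri(smp2$rho)]
  se <- sqrt(max(smp2$rho_var[lower.tri(smp2$rho_var)]))
  expect_true(all(abs(off - 0.64) < 3 * se + 0.005))
  # duplicated variables hit the clamp
  dup <- dat
  dup$responses[, 2, 1] <- dup$responses[, 1, 1]
  smp3 <- polychoric_matrix(dup)
  expect_equal(smp3$rho[1, 2], 0.999)
})

test_that("eigenvalue clipping repairs indefinite matrices", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(R, symmetric = TRUE)$values), 0)
  S <- smooth_correlation_matrix(R)
  expect_gte(min(eigen(S, symmetric = TRUE)$values), 1e-5)
  expect_equal(diag(S), rep(1, 3))
  # already-PD matrices pass through untouched
  R2 <- diag(3) * 0.5 + 0.5
  expect_identical(smooth_correlation_matrix(R2), R2)
})
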