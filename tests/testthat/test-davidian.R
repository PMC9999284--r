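test_that("order 0 is exactly the standard normal density", {
  d <- davidian_density(0)
  expect_equal(davidian_pdf(0, d), dnorm(0))
  z <- seq(-4, 4, 0.25)
  expect_equal(davidian_pdf(z, d), dnorm(z), tolerance = 1e-12)
  s <- density_summary(d)
  expect_equal(c(s$mean, s$variance, s$skewness), c(0, 1, 0),
               tolerance = 1e-6)
})

test_that("any angle configuration integrates to one", {
  set.seed(2)
  for (k in c(1, 3, 5, 7)) {
    d <- davidian_density(k, angles = runif(k, -pi, pi))
    z <- seq(-10, 10, length.out = 2001)
    integral <- sum(davidian_pdf(z, d)) * (z[2] - z[1])
    expect_lt(abs(integral - 1), 1e-6)
  }
})

test_that("the family expresses bimodal shapes with known moments", {
  # c = (0, 1): h(z) = z^2 phi(z), modes at +/- sqrt(2), var = 3, skew = 0
  ms <- ordlmi:::moment_matrix_sqrt(2)
  u <- ms$half %*% c(0, 1, 0)
  d <- davidian_density(2, ordlmi:::angles_from_unit_vector(as.vector(u)))
  expect_equal(d$coefficients, c(0, 1, 0), tolerance = 1e-10)
  z <- seq(-4, 4, 0.01)
  h <- davidian_pdf(z, d)
  expect_equal(h, z^2 * dnorm(z), tolerance = 1e-10)
  s <- density_summary(d)
  expect_equal(c(s$mean, s$variance, s$skewness), c(0, 3, 0),
               tolerance = 1e-4)
  # two local maxima
  peaks <- which(diff(sign(diff(h))) == -2) + 1
  expect_identical(length(peaks), 2L)
})

test_that("standardized grids have mean zero and unit variance", {
  set.seed(8)
  d <- davidian_density(3, angles = runif(3, -1, 1))
  g <- density_summary(d)$standardized_grid
  dz <- diff(g$z)
  mid <- (g$h[-1] + g$h[-nrow(g)]) / 2
  m0 <- sum(mid * dz)
  m1 <- sum(mid * dz * (g$z[-1] + g$z[-nrow(g)]) / 2)
  expect_lt(abs(m1 / m0), 1e-6)
})

test_that("Hannan-Quinn follows its closed form and penalty ordering", {
  expect_equal(hannan_quinn(-1000, 10, 1000),
               2000 + 20 * log(log(1000)), tolerance = 1e-12)
  expect_lt(hannan_quinn(-500, 5, 100), hannan_quinn(-500, 9, 100))
  expect_equal(hannan_quinn(-500, 0, 100), 1000)
  expect_error(hannan_quinn(-500, 5, 2), "exceed")
})

test_that("EM is monotone and recovers a normal latent shape", {
  cfg <- synthetic_config(1500, 6, 1, loadings = rep(0.9, 6), seed = 14)
  dat <- generate_cohort(cfg)
  f <- fit_graded_davidian(dat$responses[, , 1], order = 2)
  expect_true(all(diff(f$loglik_trace) > -1e-8))
  expect_true(f$converged)
  s <- density_summary(f$density)
  expect_lt(abs(s$skewness), 0.3)
})

test_that("order selection returns the HQ minimizer", {
  # a loose EM tolerance keeps this property check cheap at small n; the
  # selection logic under test does not depend on it
  cfg <- synthetic_config(600, 5, 1, seed = 15)
  dat <- generate_cohort(cfg)
  sel <- select_order(dat$responses[, , 1], orders = c(0, 2), tol = 1e-3)
  expect_true(sel$order %in% c(0, 2))
  expect_identical(nrow(sel$table), 2L)
  expect_equal(sel$table$hq,
               -2 * sel$table$loglik +
                 2 * sel$table$n_params * log(log(600)), tolerance = 1e-10)
  # singleton candidate set is returned as-is
  sel1 <- select_order(dat$responses[, , 1], orders = 2, tol = 1e-3)
  expect_identical(sel1$order, 2)
})

test_that("marginal pattern probabilities sum to one on small designs", {
  cfg <- synthetic_config(400, 3, 1, n_categories = 3, seed = 16)
  dat <- generate_cohort(cfg)
  f <- fit_graded_davidian(dat$responses[, , 1], order = 1,
                           n_categories = 3)
  grid <- seq(-6, 6, length.out = 101)
  h <- davidian_pdf(grid, f$density)
  pi_q <- h / sum(h)
  pats <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  tot <- 0
  for (r in seq_len(nrow(pats))) {
    L <- rep(1, 101)
    for (i in 1:3) {
      lp <- ordlmi:::graded_logprob(
        c(log(f$items[[i]]$a), f$items[[i]]$b[1],
          log(diff(f$items[[i]]$b))), grid, 3)
      L <- L * exp(lp[pats[r, i] + 1, ])
    }
    tot <- tot + sum(L * pi_q)
  }
  expect_equal(tot, 1, tolerance = 1e-8)
})
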