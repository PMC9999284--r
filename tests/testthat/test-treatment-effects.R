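test_that("sum scores respect range and the completeness rule", {
  arr <- array(3L, c(2, 7, 2))
  arr[2, , 1] <- 0L
  arr[2, 4, 2] <- NA_integer_
  dat <- longitudinal_ordinal_data(arr, check_monotone = FALSE)
  ss <- sum_scores(dat)
  expect_equal(ss[1, ], c(21, 21))
  expect_equal(ss[2, 1], 0)
  expect_true(is.na(ss[2, 2]))
})

test_that("sample skewness matches sign conventions and the log-normal oracle", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  expect_gt(sample_skewness(c(0, 0, 0, 1)), 0)
  set.seed(23)
  x <- rlnorm(100000, 0, 0.5)
  truth <- (exp(0.25) + 2) * sqrt(exp(0.25) - 1)
  # skewness SE for a log-normal parent is large; generous 3-sigma band
  expect_lt(abs(sample_skewness(x) - truth), 0.1)
  expect_error(sample_skewness(c(1, 1, 1)), "zero")
  expect_error(sample_skewness(c(1, 2)), "3 values")
})

test_that("effect ratios reproduce the reference arithmetic", {
  expect_equal(effect_ratio(1.39, 1.07), 1.39 / 1.07)
  expect_lt(abs(effect_ratio(1.39, 1.07) - 1.30), 0.005)
  expect_lt(abs(effect_ratio(1.23, 1.02) - 1.21), 0.005)
  expect_equal(effect_ratio(2, 2), 1)
  expect_error(effect_ratio(1, 0), "zero")
})

test_that("tail risk ratio crosses one exactly at the analytic root", {
  xs <- seq(-2, 4, 0.1)
  expect_equal(tail_risk_ratio(0, 1, 0, 1, xs), rep(1, length(xs)))
  # pure mean decrease: uniformly below one
  expect_true(all(tail_risk_ratio(0, 1, -1, 1, xs) < 1))
  # mean decrease with tripled variance: crossing in the upper tail
  m1 <- 0; v1 <- 1; m2 <- -1.39; v2 <- 3
  a <- 1 / v2 - 1 / v1
  b <- -2 * (m2 / v2 - m1 / v1)
  cc <- m2^2 / v2 - m1^2 / v1
  xstar <- max(Re(polyroot(c(cc, b, a))))
  expect_lt(abs(tail_risk_ratio(m1, v1, m2, v2, xstar) - 1), 1e-8)
  expect_lt(tail_risk_ratio(m1, v1, m2, v2, 1), 1)
  expect_gt(tail_risk_ratio(m1, v1, m2, v2, xstar + 0.5), 1)
  # exactly one sign change right of both means
  sgn <- sign(tail_risk_ratio(m1, v1, m2, v2, seq(0.1, 6, 0.01)) - 1)
  expect_identical(sum(diff(sgn) != 0), 1L)
})

test_that("trajectories are null when nothing changes", {
  cfg <- small_cohort(n = 1500, I = 4, TT = 2, seed = 33,
                      alpha = c(0, 0), phi = c(1, 1), retention = NULL)
  dat <- generate_cohort(cfg)
  fit <- fit_dwls(polychoric_matrix(dat),
                  build_model("unique_factor", 4, 2, 4))
  traj <- standardized_trajectories(dat, fit)
  ss2 <- traj[traj$estimator == "sum_score" & traj$session == 2, ]
  expect_true(ss2$ci_low < 0 && ss2$ci_high > 0)
  lat2 <- traj[traj$estimator == "latent_lmi" & traj$session == 2, ]
  expect_lt(abs(lat2$effect), 0.1)
})

test_that("increasing latent variance splits latent and sum-score effects", {
  cfg <- synthetic_config(2000, 5, 3, latent_means = c(0, -0.6, -1.2),
                          latent_variances = c(1, 1.6, 2.5),
                          loadings = rep(0.8, 5), seed = 44)
  dat <- generate_cohort(cfg)
  fit <- fit_dwls(polychoric_matrix(dat),
                  build_model("unique_factor", 5, 3, 4))
  traj <- standardized_trajectories(dat, fit)
  lat <- traj$effect[traj$estimator == "latent_lmi"]
  ss <- traj$effect[traj$estimator == "sum_score"]
  expect_gt(abs(lat[3]), abs(ss[3]))
  # the bootstrap CI machinery runs (tiny B, just exercised)
  traj_b <- standardized_trajectories(dat, fit, bootstrap_B = 2)
  lat_b <- traj_b[traj_b$estimator == "latent_lmi", ]
  expect_true(all(is.finite(lat_b$ci_low)))
})
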