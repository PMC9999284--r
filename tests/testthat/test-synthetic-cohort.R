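test_that("zero latent variance collapses trajectories to the mean curve", {
  cfg <- synthetic_config(50, 4, 3, latent_means = c(0, -1, -2),
                          latent_variances = c(0, 0, 0), seed = 1)
  theta <- generate_latent_trajectories(cfg)
  expect_equal(theta, matrix(rep(c(0, -1, -2), each = 50), 50, 3))
})

test_that("normal-family margins match the configured moments", {
  cfg <- synthetic_config(50000, 3, 2, latent_means = c(0, -1),
                          latent_variances = c(1, 1), seed = 42)
  theta <- generate_latent_trajectories(cfg)
  se <- 1 / sqrt(50000)
  expect_lt(abs(mean(theta[, 1]) - 0), 3 * se)
  expect_lt(abs(mean(theta[, 2]) - (-1)), 3 * se)
  expect_lt(abs(sd(theta[, 1]) - 1), 0.02)
  # cross-session correlation as configured (AR(1) default 0.8)
  expect_lt(abs(cor(theta[, 1], theta[, 2]) - 0.8), 0.02)
})

test_that("shifted log-normal family hits the target skewness and moments", {
  cfg <- synthetic_config(100000, 3, 1, latent_means = -0.5,
                          latent_variances = 2,
                          latent_family = "lognormal_shifted",
                          family_params = list(skewness = 1.5), seed = 9)
  theta <- generate_latent_trajectories(cfg)[, 1]
  # SE of sample skewness for a skewed parent: bootstrap-free bound ~ sqrt(15/n)
  expect_lt(abs(sample_skewness(theta) - 1.5), 3 * sqrt(15 / 1e5))
  expect_lt(abs(mean(theta) - (-0.5)), 3 * sqrt(2 / 1e5))
  expect_lt(abs(var(theta) - 2), 0.1)
})

test_that("latent trajectory generation rejects invalid configurations", {
  bad <- matrix(c(1, 2, 2, 1), 2)   # not a correlation matrix, not PD
  expect_error(synthetic_config(10, 3, 2, latent_corr = bad),
               "positive definite")
  expect_error(synthetic_config(10, 3, 2, retention = c(1, 1.2)),
               "retention")
  expect_error(synthetic_config(10, 3, 2, retention = c(0.8, 1)),
               "non-increasing")
})

test_that("liability-threshold rendering reproduces closed-form cell rates", {
  # saturating thresholds push every response to category 0
  tau <- matrix(rep(c(1e6, 2e6, 3e6), each = 4), 4, 3)
  cfg <- synthetic_config(500, 4, 1, thresholds = tau, seed = 2)
  dat <- render_ordinal_items(generate_latent_trajectories(cfg), cfg)
  expect_true(all(dat$responses == 0L))

  # zero loading: frequencies follow the univariate normal cells
  tau2 <- matrix(rep(c(-1, 0, 1), each = 4), 4, 3)
  cfg2 <- synthetic_config(40000, 4, 1, loadings = rep(0, 4),
                           thresholds = tau2, seed = 3)
  dat2 <- render_ordinal_items(generate_latent_trajectories(cfg2), cfg2)
  freq <- tabulate(dat2$responses[, 1, 1] + 1L, 4) / 40000
  truth <- diff(c(0, pnorm(c(-1, 0, 1)), 1))
  expect_lt(max(abs(freq - truth)), 3 * sqrt(0.25 / 40000) + 0.002)

  # unit loading + unit uniqueness: marginal liability variance is 2
  cfg3 <- synthetic_config(40000, 3, 1, loadings = rep(1, 3),
                           thresholds = matrix(rep(c(-1, 0, 1),
                                                   each = 3), 3, 3),
                           seed = 4)
  dat3 <- render_ordinal_items(generate_latent_trajectories(cfg3), cfg3)
  p0 <- mean(dat3$responses[, 1, 1] == 0)
  expect_lt(abs(p0 - pnorm(-1 / sqrt(2))), 3 * sqrt(0.2 / 40000) + 0.002)
})

test_that("schedule dropout matches configured retention and is monotone", {
  cfg <- preset_config("gad7", n_subjects = 20000, seed = 6)
  dat <- generate_cohort(cfg)
  obs <- n_per_session(dat) / 20000
  expect_lt(abs(obs[2] - 0.91), 3 * sqrt(0.91 * 0.09 / 20000))
  expect_lt(abs(obs[12] - 0.44), 3 * sqrt(0.44 * 0.56 / 20000) + 0.01)
  expect_true(is_monotone_missing(dat))
  # no dropout leaves the data untouched
  cfg2 <- small_cohort(n = 200, seed = 8, retention = NULL)
  dat2 <- render_ordinal_items(generate_latent_trajectories(cfg2), cfg2)
  expect_identical(apply_dropout(dat2, cfg2)$responses, dat2$responses)
})

test_that("logistic dropout recovers the configured age odds ratio", {
  TT <- 4
  cfg <- synthetic_config(
    40000, 3, TT, seed = 10,
    dropout_logistic = list(or = c(age = 0.7),
                            baseline_retention = c(1, 0.9, 0.8, 0.7)))
  dat <- generate_cohort(cfg)
  # discrete-time hazard: continuation events per at-risk session
  obs <- !is.na(dat$responses[, 1, ])
  ev <- NULL
  for (t in 2:TT) {
    at_risk <- obs[, t - 1]
    ev <- rbind(ev, data.frame(cont = obs[at_risk, t],
                               age = dat$covariates$age[at_risk],
                               sess = factor(t)))
  }
  fit <- glm(cont ~ sess + age, family = binomial, data = ev)
  se <- summary(fit)$coefficients["age", "Std. Error"]
  expect_lt(abs(coef(fit)[["age"]] - log(0.7)), 3 * se)
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- small_cohort(n = 300, seed = 123, retention = c(1, 0.9, 0.8))
  d1 <- generate_cohort(cfg); d2 <- generate_cohort(cfg)
  expect_identical(d1$responses, d2$responses)
  expect_identical(attr(d1, "latents"), attr(d2, "latents"))
})

test_that("violation scenarios only move the targeted parameter block", {
  cfg <- small_cohort(n = 100, seed = 31, retention = NULL)
  tau_shift <- cfg$thresholds
  tau_shift[, , 2] <- tau_shift[, , 2] + 0.5
  cfg2 <- small_cohort(n = 100, seed = 31, retention = NULL,
                       thresholds = tau_shift)
  expect_identical(cfg$loadings, cfg2$loadings)
  expect_identical(cfg$thresholds[, , 1], cfg2$thresholds[, , 1])
  expect_equal(cfg2$thresholds[, , 2], cfg$thresholds[, , 2] + 0.5)
  # same latents, same item noise: only session 2 responses change
  d1 <- render_ordinal_items(generate_latent_trajectories(cfg), cfg)
  d2 <- render_ordinal_items(generate_latent_trajectories(cfg2), cfg2)
  expect_identical(d1$responses[, , 1], d2$responses[, , 1])
  expect_false(identical(d1$responses[, , 2], d2$responses[, , 2]))
})

test_that("cohort CSV round-trips through write and validate", {
  cfg <- small_cohort(n = 60, seed = 13, retention = c(1, 0.8, 0.6))
  dat <- generate_cohort(cfg)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(dat, path, config = cfg)
  back <- read_cohort_csv(path)
  expect_identical(back$responses, dat$responses)
  expect_true(file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json")))
})
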