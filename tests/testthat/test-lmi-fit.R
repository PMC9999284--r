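# a complete parameter set for a small design, used by several tests
make_values <- function(I = 4, TT = 3, C = 4, lambda = 0.8,
                        alpha = c(0, -0.4, -0.8),
                        phi_diag = c(1, 1.2, 1.5), rho = 0.6) {
  phi <- outer(seq_len(TT), seq_len(TT),
               function(a, b) rho^abs(a - b)) *
    sqrt(tcrossprod(phi_diag))
  tau <- array(rep(qnorm(c(0.45, 0.75, 0.9))[seq_len(C - 1)],
                   each = I), c(I, C - 1, TT)) * sqrt(lambda^2 + 1)
  list(lambda = matrix(lambda, I, TT), tau = tau,
       psi = matrix(1, I, TT), alpha = alpha, phi = phi)
}

test_that("implied moments follow the closed-form factor expressions", {
  spec <- build_model("configural", 4, 2, 4)
  v <- make_values(4, 2, 4, lambda = 1, alpha = c(0, 0),
                   phi_diag = c(1, 1), rho = 0)
  imp <- model_implied_moments(spec, v)
  within <- imp$corr[1:4, 1:4][lower.tri(diag(4))]
  expect_equal(within, rep(0.5, 6))
  expect_equal(imp$corr[1:4, 5:8], matrix(0, 4, 4))
  # null loading: zero correlations, standardized thresholds = raw
  v2 <- make_values(4, 2, 4, alpha = c(0, 0), phi_diag = c(1, 1))
  v2$lambda[2, ] <- 0
  imp2 <- model_implied_moments(spec, v2)
  expect_equal(imp2$corr[2, -2], rep(0, 7))
  expect_equal(imp2$thresholds[2, , 1], v2$tau[2, , 1])
})

test_that("implied moments are invariant to consistent rescaling", {
  spec <- build_model("configural", 4, 3, 4)
  v <- make_values()
  imp <- model_implied_moments(spec, v)
  # double the liability scale of item 3 everywhere
  v2 <- v
  v2$lambda[3, ] <- 2 * v$lambda[3, ]
  v2$psi[3, ] <- 4 * v$psi[3, ]
  v2$tau[3, , ] <- 2 * v$tau[3, , ]
  imp2 <- model_implied_moments(spec, v2)
  expect_equal(imp2$corr, imp$corr, tolerance = 1e-12)
  expect_equal(imp2$thresholds, imp$thresholds, tolerance = 1e-12)
})

test_that("non-positive-definite latent covariance is rejected", {
  spec <- build_model("configural", 4, 2, 4)
  v <- make_values(4, 2, 4, alpha = c(0, 0), phi_diag = c(1, 1))
  v$phi <- matrix(c(1, 1.5, 1.5, 1), 2)
  expect_error(model_implied_moments(spec, v), "positive definite")
})

test_that("fitting exact implied moments returns a zero discrepancy", {
  I <- 4; TT <- 2; C <- 4
  spec <- build_model("unique_factor", I, TT, C)
  truth <- make_values(I, TT, C, alpha = c(0, -0.5),
                       phi_diag = c(1, 1.4), rho = 0.7)
  imp <- model_implied_moments(spec, truth)
  vars <- as.vector(outer(paste0("item", 1:I), paste0("s", 1:TT),
                          paste, sep = "@"))
  sample <- list(
    rho = structure(imp$corr, dimnames = list(vars, vars)),
    thresholds = setNames(lapply(seq_len(I * TT), function(k) {
      i <- (k - 1) %% I + 1; t <- (k - 1) %/% I + 1
      imp$thresholds[i, , t]
    }), vars),
    n_pairwise = matrix(1000L, I * TT, I * TT),
    n_var = rep(1000L, I * TT), variables = vars, n_categories = C)
  fit <- fit_dwls(sample, spec)
  expect_lt(fit$T_stat, 1e-6)
  imp_fit <- model_implied_moments(fit$spec, fit$estimates)
  expect_equal(imp_fit$corr, unname(imp$corr), tolerance = 1e-4)
})

test_that("discrepancy is non-decreasing along the invariance sequence", {
  fit <- cached_uf_fit()
  dat <- cached_uf_data()
  smp <- polychoric_matrix(dat)
  fits <- fit_lmi_sequence(smp, 5, 3, 4, fixed_variance = TRUE)
  Ts <- vapply(fits, function(f) f$T_stat, numeric(1))
  expect_true(all(diff(Ts) > -1e-4))
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
})

test_that("unique-factor fit recovers the generating parameters", {
  cfg <- small_cohort(n = 2000, I = 5, TT = 3, seed = 77,
                      alpha = c(0, -0.4, -0.8), phi = c(1, 1.2, 1.5),
                      loadings = rep(0.8, 5), retention = NULL)
  dat <- generate_cohort(cfg)
  fit <- fit_dwls(polychoric_matrix(dat),
                  build_model("unique_factor", 5, 3, 4))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates$alpha - c(0, -0.4, -0.8))), 0.15)
  expect_lt(max(abs(diag(fit$estimates$phi) - c(1, 1.2, 1.5))), 0.3)
  expect_lt(max(abs(fit$estimates$lambda - 0.8)), 0.12)
})

test_that("constant-SD reparameterization preserves implied moments", {
  # closed-form rescaling
  v <- make_values(4, 3, 4, alpha = c(0, -0.7, -1.4),
                   phi_diag = c(1, 2, 3), rho = 0.6)
  out <- constant_sd_reparameterization(v)
  expect_equal(out$alpha[3], -1.4 / sqrt(3))
  expect_equal(diag(out$phi), rep(1, 3))
  spec <- build_model("configural", 4, 3, 4)
  imp0 <- model_implied_moments(spec, v)
  imp1 <- model_implied_moments(spec, out)
  expect_lt(max(abs(imp0$corr - imp1$corr)), 1e-10)
  expect_lt(max(abs(imp0$thresholds - imp1$thresholds)), 1e-10)
  # identity when variances are already 1
  v1 <- make_values(4, 3, 4, phi_diag = c(1, 1, 1))
  expect_equal(constant_sd_reparameterization(v1), v1)
  # and on a real fit
  fit <- cached_uf_fit()
  rep_v <- constant_sd_reparameterization(fit)
  impf <- model_implied_moments(fit$spec, fit$estimates)
  impr <- model_implied_moments(fit$spec, rep_v)
  expect_lt(max(abs(impf$corr - impr$corr)), 1e-10)
})
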