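# shared fixture builders (all data generated in code at test time)

# small LMI-respecting cohort for fitting tests
small_cohort <- function(n = 800, I = 5, TT = 3, seed = 7,
                         alpha = NULL, phi = NULL, ...) {
  if (is.null(alpha)) alpha <- seq(0, -1, length.out = TT)
  if (is.null(phi)) phi <- rep(1, TT)
  synthetic_config(n, I, TT, latent_means = alpha,
                   latent_variances = phi, seed = seed, ...)
}

# cut a pair of continuous vectors into a 4x4 contingency table
cut_table <- function(y1, y2, cuts1 = c(-1, 0, 1), cuts2 = cuts1) {
  table(factor(findInterval(y1, cuts1), levels = 0:length(cuts1)),
        factor(findInterval(y2, cuts2), levels = 0:length(cuts2)))
}

# a one-shot fitted unique-factor model reused across test files
fit_cache <- new.env()
cached_uf_fit <- function() {
  if (!is.null(fit_cache$fit)) return(fit_cache$fit)
  cfg <- small_cohort(n = 1200, I = 5, TT = 3, seed = 21)
  dat <- generate_cohort(cfg)
  smp <- polychoric_matrix(dat)
  fit_cache$data <- dat
  fit_cache$fit <- fit_dwls(smp, build_model("unique_factor", 5, 3, 4))
  fit_cache$fit
}
cached_uf_data <- function() {
  cached_uf_fit()
  fit_cache$data
}
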