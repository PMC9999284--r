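#' Sum scores per subject and session
#'
#' The conventional clinical outcome: the plain total of the ordinal item
#' responses, missing whenever any item at that session is missing.
#'
#' @param data a `longitudinal_ordinal_data`.
#' @return `n x T` numeric matrix of totals (`NA` for incomplete sessions).
#' @export
sum_scores <- function(data) {
  apply(data$responses, c(1L, 3L), function(x) {
    if (anyNA(x)) NA_real_ else sum(x)
  })
}

#' Adjusted sample skewness
#'
#' The adjusted Fisher-Pearson coefficient
#' `g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^{3/2}`.
#'
#' @param values numeric vector (`n >= 3`, positive SD); NAs dropped.
#' @return skewness estimate.
#' @export
sample_skewness <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("zero standard deviation", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Ratio of latent to sum-score standardized treatment effects
#'
#' @param latent_effect,sum_effect standardized effects on the same
#'   session-1 scale (`sum_effect` nonzero).
#' @return `latent_effect / sum_effect`.
#' @export
effect_ratio <- function(latent_effect, sum_effect) {
  if (any(sum_effect == 0))
    stop("sum-score effect is zero; ratio undefined", call. = FALSE)
  latent_effect / sum_effect
}

#' Tail risk ratio between two normal latent distributions
#'
#' `TRR(x) = P(Z_last > x) / P(Z_first > x)` for normal latents with the
#' given means and variances — the model-implied change in the prevalence
#' of severe cases above cutoff `x`.  When the last session's variance
#' exceeds the first's, TRR crosses 1 in the upper tail even though the
#' mean decreased.
#'
#' @param mean_first,var_first,mean_last,var_last latent moments.
#' @param x cutoff(s); vectorized.
#' @return numeric vector `TRR(x)`.
#' @export
tail_risk_ratio <- function(mean_first, var_first, mean_last, var_last, x) {
  stopifnot(var_first > 0, var_last > 0)
  num <- pnorm((x - mean_last) / sqrt(var_last), lower.tail = FALSE)
  den <- pnorm((x - mean_first) / sqrt(var_first), lower.tail = FALSE)
  num / den
}

#' Latent versus sum-score standardized treatment trajectories
#'
#' Latent effects are the fitted latent means (the identification fixes
#' the session-1 mean to 0 and variance to 1, so `alpha_t` is already the
#' standardized effect).  Sum-score effects are
#' `(mean_t - mean_1) / SD_1` over observed cases per session.  Sum-score
#' CIs use the normal approximation; latent CIs (optional) use a
#' nonparametric subject-level bootstrap refitting the model `B` times.
#'
#' @param data the analyzed cohort.
#' @param fit a converged `lmi_fit`.
#' @param bootstrap_B bootstrap replicates for latent CIs (0 = skip;
#'   the default 200 is appropriate for reporting, not for quick checks).
#' @param conf confidence level.
#' @return data.frame with one row per session and estimator
#'   (`latent_lmi`, `sum_score`): `effect`, `ci_low`, `ci_high`, plus
#'   per-session sum-score `mean`, `sd`, `skewness`, `n` and latent
#'   `variance`.
#' @export
standardized_trajectories <- function(data, fit, bootstrap_B = 0L,
                                      conf = 0.95) {
  stopifnot(inherits(fit, "lmi_fit"))
  if (!fit$converged) warning("fit did not converge", call. = FALSE)
  TT <- fit$spec$n_sessions
  z <- qnorm(1 - (1 - conf) / 2)
  ss <- sum_scores(data)
  m1 <- mean(ss[, 1L], na.rm = TRUE)
  sd1 <- stats::sd(ss[, 1L], na.rm = TRUE)
  rows <- list()
  n1 <- sum(!is.na(ss[, 1L]))
  for (t in seq_len(TT)) {
    x <- ss[, t]; x <- x[!is.na(x)]
    if (!length(x)) { warning("session ", t, " empty; skipped",
                              call. = FALSE); next }
    eff <- (mean(x) - m1) / sd1
    # SE of the mean difference against session 1 (independence
    # approximation; conservative under the positive serial correlation)
    se <- if (t == 1L) 0 else
      sqrt(stats::var(x) / length(x) + sd1^2 / n1) / sd1
    rows[[length(rows) + 1L]] <- data.frame(
      session = t, estimator = "sum_score", effect = eff,
      ci_low = eff - z * se, ci_high = eff + z * se, mean = mean(x),
      sd = stats::sd(x),
      skewness = if (length(x) >= 3 && stats::sd(x) > 0)
        sample_skewness(x) else NA_real_,
      n = length(x), variance = NA_real_)
  }
  boot_alpha <- NULL
  if (bootstrap_B > 0L) {
    n <- dim(data$responses)[1L]
    boot_alpha <- matrix(NA_real_, bootstrap_B, TT)
    for (b in seq_len(bootstrap_B)) {
      idx <- sample.int(n, n, replace = TRUE)
      bdat <- data
      bdat$responses <- data$responses[idx, , , drop = FALSE]
      bs <- tryCatch({
        smp <- polychoric_matrix(bdat)
        fit_dwls(smp, fit$spec)$estimates$alpha
      }, error = function(e) rep(NA_real_, TT))
      boot_alpha[b, ] <- bs
    }
  }
  for (t in seq_len(TT)) {
    eff <- fit$estimates$alpha[t]
    ci <- if (!is.null(boot_alpha))
      stats::quantile(boot_alpha[, t], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                      na.rm = TRUE)
    else c(NA_real_, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      session = t, estimator = "latent_lmi", effect = eff,
      ci_low = ci[1L], ci_high = ci[2L], mean = NA_real_, sd = NA_real_,
      skewness = NA_real_, n = NA_integer_,
      variance = fit$estimates$phi[t, t])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
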