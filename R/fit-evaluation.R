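#' Chi-square difference test between nested fits
#'
#' @param T_a,df_a statistic and df of the less constrained model.
#' @param T_b,df_b statistic and df of the more constrained model
#'   (`df_b > df_a`).
#' @return list with `delta_T`, `delta_df`, `p` (upper tail of the central
#'   chi-square).  A negative raw difference (possible under robust
#'   scaling) is floored at 0 with a warning.
#' @export
chi_square_difference <- function(T_a, df_a, T_b, df_b) {
  if (df_b <= df_a)
    stop("the second model must be more constrained (df_b > df_a)",
         call. = FALSE)
  dT <- T_b - T_a
  if (dT < 0) {
    warning("negative chi-square difference floored at 0", call. = FALSE)
    dT <- 0
  }
  ddf <- df_b - df_a
  list(delta_T = dT, delta_df = ddf,
       p = pchisq(dT, ddf, lower.tail = FALSE))
}

#' RMSEA-based equivalence test of model fit
#'
#' Tests the null hypothesis that the model fit is *poor* (population
#' RMSEA at least `eps0`) against the alternative of acceptable fit:
#' `p = P[chi2(df, ncp) <= T]` with noncentrality
#' `ncp = (N - 1) * df * eps0^2`.  A p-value below .05 rejects poor fit,
#' i.e. supports measurement equivalence; the classic exact-fit test's
#' logic reversed.
#'
#' @param T observed discrepancy statistic (>= 0).
#' @param df model degrees of freedom (>= 1).
#' @param N analysis sample size (>= 2).
#' @param eps0 RMSEA bound defining "poor" fit (default 0.08).
#' @return the equivalence p-value.
#' @export
equivalence_test <- function(T, df, N, eps0 = 0.08) {
  if (eps0 <= 0) stop("eps0 must be > 0", call. = FALSE)
  stopifnot(T >= 0, df >= 1, N >= 2)
  ncp <- (N - 1) * df * eps0^2
  pchisq(T, df, ncp = ncp)
}

#' Root mean square error of approximation
#'
#' `sqrt(max(0, (T - df) / (df * (N - 1))))`.
#'
#' @inheritParams equivalence_test
#' @return RMSEA point estimate.
#' @export
rmsea <- function(T, df, N) {
  stopifnot(df >= 1, N >= 2)
  sqrt(pmax(0, (T - df) / (df * (N - 1))))
}

#' Comparative fit index
#'
#' `1 - max(T - df, 0) / max(T_baseline - df_baseline, T - df, 0)` against
#' the independence baseline (zero correlations, free thresholds), clamped
#' to `[0, 1]`; a degenerate baseline with the target at exact fit returns
#' 1 by convention.
#'
#' @param T,df target model statistic and df.
#' @param T_baseline,df_baseline independence-model statistic and df.
#' @return CFI in `[0, 1]`.
#' @export
cfi <- function(T, df, T_baseline, df_baseline) {
  num <- max(T - df, 0)
  den <- max(T_baseline - df_baseline, T - df, 0)
  if (den <= 0) return(1)
  if (T_baseline - df_baseline < T - df)
    warning("baseline fits better than the target model", call. = FALSE)
  min(max(1 - num / den, 0), 1)
}

#' Standardized root mean square residual
#'
#' Root mean square of the residuals over the unique off-diagonal
#' correlation entries; threshold residuals are not included (the
#' conventional definition for categorical-moment models).
#'
#' @param sample_corr,implied_corr correlation matrices of equal dimension.
#' @param sample_thresholds,implied_thresholds accepted for interface
#'   completeness; not used.
#' @return SRMR value.
#' @export
srmr <- function(sample_corr, implied_corr, sample_thresholds = NULL,
                 implied_thresholds = NULL) {
  if (!all(dim(sample_corr) == dim(implied_corr)))
    stop("correlation matrices must have matching dimensions",
         call. = FALSE)
  res <- (sample_corr - implied_corr)[lower.tri(sample_corr)]
  sqrt(mean(res^2))
}

#' Independence-baseline fit for CFI
#'
#' The baseline model has zero correlations and saturated thresholds, so
#' its discrepancy under diagonal weighting is the weighted sum of squared
#' sample correlations, on df = number of correlation moments.
#'
#' @param fit an `lmi_fit` (its stored sample moments are reused).
#' @return list with `T_stat`, `df`.
#' @export
independence_fit <- function(fit) {
  sm <- fit$sample_moments
  idx <- seq.int(sm$n_thr + 1L, length(sm$values))
  list(T_stat = sum(sm$weights[idx] * sm$values[idx]^2),
       df = length(idx))
}

#' Fit-evaluation table for a fitted invariance sequence
#'
#' Produces one row per model with SRMR, RMSEA, CFI, the chi-square
#' difference test against the previous (less constrained) model, and the
#' RMSEA equivalence test.
#'
#' @param fits named list of `lmi_fit` objects in nesting order, as from
#'   [fit_lmi_sequence()].
#' @param eps0 equivalence-test RMSEA bound.
#' @return data.frame with columns `model, T_stat, df, srmr, rmsea, cfi,
#'   delta_T, delta_df, p_difference, p_equivalence`.
#' @export
fit_evaluation_table <- function(fits, eps0 = 0.08) {
  rows <- list()
  prev <- NULL
  for (nm in names(fits)) {
    f <- fits[[nm]]
    base <- independence_fit(f)
    sm <- f$sample_moments
    p_corr <- nrow(f$implied_corr)
    Rsamp <- matrix(0, p_corr, p_corr)
    Rsamp[sm$lt] <- sm$values[seq.int(sm$n_thr + 1L, length(sm$values))]
    Rsamp <- Rsamp + t(Rsamp); diag(Rsamp) <- 1
    cmp <- if (!is.null(prev) && f$df > prev$df)
      chi_square_difference(prev$T_stat, prev$df, f$T_stat, f$df)
    else list(delta_T = NA_real_, delta_df = NA_integer_, p = NA_real_)
    rows[[nm]] <- data.frame(
      model = nm, T_stat = f$T_stat, df = f$df,
      srmr = srmr(Rsamp, f$implied_corr),
      rmsea = rmsea(f$T_stat, f$df, f$N),
      cfi = cfi(f$T_stat, f$df, base$T_stat, base$df),
      delta_T = cmp$delta_T, delta_df = cmp$delta_df,
      p_difference = cmp$p,
      p_equivalence = equivalence_test(f$T_stat, f$df, f$N, eps0))
    prev <- f
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
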