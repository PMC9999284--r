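#' Counts of endorsed symptoms at a session
#'
#' For every subject with a complete item-response vector at the session,
#' the number of items answered above category 0.
#'
#' @param data a `longitudinal_ordinal_data`.
#' @param session session index.
#' @return integer vector of counts in `0..I`, attribute `"max_count" = I`.
#' @export
endorsed_counts <- function(data, session) {
  resp <- data$responses[, , session, drop = FALSE]
  dim(resp) <- dim(resp)[1:2]
  complete <- rowSums(is.na(resp)) == 0L
  if (!any(complete))
    stop("no subject has complete responses at session ", session,
         call. = FALSE)
  counts <- rowSums(resp[complete, , drop = FALSE] > 0L)
  structure(as.integer(counts), max_count = ncol(resp))
}

#' Score test of zero-inflation in symptom counts
#'
#' One-degree-of-freedom score test of excess zeros relative to a Poisson
#' fit (van den Broek form): with `lambda = mean(counts)`,
#' `p0 = exp(-lambda)` and `n0` observed zeros,
#' `S = (n0/p0 - n)^2 / (n (1/p0 - 1) - n lambda)`, referred to
#' `chi^2(1)`.  Counts are treated as unbounded; a warning is emitted when
#' the Poisson mean approaches the instrument's maximum count.
#'
#' @param counts integer vector of endorsed-symptom counts.
#' @return list with `S`, `df = 1`, `p`, `n`, `n_zero`, `lambda_hat`,
#'   `degenerate` flag.
#' @export
zero_inflation_score_test <- function(counts) {
  mx <- attr(counts, "max_count")
  counts <- as.numeric(counts)
  n <- length(counts)
  if (n < 30L) stop("need at least 30 counts", call. = FALSE)
  lam <- mean(counts)
  if (lam <= 0) stop("all counts are zero; the test is undefined",
                     call. = FALSE)
  if (!is.null(mx) && lam > mx / 2)
    warning("Poisson mean exceeds half the maximum count; truncation may ",
            "distort the test", call. = FALSE)
  p0 <- exp(-lam)
  n0 <- sum(counts == 0)
  denom <- n * (1 / p0 - 1) - n * lam
  if (denom <= 0) {
    return(list(S = NA_real_, df = 1L, p = NA_real_, n = n, n_zero = n0,
                lambda_hat = lam, degenerate = TRUE))
  }
  S <- max((n0 / p0 - n)^2 / denom, 0)
  list(S = S, df = 1L, p = pchisq(S, 1L, lower.tail = FALSE), n = n,
       n_zero = n0, lambda_hat = lam, degenerate = FALSE)
}

#' Zero-inflation test on counts simulated from a fitted invariance model
#'
#' Simulates `n_sim` subjects' ordinal responses at one session from the
#' fitted model's parameters (normal latent trait, liability-threshold
#' link), forms endorsed-symptom counts, and applies
#' [zero_inflation_score_test()] — the check that the fitted model can
#' reproduce the zero-inflation observed in the data.
#'
#' @param fit an `lmi_fit` (must have converged).
#' @param session session index.
#' @param n_sim number of simulated subjects.
#' @param seed RNG seed.
#' @return as [zero_inflation_score_test()], plus `source =
#'   "model_implied"`.
#' @export
model_implied_count_test <- function(fit, session, n_sim = 10000L,
                                     seed = 1L) {
  stopifnot(inherits(fit, "lmi_fit"))
  if (!fit$converged)
    stop("fit did not converge; refusing to simulate from it",
         call. = FALSE)
  est <- fit$estimates
  I <- fit$spec$n_items
  set.seed(as.integer(seed) %% .Machine$integer.max)
  theta <- rnorm(n_sim, est$alpha[session],
                 sqrt(est$phi[session, session]))
  resp <- matrix(0L, n_sim, I)
  for (i in seq_len(I)) {
    y <- est$lambda[i, session] * theta +
      rnorm(n_sim, sd = sqrt(est$psi[i, session]))
    tau <- est$tau[i, , session]
    resp[, i] <- findInterval(y, tau[is.finite(tau)])
  }
  counts <- structure(rowSums(resp > 0L), max_count = I)
  out <- zero_inflation_score_test(counts)
  out$source <- "model_implied"
  out
}

#' Tidy zero-inflation summary over sessions
#'
#' @param data a `longitudinal_ordinal_data`.
#' @param sessions sessions to test (default: all with any complete case).
#' @return data.frame `session, n, n_zero, lambda_hat, S, p, source`.
#' @export
zero_inflation_table <- function(data, sessions = NULL) {
  TT <- dim(data$responses)[3L]
  if (is.null(sessions)) sessions <- seq_len(TT)
  rows <- list()
  for (t in sessions) {
    counts <- tryCatch(endorsed_counts(data, t), error = function(e) NULL)
    if (is.null(counts) || length(counts) < 30L) next
    z <- zero_inflation_score_test(counts)
    rows[[length(rows) + 1L]] <- data.frame(
      session = t, n = z$n, n_zero = z$n_zero, lambda_hat = z$lambda_hat,
      S = z$S, p = z$p, source = "observed")
  }
  do.call(rbind, rows)
}
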