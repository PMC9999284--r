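#' Estimate liability thresholds from a univariate category margin
#'
#' Thresholds are normal quantiles of the cumulative category proportions:
#' `tau_c = qnorm(P(Y <= c))` for `c = 0..C-2`, the standard
#' liability-threshold estimator.  Empty leading/trailing categories give
#' `-Inf` / `+Inf` sentinels; interior empty categories produce tied
#' thresholds and are flagged for collapsing (attribute `"collapsed"`).
#'
#' @param category_counts nonnegative integer vector of category counts.
#' @return increasing numeric vector of length `C - 1`, with attribute
#'   `"collapsed"` = TRUE when any category was empty.
#' @export
estimate_thresholds <- function(category_counts) {
  counts <- as.numeric(category_counts)
  if (length(counts) < 2L || any(counts < 0))
    stop("need >= 2 nonnegative category counts", call. = FALSE)
  n <- sum(counts)
  if (n <= 0) stop("all category counts are zero", call. = FALSE)
  cum <- cumsum(counts)[-length(counts)] / n
  tau <- qnorm(cum)
  structure(tau, collapsed = any(counts == 0))
}

# drop empty rows/columns of a contingency table; returns the reduced
# table plus which original categories survived
occupied_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) < 1)
    stop("contingency table must be nonnegative with total count >= 1",
         call. = FALSE)
  ri <- rowSums(counts) > 0; ci <- colSums(counts) > 0
  list(counts = counts[ri, ci, drop = FALSE], rows = which(ri),
       cols = which(ci), collapsed = !all(ri) || !all(ci))
}

# bivariate-normal cell probabilities for threshold vectors ta, tb
bvn_cell_probs <- function(ta, tb, rho) {
  a <- c(-Inf, ta, Inf); b <- c(-Inf, tb, Inf)
  r <- length(a); s <- length(b)
  G <- matrix(pbvnorm(rep(a, times = s), rep(b, each = r), rho), r, s)
  P <- G[-1L, -1L, drop = FALSE] - G[-r, -1L, drop = FALSE] -
    G[-1L, -s, drop = FALSE] + G[-r, -s, drop = FALSE]
  pmax(P, 0)
}

#' Polychoric correlation by two-step maximum likelihood
#'
#' Step 1 estimates the thresholds from the table margins; step 2 maximizes
#' the multinomial likelihood with bivariate-normal cell probabilities over
#' `atanh(rho)` (bounded so `|rho| <= 0.999`, tolerance 1e-8 on the
#' transformed scale).  Also returns the likelihood-ratio test of the
#' latent bivariate-normality assumption.
#'
#' @param table an `r x c` contingency table (counts) of two ordinal items.
#' @return an object of class `polychoric_result` with elements `rho`,
#'   `thresholds_a`, `thresholds_b`, `loglik`, `chi2`, `df`, `p`, `n`.
#' @export
estimate_polychoric <- function(table) {
  occ <- occupied_table(table)
  counts <- occ$counts
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("degenerate table: fewer than 2 occupied rows or columns",
         call. = FALSE)
  if (occ$collapsed)
    warning("empty categories collapsed out of the table", call. = FALSE)
  n <- sum(counts)
  ta <- as.numeric(estimate_thresholds(rowSums(counts)))
  tb <- as.numeric(estimate_thresholds(colSums(counts)))
  negll <- function(z) {
    P <- bvn_cell_probs(ta, tb, tanh(z))
    -sum(counts * log(pmax(P, 1e-300)))
  }
  zmax <- atanh(0.999)
  opt <- optimize(negll, c(-zmax, zmax), tol = 1e-8)
  rho <- tanh(opt$minimum)
  # snap to the clamp when the optimum sits at the search boundary
  if (abs(opt$minimum) > zmax - 1e-6) rho <- sign(rho) * 0.999
  P <- bvn_cell_probs(ta, tb, rho)
  expected <- n * P
  obs <- counts
  pos <- obs > 0
  if (any(pos & expected <= 0)) {
    warning("sparse table: zero expected cell with nonzero count; ",
            "G2 is infinite", call. = FALSE)
    chi2 <- Inf
  } else {
    chi2 <- 2 * sum(obs[pos] * log(obs[pos] / expected[pos]))
    chi2 <- max(chi2, 0)
  }
  r <- nrow(counts); s <- ncol(counts)
  df <- r * s - r - s
  # asymptotic variance of rho-hat from the observed information of the
  # profile likelihood (central second difference); delta-method fallback
  # near the clamp boundary
  rho_var <- NA_real_
  if (abs(rho) < 0.995) {
    h <- 1e-4
    f <- function(r2) -sum(counts *
                             log(pmax(bvn_cell_probs(ta, tb, r2), 1e-300)))
    d2 <- (f(rho + h) - 2 * f(rho) + f(rho - h)) / h^2
    if (is.finite(d2) && d2 > 0) rho_var <- 1 / d2
  }
  if (!is.finite(rho_var)) rho_var <- (1 - rho^2)^2 * 3 / n
  structure(
    list(rho = rho, thresholds_a = ta, thresholds_b = tb,
         loglik = -opt$objective, chi2 = chi2, df = df,
         p = pchisq(chi2, df, lower.tail = FALSE), n = n,
         rho_var = rho_var),
    class = "polychoric_result")
}

#' @export
print.polychoric_result <- function(x, ...) {
  cat(sprintf("polychoric rho = %.4f (n = %d); normality G2 = %.3f, df = %d, p = %.4g\n",
              x$rho, x$n, x$chi2, x$df, x$p))
  invisible(x)
}

#' Likelihood-ratio test of latent bivariate normality
#'
#' Compares the observed two-way table to the cell counts implied by the
#' fitted bivariate-normal liability model (thresholds from margins,
#' polychoric `rho` by ML): `G2 = 2 sum obs * log(obs/expected)` on
#' `r*c - r - c` degrees of freedom.  Rejection indicates the pair of item
#' liabilities is not jointly normal.
#'
#' @param table an `r x c` contingency table.
#' @return list with `chi2`, `df`, `p`.
#' @export
bivariate_normality_test <- function(table) {
  fit <- estimate_polychoric(table)
  list(chi2 = fit$chi2, df = fit$df, p = fit$p)
}

#' Pairwise polychoric correlation matrix
#'
#' Estimates all pairwise polychoric correlations over the `item x session`
#' variables of a longitudinal data set using pairwise-complete subjects,
#' plus univariate thresholds per variable and the per-pair sample sizes.
#' The result is not guaranteed positive definite; see
#' [smooth_correlation_matrix()].
#'
#' @param data a `longitudinal_ordinal_data` object.
#' @return list with `rho` (correlation matrix), `thresholds` (list per
#'   variable), `n_pairwise` (matrix), `n_var` (per-variable n), `variables`
#'   (names), `excluded` (variables dropped for having a single occupied
#'   category), `n_categories`.
#' @export
polychoric_matrix <- function(data) {
  m <- flatten_responses(data)
  C <- data$n_categories
  occ_ok <- apply(m, 2L, function(x) {
    tab <- tabulate(x + 1L, nbins = C)
    sum(tab > 0) >= 2L
  })
  if (!all(occ_ok))
    warning("excluding variables with a single occupied category: ",
            paste(colnames(m)[!occ_ok], collapse = ", "), call. = FALSE)
  m <- m[, occ_ok, drop = FALSE]
  p <- ncol(m)
  if (p < 2L) stop("need >= 2 usable variables", call. = FALSE)
  thresholds <- lapply(seq_len(p), function(j) {
    estimate_thresholds(tabulate(m[, j] + 1L, nbins = C))
  })
  names(thresholds) <- colnames(m)
  rho <- diag(1, p); npair <- matrix(0L, p, p)
  rho_var <- matrix(NA_real_, p, p)
  diag(npair) <- colSums(!is.na(m))
  for (j in seq_len(p - 1L)) {
    for (k in (j + 1L):p) {
      ok <- !is.na(m[, j]) & !is.na(m[, k])
      nok <- sum(ok)
      npair[j, k] <- npair[k, j] <- nok
      if (nok == 0L) { rho[j, k] <- rho[k, j] <- NA_real_; next }
      tab <- table(factor(m[ok, j], levels = 0:(C - 1L)),
                   factor(m[ok, k], levels = 0:(C - 1L)))
      fit <- suppressWarnings(tryCatch(estimate_polychoric(tab),
                                       error = function(e) NULL))
      rho[j, k] <- rho[k, j] <- if (is.null(fit)) NA_real_ else fit$rho
      rho_var[j, k] <- rho_var[k, j] <-
        if (is.null(fit)) NA_real_ else fit$rho_var
    }
  }
  dimnames(rho) <- list(colnames(m), colnames(m))
  list(rho = rho, thresholds = thresholds, n_pairwise = npair,
       rho_var = rho_var, n_var = colSums(!is.na(m)),
       variables = colnames(m), excluded = names(occ_ok)[!occ_ok],
       n_categories = C)
}

#' Repair a pairwise correlation matrix to positive definiteness
#'
#' Pairwise-complete polychoric matrices can be indefinite.  Eigenvalues
#' below `floor` are clipped up to it and the matrix is rescaled back to
#' unit diagonal.
#'
#' @param R symmetric correlation matrix (NAs not allowed).
#' @param floor smallest admissible eigenvalue (default 1e-4).
#' @return positive-definite correlation matrix.
#' @export
smooth_correlation_matrix <- function(R, floor = 1e-4) {
  if (any(is.na(R))) stop("correlation matrix contains NA", call. = FALSE)
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (all(e$values >= floor)) return(R)
  v <- pmax(e$values, floor)
  S <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  dimnames(S) <- dimnames(R)
  (S + t(S)) / 2
}

#' Tidy table of pairwise latent-normality tests
#'
#' Runs [bivariate_normality_test()] on every variable pair of a data set
#' (pairwise-complete subjects) and returns a tidy data.frame.
#'
#' @param data a `longitudinal_ordinal_data` object.
#' @param sessions optional subset of sessions to test (default: all).
#' @return data.frame with columns `var_a, var_b, n, chi2, df, p`.
#' @export
pairwise_normality_tests <- function(data, sessions = NULL) {
  m <- flatten_responses(data)
  C <- data$n_categories
  if (!is.null(sessions)) {
    keep <- grepl(paste0("@(", paste0("s", sessions, collapse = "|"), ")$"),
                  colnames(m))
    m <- m[, keep, drop = FALSE]
  }
  p <- ncol(m)
  res <- list()
  for (j in seq_len(p - 1L)) {
    for (k in (j + 1L):p) {
      ok <- !is.na(m[, j]) & !is.na(m[, k])
      if (!sum(ok)) next
      tab <- table(factor(m[ok, j], levels = 0:(C - 1L)),
                   factor(m[ok, k], levels = 0:(C - 1L)))
      tst <- suppressWarnings(tryCatch(bivariate_normality_test(tab),
                                       error = function(e) NULL))
      if (is.null(tst)) next
      res[[length(res) + 1L]] <- data.frame(
        var_a = colnames(m)[j], var_b = colnames(m)[k], n = sum(ok),
        chi2 = tst$chi2, df = tst$df, p = tst$p)
    }
  }
  do.call(rbind, res)
}
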