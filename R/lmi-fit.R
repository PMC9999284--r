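#' Model-implied polychoric correlations and standardized thresholds
#'
#' For the one-factor-per-session liability model, total liability variance
#' is `v_it = lambda_it^2 * phi_tt + psi_it`; the implied correlation
#' between variables `(i,t)` and `(j,s)` is
#' `lambda_it * phi_ts * lambda_js / sqrt(v_it * v_js)` and the implied
#' standardized threshold is `(tau_ict - lambda_it * alpha_t) / sqrt(v_it)`.
#'
#' @param spec an `lmi_model_spec`.
#' @param values parameter values: list with `lambda` (`I x T`), `tau`
#'   (`I x (C-1) x T`, `NA` where unoccupied), `psi` (`I x T`), `alpha`
#'   (length `T`), `phi` (`T x T` latent covariance, variances on the
#'   diagonal; must be positive definite).
#' @return list with `corr` (`IT x IT`, session-major variable order) and
#'   `thresholds` (same shape as `values$tau`).
#' @export
model_implied_moments <- function(spec, values) {
  I <- spec$n_items; TT <- spec$n_sessions
  lam <- values$lambda; psi <- values$psi
  phi <- values$phi; alpha <- values$alpha
  if (any(psi <= 0)) stop("psi must be > 0", call. = FALSE)
  ev <- eigen((phi + t(phi)) / 2, symmetric = TRUE, only.values = TRUE)
  if (any(ev$values <= 0))
    stop("latent covariance matrix is not positive definite", call. = FALSE)
  implied_moments_unchecked(spec, values)
}

# ---- parameter mapping: ledger -> flat parameter vector ------------------

# Linear index of a ledger row into its target array, plus a slot id
# 1=lambda (I x T), 2=tau (I x (C-1) x T), 3=psi (I x T), 4=alpha (T),
# 5=phi (T x T).  phi_cov rows get two indices (both triangles).
ledger_linear_index <- function(led, I, C, TT) {
  idx <- integer(nrow(led)); idx2 <- rep(NA_integer_, nrow(led))
  slot <- integer(nrow(led))
  for (r in seq_len(nrow(led))) {
    p <- led$param[r]; i <- led$item[r]; cc <- led$category[r]
    t <- led$session[r]; s <- led$session2[r]
    if (p == "lambda") { slot[r] <- 1L; idx[r] <- i + (t - 1L) * I }
    else if (p == "tau") { slot[r] <- 2L
      idx[r] <- i + (cc - 1L) * I + (t - 1L) * I * (C - 1L) }
    else if (p == "psi") { slot[r] <- 3L; idx[r] <- i + (t - 1L) * I }
    else if (p == "alpha") { slot[r] <- 4L; idx[r] <- t }
    else if (p == "phi_var") { slot[r] <- 5L; idx[r] <- t + (t - 1L) * TT }
    else { slot[r] <- 5L; idx[r] <- t + (s - 1L) * TT
           idx2[r] <- s + (t - 1L) * TT }
  }
  list(slot = slot, idx = idx, idx2 = idx2)
}

# Builds the mapping between the ledger and an unconstrained parameter
# vector (psi and phi_var on the log scale).  Returns starting values too.
make_param_map <- function(spec, start_values) {
  I <- spec$n_items; TT <- spec$n_sessions; C <- spec$n_categories
  led <- spec$ledger
  lin <- ledger_linear_index(led, I, C, TT)
  led$key <- ifelse(led$status == "equal", led$group,
                    paste(led$param, led$item, led$category, led$session,
                          led$session2, sep = "."))
  is_free <- led$status != "fixed"
  keys <- unique(led$key[is_free])
  par_index <- match(led$key[is_free], keys)
  first <- match(keys, led$key)
  transform <- ifelse(led$param[first] %in% c("psi", "phi_var"),
                      "log", "identity")
  start_arrays <- list(start_values$lambda, start_values$tau,
                       start_values$psi, start_values$alpha,
                       start_values$phi)
  row_start <- vapply(which(is_free), function(r)
    start_arrays[[lin$slot[r]]][lin$idx[r]], numeric(1))
  start <- as.numeric(tapply(row_start, par_index, mean))
  start <- ifelse(transform == "log", log(pmax(start, 1e-3)), start)
  fx <- which(!is_free)
  fr <- which(is_free)
  list(start = start, transform = transform, n_par = length(keys),
       fixed_slot = lin$slot[fx], fixed_idx = lin$idx[fx],
       fixed_idx2 = lin$idx2[fx], fixed_value = led$value[fx],
       free_slot = lin$slot[fr], free_idx = lin$idx[fr],
       free_idx2 = lin$idx2[fr], free_par = par_index)
}

# materialize a values list from the flat parameter vector
values_from_par <- function(par, map, spec) {
  I <- spec$n_items; TT <- spec$n_sessions; C <- spec$n_categories
  arrs <- list(matrix(NA_real_, I, TT),
               array(NA_real_, c(I, C - 1L, TT)),
               matrix(NA_real_, I, TT),
               rep(NA_real_, TT),
               matrix(NA_real_, TT, TT))
  raw <- ifelse(map$transform == "log", exp(par), par)
  vals_fixed <- map$fixed_value
  vals_free <- raw[map$free_par]
  for (sl in 1:5) {
    fsel <- map$fixed_slot == sl
    if (any(fsel)) arrs[[sl]][map$fixed_idx[fsel]] <- vals_fixed[fsel]
    rsel <- map$free_slot == sl
    if (any(rsel)) arrs[[sl]][map$free_idx[rsel]] <- vals_free[rsel]
  }
  # mirror phi lower triangle
  f2 <- !is.na(map$fixed_idx2)
  if (any(f2)) arrs[[5L]][map$fixed_idx2[f2]] <- vals_fixed[f2]
  r2 <- !is.na(map$free_idx2)
  if (any(r2)) arrs[[5L]][map$free_idx2[r2]] <- vals_free[r2]
  list(lambda = arrs[[1L]], tau = arrs[[2L]], psi = arrs[[3L]],
       alpha = arrs[[4L]], phi = arrs[[5L]])
}

# ---- sample-side moment vector and weights -------------------------------

# Extract the sample moment vector (finite standardized thresholds, then
# lower-triangle correlations) and inverse-sampling-variance weights from a
# polychoric_matrix() result.
sample_moments <- function(sample, spec) {
  I <- spec$n_items; TT <- spec$n_sessions; C <- spec$n_categories
  p <- I * TT
  if (length(sample$variables) != p)
    stop("sample does not cover all item x session variables; ",
         "refit with more data or a reduced design", call. = FALSE)
  thr_val <- c(); thr_w <- c(); thr_lin <- integer(0)
  occ <- array(FALSE, c(I, C - 1L, TT))
  for (k in seq_len(p)) {
    tau <- as.numeric(sample$thresholds[[k]])
    nk <- sample$n_var[k]
    i <- (k - 1L) %% I + 1L; t <- (k - 1L) %/% I + 1L
    fin <- is.finite(tau)
    occ[i, fin, t] <- TRUE
    pc <- pnorm(tau[fin])
    w <- nk * dnorm(tau[fin])^2 / (pc * (1 - pc))
    thr_val <- c(thr_val, tau[fin]); thr_w <- c(thr_w, w)
    thr_lin <- c(thr_lin,
                 i + (which(fin) - 1L) * I + (t - 1L) * I * (C - 1L))
  }
  R <- sample$rho
  lt <- lower.tri(R)
  corr_val <- R[lt]
  if (any(is.na(corr_val)))
    stop("sample polychoric matrix contains NA correlations", call. = FALSE)
  npair <- sample$n_pairwise[lt]
  corr_w <- npair / (1 - corr_val^2)^2
  if (!is.null(sample$rho_var)) {
    rv <- sample$rho_var[lt]
    use <- is.finite(rv) & rv > 0
    corr_w[use] <- 1 / rv[use]
  }
  list(values = c(thr_val, corr_val), weights = c(thr_w, corr_w),
       n_thr = length(thr_val), occ = occ, lt = lt, thr_lin = thr_lin)
}

# implied moments without the PD guard, for the optimizer's hot path
implied_moments_unchecked <- function(spec, values) {
  I <- spec$n_items; TT <- spec$n_sessions
  lam <- values$lambda; phi <- values$phi
  tt_idx <- rep(seq_len(TT), each = I)
  l <- as.vector(lam)
  v <- l^2 * diag(phi)[tt_idx] + as.vector(values$psi)
  corr <- (tcrossprod(l) * phi[tt_idx, tt_idx]) / sqrt(tcrossprod(v))
  diag(corr) <- 1
  thr <- values$tau
  for (t in seq_len(TT))
    thr[, , t] <- (values$tau[, , t] - lam[, t] * values$alpha[t]) /
      sqrt(v[tt_idx == t])
  list(corr = corr, thresholds = thr)
}

# implied moment vector in the sample ordering
implied_moment_vector <- function(spec, values, sm) {
  imp <- implied_moments_unchecked(spec, values)
  c(imp$thresholds[sm$thr_lin], imp$corr[sm$lt])
}

# ---- starting values -----------------------------------------------------

dwls_start_values <- function(spec, sample, sm) {
  I <- spec$n_items; TT <- spec$n_sessions; C <- spec$n_categories
  R <- sample$rho
  # average within-session inter-item correlation matrix
  Rw <- matrix(0, I, I)
  for (t in seq_len(TT)) {
    idx <- (t - 1L) * I + seq_len(I)
    Rw <- Rw + R[idx, idx]
  }
  Rw <- Rw / TT; diag(Rw) <- 1
  e <- eigen(Rw, symmetric = TRUE)
  u <- e$vectors[, 1L] * sqrt(max(e$values[1L], 1e-4))
  if (mean(u) < 0) u <- -u
  u <- pmin(pmax(u, 0.05), 0.95)
  lam0 <- u / sqrt(1 - u^2)
  lam <- matrix(lam0, I, TT)
  # cross-session latent correlation from average cross-block correlations
  phi <- diag(1, TT)
  uu <- tcrossprod(u)
  for (t in seq_len(TT - 1L)) if (TT > 1L) {
    for (s in (t + 1L):TT) {
      bi <- (t - 1L) * I + seq_len(I); bj <- (s - 1L) * I + seq_len(I)
      r <- mean(R[bi, bj] / uu)
      phi[t, s] <- phi[s, t] <- min(max(r, -0.9), 0.9)
    }
  }
  # shrink toward AR(1)-ish PD structure if needed
  k <- 0
  while (any(eigen(phi, symmetric = TRUE,
                   only.values = TRUE)$values <= 1e-6) && k < 20) {
    phi <- 0.9 * phi; diag(phi) <- 1; k <- k + 1
  }
  tau <- array(NA_real_, c(I, C - 1L, TT))
  for (t in seq_len(TT))
    for (i in seq_len(I)) {
      k2 <- (t - 1L) * I + i
      st <- as.numeric(sample$thresholds[[k2]])
      fin <- is.finite(st)
      tau[i, fin, t] <- st[fin] * sqrt(lam[i, t]^2 + 1)
    }
  tau[is.na(tau)] <- 0
  list(lambda = lam, tau = tau, psi = matrix(1, I, TT),
       alpha = rep(0, TT), phi = phi)
}

# ---- the DWLS fit --------------------------------------------------------

#' Fit an invariance model by diagonally weighted least squares
#'
#' Minimizes the weighted squared discrepancy between the sample moments
#' (standardized thresholds and polychoric correlations) and the
#' model-implied moments, with weights equal to the inverse estimated
#' sampling variances of the sample moments (threshold variances by the
#' delta method from the cumulative proportions; correlation variances from
#' the pairwise observed information when available).  The reported test
#' statistic is `T = F_min` with these variance-scaled weights, referred to
#' `chi^2(df)` with `df = #moments - #free parameters`.
#'
#' @param sample output of [polychoric_matrix()] (optionally carrying a
#'   `rho_var` matrix of correlation sampling variances); the correlation
#'   matrix is PD-smoothed internally.
#' @param spec an `lmi_model_spec`; its occupancy is aligned to the sample
#'   (empty item-category margins drop moments and parameters).
#' @param N analysis sample size for downstream fit indices; defaults to
#'   the largest per-variable n at session 1.
#' @param start optional values list overriding the automatic starts.
#' @param control passed to [stats::nlminb()].
#' @return object of class `lmi_fit`: `spec`, `estimates` (values list),
#'   `T_stat`, `df`, `N`, `implied_corr`, `implied_thresholds`,
#'   `converged`, `n_iterations`, `heywood`, `F_min`, `weights`.
#' @export
fit_dwls <- function(sample, spec, N = NULL, start = NULL,
                     control = list(iter.max = 1000, eval.max = 4000)) {
  stopifnot(inherits(spec, "lmi_model_spec"))
  sample$rho <- smooth_correlation_matrix(sample$rho)
  sm <- sample_moments(sample, spec)
  if (!identical(dim(sm$occ), dim(spec$occupancy)) ||
      !all(sm$occ == spec$occupancy)) {
    spec <- build_model(spec$level, spec$n_items, spec$n_sessions,
                        spec$n_categories, occupancy = sm$occ)
  }
  if (is.null(N)) N <- max(sample$n_var[seq_len(spec$n_items)])
  sv <- dwls_start_values(spec, sample, sm)
  if (!is.null(start)) sv <- utils::modifyList(sv, start)
  map <- make_param_map(spec, sv)
  w <- sm$weights; s <- sm$values
  objective <- function(par) {
    values <- values_from_par(par, map, spec)
    # guard: PD latent covariance (psi > 0 by the log transform)
    ch <- tryCatch(chol(values$phi), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    sigma <- implied_moment_vector(spec, values, sm)
    sum(w * (s - sigma)^2)
  }
  opt <- stats::nlminb(map$start, objective, control = control)
  est <- values_from_par(opt$par, map, spec)
  imp <- model_implied_moments(spec, est)
  heywood <- any(est$psi < 1e-2)
  structure(
    list(spec = spec, estimates = est, T_stat = max(opt$objective, 0),
         F_min = opt$objective, df = model_df(spec), N = N,
         implied_corr = imp$corr, implied_thresholds = imp$thresholds,
         converged = opt$convergence == 0 ||
           grepl("relative convergence|both X|singular convergence",
                 opt$message),
         n_iterations = opt$iterations, heywood = heywood,
         sample_moments = sm, param_map = map),
    class = "lmi_fit")
}

#' @export
print.lmi_fit <- function(x, ...) {
  cat(sprintf("LMI %s fit: T = %.3f, df = %d, N = %d (%s%s)\n",
              x$spec$level, x$T_stat, x$df, x$N,
              if (x$converged) "converged" else "NOT converged",
              if (x$heywood) "; Heywood pattern flagged" else ""))
  invisible(x)
}

#' Fit the full invariance sequence
#'
#' Fits the four nested levels (plus optionally the fixed-variance
#' constrained model) to the same sample moments, warm-starting each level
#' from the previous solution.
#'
#' @param sample output of [polychoric_matrix()].
#' @param n_items,n_sessions,n_categories design dimensions.
#' @param fixed_variance also fit the unique-factor model with all latent
#'   variances fixed to 1.
#' @param N analysis sample size (see [fit_dwls()]).
#' @return named list of `lmi_fit` objects.
#' @export
fit_lmi_sequence <- function(sample, n_items, n_sessions, n_categories = 4L,
                             fixed_variance = FALSE, N = NULL) {
  levels <- c("configural", "loadings", "threshold", "unique_factor")
  fits <- list()
  prev <- NULL
  for (lv in levels) {
    spec <- build_model(lv, n_items, n_sessions, n_categories)
    fits[[lv]] <- fit_dwls(sample, spec, N = N, start = prev)
    prev <- fits[[lv]]$estimates
  }
  if (fixed_variance) {
    spec <- fix_variance_constraint(
      build_model("unique_factor", n_items, n_sessions, n_categories))
    fits[["fixed_variance"]] <- fit_dwls(sample, spec, N = N, start = prev)
  }
  fits
}

#' Constant-SD reparameterization of a unique-factor fit
#'
#' Rescales a fitted parameter set so every session's latent variance is 1
#' while leaving the implied moments (and hence the fit statistic) exactly
#' unchanged: `lambda'_it = lambda_i * sqrt(phi_tt)`,
#' `alpha'_t = alpha_t / sqrt(phi_tt)`, `phi'_tt = 1`,
#' `phi'_ts = phi_ts / sqrt(phi_tt * phi_ss)`, `tau' = tau`, `psi' = psi`.
#' Under it the latent trajectory is expressed per-session-SD, at the cost
#' of session-varying loadings (measurement invariance no longer holds in
#' the parameter ledger).
#'
#' @param fit an `lmi_fit` (or a bare values list) with positive latent
#'   variances.
#' @return the reparameterized values list.
#' @export
constant_sd_reparameterization <- function(fit) {
  values <- if (inherits(fit, "lmi_fit")) fit$estimates else fit
  phi <- values$phi
  sdv <- sqrt(diag(phi))
  if (any(!is.finite(sdv)) || any(sdv <= 0))
    stop("latent variances must be positive", call. = FALSE)
  out <- values
  out$lambda <- sweep(values$lambda, 2L, sdv, `*`)
  out$alpha <- values$alpha / sdv
  out$phi <- phi / tcrossprod(sdv)
  diag(out$phi) <- 1
  out
}
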