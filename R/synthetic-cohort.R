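#' Configuration for a synthetic therapy cohort
#'
#' Defines the generating model for ordinal longitudinal item responses:
#' a unidimensional latent trait per session (with configurable trajectory,
#' cross-session correlation, and marginal family), a liability-threshold
#' measurement model per item, and monotone dropout.
#'
#' @param n_subjects,n_items,n_sessions design dimensions.
#' @param n_categories ordinal categories per item (default 4).
#' @param latent_means vector `alpha_t` of latent means per session
#'   (session-1 standard-deviation units).
#' @param latent_variances vector `phi_tt` of latent variances per session.
#' @param latent_corr either a `T x T` correlation matrix (must be symmetric
#'   positive definite) or a scalar AR(1) lag-1 correlation (default 0.8).
#' @param latent_family `"normal"`, `"lognormal_shifted"` (moment-matched to
#'   the configured mean/variance with `family_params$skewness` controlling
#'   shape), or `"davidian"` (`family_params$angles` give the curve).
#' @param family_params list of family parameters (see above).
#' @param loadings item loadings `lambda_i`; a length-`I` vector, or an
#'   `I x T` matrix for loading-noninvariance scenarios.
#' @param thresholds raw liability thresholds; an `I x (C-1)` matrix shared
#'   across sessions, or an `I x (C-1) x T` array for threshold-shift
#'   scenarios.  Must be strictly increasing in the category index.
#' @param unique_variances unique liability variances `psi_it`; scalar,
#'   length-`I` vector, or `I x T` matrix (default 1, the theta
#'   identification the invariance models use).
#' @param retention per-session retention proportions in `(0, 1]`,
#'   non-increasing, with `retention[1] == 1`; or `NULL` for no dropout.
#' @param dropout_logistic optional list
#'   `list(or = c(age = ..., gender = ...), baseline_retention = ...)`
#'   switching dropout to a discrete-time logistic hazard on standardized
#'   subject covariates; odds ratios multiply the per-session continuation
#'   odds implied by `baseline_retention`.
#' @param seed integer RNG seed; every generated array is a deterministic
#'   function of it.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_subjects, n_items, n_sessions,
                             n_categories = 4L,
                             latent_means = rep(0, n_sessions),
                             latent_variances = rep(1, n_sessions),
                             latent_corr = 0.8,
                             latent_family = c("normal", "lognormal_shifted",
                                               "davidian"),
                             family_params = list(),
                             loadings = NULL,
                             thresholds = NULL,
                             unique_variances = 1,
                             retention = NULL,
                             dropout_logistic = NULL,
                             seed = 1L) {
  latent_family <- match.arg(latent_family)
  I <- as.integer(n_items); TT <- as.integer(n_sessions)
  C <- as.integer(n_categories)
  stopifnot(n_subjects >= 1, I >= 1, TT >= 1, C >= 2)
  if (length(latent_means) != TT || length(latent_variances) != TT)
    stop("latent_means / latent_variances must have length n_sessions",
         call. = FALSE)
  if (any(latent_variances < 0))
    stop("latent_variances must be nonnegative", call. = FALSE)
  if (is.matrix(latent_corr)) {
    if (!isSymmetric(unname(latent_corr)) ||
        any(eigen(latent_corr, symmetric = TRUE,
                  only.values = TRUE)$values <= 1e-10))
      stop("latent_corr matrix must be symmetric positive definite",
           call. = FALSE)
    if (nrow(latent_corr) != TT)
      stop("latent_corr matrix must be n_sessions x n_sessions",
           call. = FALSE)
  } else if (abs(latent_corr) >= 1 && TT > 1) {
    stop("AR(1) lag correlation must be in (-1, 1)", call. = FALSE)
  }
  if (is.null(loadings)) loadings <- seq(0.7, 1.1, length.out = I)
  lam <- if (is.matrix(loadings)) loadings else
    matrix(loadings, nrow = I, ncol = TT)
  if (nrow(lam) != I || ncol(lam) != TT)
    stop("loadings must be length I or an I x T matrix", call. = FALSE)
  psi <- if (is.matrix(unique_variances)) unique_variances else
    matrix(unique_variances, nrow = I, ncol = TT)
  if (any(psi <= 0)) stop("unique_variances must be > 0", call. = FALSE)
  if (is.null(thresholds)) thresholds <- default_thresholds(lam, psi, C)
  tau <- if (length(dim(thresholds)) == 3L) thresholds else
    array(thresholds, dim = c(I, C - 1L, TT))
  if (!all(dim(tau) == c(I, C - 1L, TT)))
    stop("thresholds must be I x (C-1) [x T]", call. = FALSE)
  if (C > 2L) {
    dif <- apply(tau, c(1L, 3L), diff)
    if (any(dif <= 0, na.rm = TRUE))
      stop("thresholds must be strictly increasing in the category index",
           call. = FALSE)
  }
  if (!is.null(retention)) {
    if (length(retention) != TT)
      stop("retention schedule must have length n_sessions", call. = FALSE)
    if (any(retention <= 0 | retention > 1))
      stop("retention proportions must be in (0, 1]", call. = FALSE)
    if (any(diff(retention) > 1e-12))
      stop("retention must be non-increasing (monotone dropout)",
           call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_items = I, n_sessions = TT,
         n_categories = C, latent_means = as.numeric(latent_means),
         latent_variances = as.numeric(latent_variances),
         latent_corr = latent_corr, latent_family = latent_family,
         family_params = family_params, loadings = lam, thresholds = tau,
         unique_variances = psi, retention = retention,
         dropout_logistic = dropout_logistic, seed = as.integer(seed)),
    class = "synthetic_config")
}

# Baseline thresholds placing roughly (45, 30, 15, 10)% of mass in the four
# categories at session 1 (symptom reports are sparse at the top), mapped to
# the raw liability scale tau = z * sqrt(lambda^2 + psi) at alpha_1 = 0,
# phi_11 = 1.  For C != 4 an even-ish split with the same 45% floor is used.
default_thresholds <- function(lam, psi, C) {
  p0 <- if (C == 4L) c(0.45, 0.75, 0.90) else
    0.45 + (1 - 0.45) * seq_len(C - 1L) / C
  z <- qnorm(p0)
  I <- nrow(lam); TT <- ncol(lam)
  tau <- array(NA_real_, dim = c(I, C - 1L, TT))
  for (t in seq_len(TT))
    for (i in seq_len(I))
      tau[i, , t] <- z * sqrt(lam[i, 1L]^2 + psi[i, 1L])
  tau
}

#' Instrument-shaped preset configurations
#'
#' `"gad7"`: 7 four-category items over 13 weekly sessions with the anxiety
#' therapy's printed retention schedule (91% at session 2, 83% at session 3,
#' declining to 44% at session 12 and 10% at the follow-up session 13;
#' intermediate sessions interpolated linearly) and a linear latent decline
#' of 1.39 session-1 SD units over sessions 1..12.  `"bdi"`: 20 four-category
#' items at 4 assessment points with retention (1, .72, .46, .11) and a
#' decline of 1.23 units over the first three.
#'
#' @param instrument `"gad7"` or `"bdi"`.
#' @param n_subjects cohort size (defaults mirror the register: 2218 / 3922).
#' @param ... overrides passed on to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
preset_config <- function(instrument = c("gad7", "bdi"), n_subjects = NULL,
                          ...) {
  instrument <- match.arg(instrument)
  if (instrument == "gad7") {
    TT <- 13L
    ret <- c(1, 0.91, round(seq(0.83, 0.44, length.out = 10), 4), 0.10)
    alpha <- c(-1.39 * (0:11) / 11, -1.39)
    defaults <- list(n_subjects = if (is.null(n_subjects)) 2218L else
                       n_subjects,
                     n_items = 7L, n_sessions = TT, latent_means = alpha,
                     retention = ret)
  } else {
    TT <- 4L
    ret <- c(1, 0.72, 0.46, 0.11)
    alpha <- c(-1.23 * (0:2) / 2, -1.23)
    defaults <- list(n_subjects = if (is.null(n_subjects)) 3922L else
                       n_subjects,
                     n_items = 20L, n_sessions = TT, latent_means = alpha,
                     retention = ret)
  }
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# stage-specific deterministic substreams from the single config seed
stage_seed <- function(seed, stage) {
  offs <- c(latents = 11L, covariates = 29L, items = 47L, dropout = 83L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

# session correlation matrix from config (AR(1) scalar or full matrix)
latent_corr_matrix <- function(config) {
  TT <- config$n_sessions
  if (is.matrix(config$latent_corr)) return(unname(config$latent_corr))
  rho <- config$latent_corr
  outer(seq_len(TT), seq_len(TT), function(a, b) rho^abs(a - b))
}

#' Generate latent trait trajectories
#'
#' Draws one latent trait value per subject and session.  For the
#' `"normal"` family the session-`t` margin is `Normal(alpha_t, phi_tt)`
#' with the configured cross-session correlation.  `"lognormal_shifted"`
#' produces a unipolar (bounded-below) trait: a log-normal deviate with the
#' target skewness, shifted and scaled to the configured mean and variance,
#' coupled across sessions by a Gaussian copula.  `"davidian"` draws from a
#' squared-polynomial-times-normal density by inverse-CDF on a fine grid.
#'
#' @param config a `synthetic_config`.
#' @return `n_subjects x n_sessions` numeric matrix.
#' @export
generate_latent_trajectories <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stage_seed(config$seed, "latents"))
  n <- config$n_subjects; TT <- config$n_sessions
  R <- latent_corr_matrix(config)
  L <- tryCatch(chol(R), error = function(e)
    stop("latent correlation matrix is not positive definite",
         call. = FALSE))
  Z <- matrix(rnorm(n * TT), n, TT) %*% L
  alpha <- config$latent_means; phi <- config$latent_variances
  theta <- switch(
    config$latent_family,
    normal = sweep(sweep(Z, 2L, sqrt(phi), `*`), 2L, alpha, `+`),
    lognormal_shifted = {
      gamma <- config$family_params$skewness
      if (is.null(gamma)) gamma <- 1.5
      sgn <- sign(gamma); gamma <- abs(gamma)
      if (gamma <= 0) stop("lognormal_shifted needs nonzero skewness",
                           call. = FALSE)
      # solve (w + 2) sqrt(w - 1) = gamma for w = exp(sigma^2)
      w <- uniroot(function(w) (w + 2) * sqrt(w - 1) - gamma,
                   c(1 + 1e-12, 1e6), tol = 1e-12)$root
      sigma <- sqrt(log(w))
      mu_w <- exp(sigma^2 / 2)
      sd_w <- sqrt(exp(sigma^2) * (exp(sigma^2) - 1))
      W <- sgn * (exp(sigma * Z) - mu_w) / sd_w
      sweep(sweep(W, 2L, sqrt(phi), `*`), 2L, alpha, `+`)
    },
    davidian = {
      angles <- config$family_params$angles
      if (is.null(angles))
        stop("davidian family needs family_params$angles", call. = FALSE)
      dens <- davidian_density(length(angles), angles)
      q <- davidian_quantile_fun(dens, standardize = TRUE)
      U <- pnorm(Z)
      sweep(sweep(apply(U, 2L, q), 2L, sqrt(phi), `*`), 2L, alpha, `+`)
    },
    stop("unknown latent family", call. = FALSE))
  unname(theta)
}

# subject covariates driving the logistic dropout model
generate_covariates <- function(config) {
  set.seed(stage_seed(config$seed, "covariates"))
  n <- config$n_subjects
  data.frame(age = rnorm(n), gender = rbinom(n, 1L, 0.5))
}

#' Render ordinal item responses from latent trajectories
#'
#' Liability-threshold link: `y*_ist = lambda_it * theta_st + e`,
#' `e ~ Normal(0, psi_it)` independent over items; the recorded category is
#' the number of thresholds `tau_i.t` lying below `y*`.
#'
#' @param latents `n x T` matrix from [generate_latent_trajectories()].
#' @param config the `synthetic_config` (supplies measurement parameters).
#' @return a [longitudinal_ordinal_data()] object (no missingness yet).
#' @export
render_ordinal_items <- function(latents, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stage_seed(config$seed, "items"))
  n <- nrow(latents); I <- config$n_items; TT <- config$n_sessions
  resp <- array(NA_integer_, dim = c(n, I, TT))
  for (t in seq_len(TT)) {
    for (i in seq_len(I)) {
      y <- config$loadings[i, t] * latents[, t] +
        rnorm(n, sd = sqrt(config$unique_variances[i, t]))
      tau <- config$thresholds[i, , t]
      resp[, i, t] <- findInterval(y, tau)
    }
  }
  longitudinal_ordinal_data(resp, n_categories = config$n_categories,
                            covariates = generate_covariates(config),
                            check_monotone = FALSE)
}

#' Apply monotone dropout to a rendered cohort
#'
#' Schedule mode: subjects continue session-to-session with probability
#' `retention[t] / retention[t-1]`, so the expected observed fraction at
#' session `t` equals `retention[t]` exactly.  Logistic mode: per-session
#' continuation odds are the schedule's baseline odds multiplied by the
#' configured odds ratios applied to the subject's standardized covariates
#' (a discrete-time logistic hazard).  Dropout is absorbing.
#'
#' @param data a `longitudinal_ordinal_data` from [render_ordinal_items()].
#' @param config the `synthetic_config`.
#' @return the data with post-dropout sessions set to `NA`.
#' @export
apply_dropout <- function(data, config) {
  stopifnot(inherits(config, "synthetic_config"))
  TT <- config$n_sessions
  n <- dim(data$responses)[1L]
  if (is.null(config$retention) && is.null(config$dropout_logistic))
    return(data)
  set.seed(stage_seed(config$seed, "dropout"))
  logis <- config$dropout_logistic
  ret <- if (!is.null(logis)) logis$baseline_retention else config$retention
  if (is.null(ret)) ret <- config$retention
  if (is.null(ret)) stop("no retention schedule available", call. = FALSE)
  if (any(ret <= 0 | ret > 1))
    stop("retention proportions must be in (0, 1]", call. = FALSE)
  cont <- c(1, ret[-1L] / ret[-TT])    # per-session continuation probs
  eta_cov <- rep(0, n)
  if (!is.null(logis)) {
    or <- logis$or
    cov <- data$covariates
    if (is.null(cov)) stop("logistic dropout needs covariates", call. = FALSE)
    for (nm in names(or)) {
      x <- cov[[nm]]
      if (is.null(x)) stop("missing covariate: ", nm, call. = FALSE)
      x <- (x - mean(x)) / stats::sd(x)
      eta_cov <- eta_cov + log(or[[nm]]) * x
    }
  }
  alive <- rep(TRUE, n)
  for (t in seq_len(TT)[-1L]) {
    p <- plogis(qlogis(pmin(pmax(cont[t], 1e-12), 1 - 1e-12)) + eta_cov)
    if (cont[t] >= 1) p <- rep(1, n)
    alive <- alive & (runif(n) < p)
    if (any(!alive)) data$responses[!alive, , t] <- NA_integer_
  }
  data
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: latent trajectories, ordinal rendering, and dropout
#' in one call.  Deterministic given `config$seed`.
#'
#' @param config a `synthetic_config`.
#' @return a `longitudinal_ordinal_data` with the config attached as
#'   attribute `"config"`.
#' @export
generate_cohort <- function(config) {
  theta <- generate_latent_trajectories(config)
  data <- render_ordinal_items(theta, config)
  data <- apply_dropout(data, config)
  attr(data, "config") <- config
  attr(data, "latents") <- theta
  data
}
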