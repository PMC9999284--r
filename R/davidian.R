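# ---- Davidian-curve latent densities -------------------------------------
#
# A Davidian curve of order k is h(z) = P_k(z)^2 * phi(z) with P_k a degree-k
# polynomial constrained so h integrates to 1.  Writing the coefficient
# vector c, the constraint is c' M c = 1 with M the (k+1) x (k+1) Hankel
# matrix of standard-normal moments; parameterizing c = M^{-1/2} u with u a
# unit vector expressed in spherical angles makes the constraint automatic
# and leaves k free angles.  Order 0 is exactly the standard normal.

# standard normal raw moments 0..(2k)
normal_moments <- function(upto) {
  m <- numeric(upto + 1L)
  m[1L] <- 1
  for (j in seq_len(upto)) {
    m[j + 1L] <- if (j %% 2L == 1L) 0 else prod(seq(1, j - 1, by = 2))
  }
  m
}

moment_matrix_sqrt <- function(k) {
  mu <- normal_moments(2L * k)
  M <- outer(0:k, 0:k, function(a, b) mu[a + b + 1L])
  e <- eigen(M, symmetric = TRUE)
  list(M = M,
       half = e$vectors %*% (sqrt(e$values) * t(e$vectors)),
       invhalf = e$vectors %*% (1 / sqrt(e$values) * t(e$vectors)))
}

unit_vector_from_angles <- function(angles) {
  k <- length(angles)
  u <- numeric(k + 1L)
  s <- 1
  for (j in seq_len(k)) {
    u[j] <- s * cos(angles[j])
    s <- s * sin(angles[j])
  }
  u[k + 1L] <- s
  u
}

angles_from_unit_vector <- function(u) {
  k <- length(u) - 1L
  if (k == 0L) return(numeric(0))
  angles <- numeric(k)
  s <- 1
  for (j in seq_len(k)) {
    val <- u[j] / s
    angles[j] <- acos(min(max(val, -1), 1))
    s <- s * sin(angles[j])
    if (abs(s) < 1e-14) { s <- sign(s + 1e-300) * 1e-14 }
  }
  angles
}

#' Construct a Davidian latent density
#'
#' @param order polynomial order `k` in `[0, 10]`.
#' @param angles `k` spherical angles (the estimable coefficients); the
#'   default gives the standard normal member of the family.
#' @return object of class `davidian_density` with the derived polynomial
#'   coefficients.
#' @export
davidian_density <- function(order, angles = NULL) {
  k <- as.integer(order)
  if (k < 0L || k > 10L) stop("order must be in [0, 10]", call. = FALSE)
  ms <- moment_matrix_sqrt(k)
  if (is.null(angles)) {
    u <- ms$half[, 1L]          # c = e1: the standard normal
    angles <- angles_from_unit_vector(u / sqrt(sum(u^2)))
  }
  if (length(angles) != k)
    stop("need exactly `order` angles", call. = FALSE)
  if (any(!is.finite(angles))) stop("angles must be finite", call. = FALSE)
  u <- unit_vector_from_angles(angles)
  coeffs <- as.vector(ms$invhalf %*% u)
  structure(list(order = k, angles = angles, coefficients = coeffs,
                 standardization = c(location = 0, scale = 1)),
            class = "davidian_density")
}

#' Evaluate a Davidian density
#'
#' @param z evaluation points.
#' @param density a `davidian_density`.
#' @return `h(z) = P_k(z)^2 * dnorm(z)`, nonnegative and integrating to 1.
#' @export
davidian_pdf <- function(z, density) {
  cf <- density$coefficients
  P <- rep(cf[1L], length(z))
  zp <- rep(1, length(z))
  for (j in seq_along(cf)[-1L]) {
    zp <- zp * z
    P <- P + cf[j] * zp
  }
  P^2 * dnorm(z)
}

#' Moments and standardized grid of a Davidian density
#'
#' Mean, variance and skewness by rectangular quadrature on `[-10, 10]`
#' (2001 points), plus an evaluation grid rescaled to mean 0 and variance 1
#' for cross-session shape comparison.
#'
#' @param density a `davidian_density`.
#' @param n_grid quadrature points.
#' @return list with `mean`, `variance`, `skewness` and a data.frame
#'   `standardized_grid` (columns `z`, `h`).
#' @export
density_summary <- function(density, n_grid = 2001L) {
  z <- seq(-10, 10, length.out = n_grid)
  dz <- z[2L] - z[1L]
  h <- davidian_pdf(z, density)
  m0 <- sum(h) * dz
  m <- sum(z * h) * dz / m0
  v <- sum((z - m)^2 * h) * dz / m0
  sk <- sum((z - m)^3 * h) * dz / m0 / v^1.5
  zs <- (z - m) / sqrt(v)
  list(mean = m, variance = v, skewness = sk,
       standardized_grid = data.frame(z = zs, h = h * sqrt(v)))
}

# inverse-CDF sampler support for the synthetic generator
davidian_quantile_fun <- function(density, standardize = TRUE,
                                  n_grid = 4001L) {
  z <- seq(-10, 10, length.out = n_grid)
  dz <- z[2L] - z[1L]
  h <- davidian_pdf(z, density)
  cdf <- cumsum(h) * dz
  cdf <- cdf / cdf[n_grid]
  keep <- c(TRUE, diff(cdf) > 0)
  qf <- approxfun(cdf[keep], z[keep], rule = 2)
  if (!standardize) return(qf)
  s <- density_summary(density)
  function(u) (qf(u) - s$mean) / sqrt(s$variance)
}

# ---- graded-response measurement with a Davidian latent density ----------

# per-item category log-probabilities on the quadrature grid;
# pars = c(log a, b1, log(b2 - b1), ...) for a logistic graded model
graded_logprob <- function(pars, zq, C) {
  a <- exp(pars[1L])
  b <- pars[2L]
  if (C > 2L) b <- c(b, b[1L] + cumsum(exp(pars[3:C])))
  Fge <- rbind(1, plogis(a * outer(b, zq, function(b, z) z - b)), 0)
  P <- Fge[seq_len(C), , drop = FALSE] - Fge[-1L, , drop = FALSE]
  log(pmax(P, 1e-300))
}

#' Fit a graded-response model with a Davidian-curve latent density
#'
#' Marginal maximum likelihood by EM on a fixed quadrature grid: posterior
#' weights given current parameters, then per-item logistic graded-response
#' updates and a density-angle update per iteration.  The latent location
#' and scale are not separately identified from the item parameters (the
#' usual ridge); reported density shape should be read through
#' [density_summary()], whose skewness is affine-invariant.
#'
#' @param responses `n x I` integer matrix (categories `0..C-1`) for one
#'   session; rows with missing values are dropped.
#' @param order Davidian polynomial order `k`.
#' @param n_categories number of categories (default: observed max + 1).
#' @param grid quadrature nodes (default 101 equispaced on `[-6, 6]`).
#' @param max_iter,tol EM control: stop when the marginal log-likelihood
#'   gain of a plain EM step drops below `tol` (default 1e-4, the
#'   customary EM tolerance for marginal-likelihood IRT; the likelihood is
#'   near-flat along the latent location-scale direction, so far tighter
#'   tolerances buy no change in the density shape).  Periodic
#'   squared-extrapolation jumps accelerate the slow direction and are
#'   accepted only when they improve the likelihood.
#' @return list with `items` (per-item `a`, `b`), `density`
#'   (`davidian_density`), `loglik`, `n_params`, `n`, `converged`,
#'   `n_iterations`, `loglik_trace`.
#' @export
fit_graded_davidian <- function(responses, order, n_categories = NULL,
                                grid = seq(-6, 6, length.out = 101L),
                                max_iter = 2000L, tol = 1e-4) {
  responses <- as.matrix(responses)
  cc <- stats::complete.cases(responses)
  if (!all(cc)) responses <- responses[cc, , drop = FALSE]
  n <- nrow(responses); I <- ncol(responses)
  if (I < 3L) stop("need at least 3 items", call. = FALSE)
  if (n < 10L) stop("too few complete cases", call. = FALSE)
  if (is.null(n_categories)) n_categories <- max(responses) + 1L
  # collapse categories that never occur (from the top down)
  y <- responses
  C_i <- integer(I)
  for (i in seq_len(I)) {
    used <- sort(unique(y[, i]))
    if (length(used) < 2L)
      stop("item ", i, " has a single occupied category", call. = FALSE)
    if (length(used) < n_categories) {
      warning("item ", i, ": empty categories collapsed", call. = FALSE)
      y[, i] <- match(y[, i], used) - 1L
    }
    C_i[i] <- length(used)
  }
  # unique response patterns for a fast E-step
  key <- apply(y, 1L, paste, collapse = ",")
  tab <- table(key)
  upat <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  wts <- as.numeric(tab)
  np <- nrow(upat); Q <- length(grid)

  dens <- davidian_density(order)        # start at the normal member
  angles <- dens$angles
  item_pars <- lapply(seq_len(I), function(i) {
    pr <- tabulate(y[, i] + 1L, nbins = C_i[i]) / n
    cum <- cumsum(pr)[seq_len(C_i[i] - 1L)]
    b <- qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
    c(0, b[1L], if (C_i[i] > 2L) log(pmax(diff(b), 1e-3)))
  })

  # flat parameter vector <-> (item_pars, angles)
  n_ip <- lengths(item_pars)
  unflatten <- function(par) {
    split_ip <- split(par[seq_len(sum(n_ip))],
                      rep(seq_len(I), times = n_ip))
    list(items = unname(split_ip),
         angles = par[sum(n_ip) + seq_len(order)])
  }
  posterior_parts <- function(par) {
    th <- unflatten(par)
    logL <- matrix(0, np, Q)
    for (i in seq_len(I))
      logL <- logL + graded_logprob(th$items[[i]], grid,
                                    C_i[i])[upat[, i] + 1L, ]
    h <- davidian_pdf(grid, davidian_density(order, th$angles))
    logpost <- sweep(logL, 2L, log(pmax(h / sum(h), 1e-300)), `+`)
    mx <- apply(logpost, 1L, max)
    pw <- exp(logpost - mx)
    rs <- rowSums(pw)
    list(ll = sum(wts * (log(rs) + mx)), pw = pw, rs = rs, th = th)
  }
  em_step <- function(par, pp = posterior_parts(par)) {
    post <- (wts / pp$rs) * pp$pw               # np x Q expected weights
    th <- pp$th
    for (i in seq_len(I)) {
      ric <- rowsum(post, group = upat[, i])    # C_i x Q expected counts
      obj <- function(p) -sum(ric * graded_logprob(p, grid, C_i[i]))
      th$items[[i]] <- stats::nlminb(th$items[[i]], obj,
                                     control = list(iter.max = 50))$par
    }
    if (order > 0L) {
      rq <- colSums(post)
      objd <- function(a) {
        hh <- davidian_pdf(grid, davidian_density(order, a))
        -sum(rq * log(pmax(hh / sum(hh), 1e-300)))
      }
      th$angles <- stats::nlminb(th$angles, objd,
                                 control = list(iter.max = 50))$par
    }
    c(unlist(th$items), th$angles)
  }
  # Plain EM with a periodic squared-extrapolation jump: the marginal
  # likelihood is nearly flat along the latent location-scale direction,
  # which makes unaccelerated EM crawl.  Every few iterations a SQUAREM
  # candidate built from the last three iterates is tried and accepted
  # only when it improves the likelihood, so the trace stays monotone.
  par <- c(unlist(item_pars), angles)
  hist <- list()
  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  iter <- 0L
  jumped <- FALSE
  repeat {
    iter <- iter + 1L
    pp <- posterior_parts(par)
    ll <- pp$ll
    loglik_trace <- c(loglik_trace, ll)
    if (ll < prev_ll - 1e-6)
      warning("EM log-likelihood decreased by ",
              format(prev_ll - ll), call. = FALSE)
    if (is.finite(prev_ll) && !jumped && abs(ll - prev_ll) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    prev_ll <- ll
    par <- em_step(par, pp)
    hist <- c(hist, list(par))
    if (length(hist) > 3L) hist <- hist[-1L]
    jumped <- FALSE
    if (iter %% 5L == 0L && length(hist) == 3L) {
      r <- hist[[2L]] - hist[[1L]]
      v <- hist[[3L]] - 2 * hist[[2L]] + hist[[1L]]
      a_sq <- min(-sqrt(sum(r^2)) / max(sqrt(sum(v^2)), 1e-12), -1)
      cand <- hist[[1L]] - 2 * a_sq * r + a_sq^2 * v
      if (all(is.finite(cand))) {
        ll_cand <- tryCatch(posterior_parts(cand)$ll,
                            error = function(e) -Inf)
        if (is.finite(ll_cand) &&
            ll_cand > posterior_parts(par)$ll) {
          par <- cand
          hist <- list()
          jumped <- TRUE
        }
      }
    }
  }
  th <- unflatten(par)
  item_pars <- th$items
  angles <- th$angles
  items <- lapply(seq_len(I), function(i) {
    p <- item_pars[[i]]; C <- C_i[i]
    b <- p[2L]
    if (C > 2L) b <- c(b, b[1L] + cumsum(exp(p[3:C])))
    list(a = exp(p[1L]), b = b)
  })
  list(items = items, density = davidian_density(order, angles),
       loglik = loglik_trace[length(loglik_trace)],
       n_params = sum(C_i) + order, n = n, converged = converged,
       n_iterations = iter, loglik_trace = loglik_trace)
}

#' Hannan-Quinn information criterion
#'
#' `-2 loglik + 2 k log(log n)`.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters `k`.
#' @param n_subjects sample size (must exceed `e`).
#' @return HQ value (smaller is better).
#' @export
hannan_quinn <- function(loglik, n_params, n_subjects) {
  if (n_subjects <= exp(1))
    stop("sample size must exceed e for the HQ penalty", call. = FALSE)
  -2 * loglik + 2 * n_params * log(log(n_subjects))
}

#' Select the Davidian polynomial order by Hannan-Quinn
#'
#' Fits each candidate order and returns the HQ-minimizing one (ties broken
#' toward the smaller order); non-converging orders are dropped with a
#' warning.
#'
#' @param responses as in [fit_graded_davidian()].
#' @param orders candidate orders (default 3:7).
#' @param ... passed to [fit_graded_davidian()].
#' @return list with `order` (selected), `fit` (its fit), `table`
#'   (data.frame order / loglik / n_params / hq / converged).
#' @export
select_order <- function(responses, orders = 3:7, ...) {
  if (!length(orders)) stop("orders must be nonempty", call. = FALSE)
  fits <- list(); rows <- list()
  for (k in orders) {
    f <- tryCatch(fit_graded_davidian(responses, k, ...),
                  error = function(e) NULL)
    ok <- !is.null(f) && f$converged
    if (!is.null(f)) {
      fits[[as.character(k)]] <- f
      rows[[as.character(k)]] <- data.frame(
        order = k, loglik = f$loglik, n_params = f$n_params,
        hq = hannan_quinn(f$loglik, f$n_params, f$n), converged = ok)
    }
    if (!ok) warning("order ", k, " did not converge; dropped from ",
                     "selection", call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  usable <- tab[tab$converged, , drop = FALSE]
  if (!nrow(usable)) stop("no candidate order converged", call. = FALSE)
  best <- usable$order[which.min(usable$hq)]   # which.min takes first tie
  list(order = best, fit = fits[[as.character(best)]], table = tab)
}
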