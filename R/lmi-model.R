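#' Build a longitudinal measurement-invariance model specification
#'
#' Constructs the parameter ledger for one level of the nested invariance
#' sequence for `I` ordinal items measured at `T` sessions with `C`
#' categories, under the theta-style identification in which the
#' *configural* model fixes all latent means to 0, all latent variances to
#' 1, and all unique liability variances to 1, with loadings and thresholds
#' free per (item, session) and all cross-session latent covariances free:
#'
#' * `configural`: as above.
#' * `loadings`: loadings equated across sessions within item; latent
#'   variances freed for sessions `t > 1`.
#' * `threshold`: additionally equates thresholds across sessions within
#'   (item, category); latent means and unique variances freed for `t > 1`.
#' * `unique_factor`: re-fixes all unique variances to 1.
#'
#' Each ledger row records one parameter instance and its status
#' (`free`, `fixed` with a value, or `equal` with a group id).  Model
#' degrees of freedom are `#sample moments - #free parameters`, with
#' moments = occupied thresholds + all pairwise polychoric correlations.
#'
#' @param level one of `"configural"`, `"loadings"`, `"threshold"`,
#'   `"unique_factor"`.
#' @param n_items,n_sessions,n_categories design dimensions (`I >= 3`,
#'   `T >= 1`, `C >= 2`).
#' @param occupancy optional logical `I x (C-1) x T` array marking which
#'   item-category thresholds exist in the data (empty item-category cells
#'   reduce both the moment count and, when empty at every session, the
#'   threshold parameter count).  Default: all occupied.
#' @return an object of class `lmi_model_spec`.
#' @export
build_model <- function(level, n_items, n_sessions, n_categories,
                        occupancy = NULL) {
  levels_ok <- c("configural", "loadings", "threshold", "unique_factor")
  if (!is.character(level) || length(level) != 1L || !level %in% levels_ok)
    stop("unsupported level; use one of ",
         paste(levels_ok, collapse = ", "), call. = FALSE)
  I <- as.integer(n_items); TT <- as.integer(n_sessions)
  C <- as.integer(n_categories)
  if (I < 3L) stop("need at least 3 items", call. = FALSE)
  if (TT < 1L) stop("need at least 1 session", call. = FALSE)
  if (C < 2L) stop("need at least 2 categories", call. = FALSE)
  if (is.null(occupancy)) occupancy <- array(TRUE, dim = c(I, C - 1L, TT))
  stopifnot(all(dim(occupancy) == c(I, C - 1L, TT)))
  # with one session no longitudinal constraint is expressible: all levels
  # collapse to the configural ledger
  eff <- if (TT == 1L) "configural" else level
  blank <- function(n) rep(NA_integer_, n)
  # loadings: one row per (item, session)
  it <- rep(seq_len(I), times = TT); tt <- rep(seq_len(TT), each = I)
  lam <- data.frame(
    param = "lambda", item = it, category = blank(I * TT), session = tt,
    session2 = blank(I * TT),
    status = if (eff == "configural") "free" else "equal",
    value = NA_real_,
    group = if (eff == "configural") NA_character_ else paste0("lam", it))
  # thresholds: one row per occupied (item, category, session)
  w <- which(occupancy, arr.ind = TRUE)
  w <- w[order(w[, 3L], w[, 1L], w[, 2L]), , drop = FALSE]
  tau <- data.frame(
    param = "tau", item = as.integer(w[, 1L]),
    category = as.integer(w[, 2L]), session = as.integer(w[, 3L]),
    session2 = blank(nrow(w)),
    status = if (eff %in% c("configural", "loadings")) "free" else "equal",
    value = NA_real_,
    group = if (eff %in% c("configural", "loadings")) NA_character_ else
      paste0("tau", w[, 1L], "_", w[, 2L]))
  # unique variances: free for t > 1 only at the threshold level
  psi_free <- eff == "threshold" & tt > 1L
  psi <- data.frame(
    param = "psi", item = it, category = blank(I * TT), session = tt,
    session2 = blank(I * TT),
    status = ifelse(psi_free, "free", "fixed"),
    value = ifelse(psi_free, NA_real_, 1), group = NA_character_)
  # latent means and variances
  ts <- seq_len(TT)
  a_free <- eff %in% c("threshold", "unique_factor") & ts > 1L
  alpha <- data.frame(
    param = "alpha", item = blank(TT), category = blank(TT), session = ts,
    session2 = blank(TT), status = ifelse(a_free, "free", "fixed"),
    value = ifelse(a_free, NA_real_, 0), group = NA_character_)
  v_free <- eff != "configural" & ts > 1L
  phiv <- data.frame(
    param = "phi_var", item = blank(TT), category = blank(TT),
    session = ts, session2 = blank(TT),
    status = ifelse(v_free, "free", "fixed"),
    value = ifelse(v_free, NA_real_, 1), group = NA_character_)
  parts <- list(lam, tau, psi, alpha, phiv)
  if (TT > 1L) {
    pr <- which(upper.tri(diag(TT)), arr.ind = TRUE)
    parts$phic <- data.frame(
      param = "phi_cov", item = blank(nrow(pr)), category = blank(nrow(pr)),
      session = as.integer(pr[, 1L]), session2 = as.integer(pr[, 2L]),
      status = "free", value = NA_real_, group = NA_character_)
  }
  ledger <- do.call(rbind, parts)
  rownames(ledger) <- NULL
  structure(
    list(level = level, n_items = I, n_sessions = TT, n_categories = C,
         occupancy = occupancy, ledger = ledger,
         extra_constraints = character()),
    class = "lmi_model_spec")
}

# number of free parameters counted by enumerating ledger rows
n_free_params <- function(spec) {
  led <- spec$ledger
  sum(led$status == "free") +
    length(unique(led$group[led$status == "equal"]))
}

# number of non-redundant sample moments
n_sample_moments <- function(spec) {
  p <- spec$n_items * spec$n_sessions
  sum(spec$occupancy) + p * (p - 1L) / 2L
}

#' Model degrees of freedom from the parameter ledger
#' @param spec an `lmi_model_spec`.
#' @return integer df = moments - free parameters.
#' @export
model_df <- function(spec) {
  stopifnot(inherits(spec, "lmi_model_spec"))
  as.integer(n_sample_moments(spec) - n_free_params(spec))
}

#' @export
print.lmi_model_spec <- function(x, ...) {
  cat(sprintf("LMI model spec: level = %s (I = %d, T = %d, C = %d)\n",
              x$level, x$n_items, x$n_sessions, x$n_categories))
  cat(sprintf("  free parameters: %d; sample moments: %d; df = %d\n",
              n_free_params(x), n_sample_moments(x), model_df(x)))
  if (length(x$extra_constraints))
    cat("  extra constraints:", paste(x$extra_constraints, collapse = "; "),
        "\n")
  invisible(x)
}

#' Degrees-of-freedom difference between two model specs
#'
#' @param spec_a,spec_b two `lmi_model_spec`s on the same design; `spec_b`
#'   is conventionally the more constrained one.  A warning flag attribute
#'   is set when the levels are not nested in the canonical order.
#' @return integer `df(spec_b) - df(spec_a)`, attribute `"nested"`.
#' @export
delta_df <- function(spec_a, spec_b) {
  stopifnot(inherits(spec_a, "lmi_model_spec"),
            inherits(spec_b, "lmi_model_spec"))
  if (spec_a$n_items != spec_b$n_items ||
      spec_a$n_sessions != spec_b$n_sessions ||
      spec_a$n_categories != spec_b$n_categories)
    stop("specs must share the same design (I, T, C)", call. = FALSE)
  ord <- c(configural = 1L, loadings = 2L, threshold = 3L,
           unique_factor = 4L)
  nested <- ord[[spec_a$level]] <= ord[[spec_b$level]]
  if (!nested) warning("specs are not nested in the canonical order",
                       call. = FALSE)
  structure(model_df(spec_b) - model_df(spec_a), nested = nested)
}

#' Add the fixed-latent-variance constraint
#'
#' Takes a unique-factor invariance spec and additionally fixes the latent
#' variance to 1 at every session (sessions `t > 1`; session 1 is already
#' fixed by identification), adding `T - 1` constraints and degrees of
#' freedom.
#'
#' @param spec a `unique_factor` level `lmi_model_spec`.
#' @return the constrained spec.
#' @export
fix_variance_constraint <- function(spec) {
  stopifnot(inherits(spec, "lmi_model_spec"))
  if (spec$level != "unique_factor")
    stop("fixed-variance constraint applies to the unique_factor model",
         call. = FALSE)
  if (spec$n_sessions == 1L) return(spec)
  led <- spec$ledger
  sel <- led$param == "phi_var" & led$status == "free"
  led$status[sel] <- "fixed"
  led$value[sel] <- 1
  spec$ledger <- led
  spec$extra_constraints <- c(spec$extra_constraints,
                              "phi_tt = 1 for all sessions")
  spec
}

#' Serialize / deserialize a model spec as JSON
#' @param spec an `lmi_model_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  obj <- list(level = spec$level, n_items = spec$n_items,
              n_sessions = spec$n_sessions,
              n_categories = spec$n_categories,
              occupancy = spec$occupancy,
              extra_constraints = spec$extra_constraints,
              ledger = spec$ledger)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
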