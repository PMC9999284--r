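#' Longitudinal ordinal response data
#'
#' The pipeline's single input container: an `n_subjects x n_items x
#' n_sessions` integer array of ordinal responses in `0..C-1` with `NA`
#' marking missing values, plus optional per-subject covariates used by the
#' logistic dropout model.
#'
#' @param responses integer array (subject x item x session); `NA` = missing.
#' @param n_categories number of ordinal categories `C` (responses must lie
#'   in `0..C-1`).
#' @param item_labels,session_labels optional dimension labels.
#' @param covariates optional data.frame with one row per subject.
#' @param check_monotone if `TRUE`, warn when observed sessions do not form
#'   a prefix (generated cohorts are always monotone; imported data may not
#'   be).
#' @return an object of class `longitudinal_ordinal_data`.
#' @export
longitudinal_ordinal_data <- function(responses, n_categories = 4L,
                                      item_labels = NULL,
                                      session_labels = NULL,
                                      covariates = NULL,
                                      check_monotone = TRUE) {
  if (length(dim(responses)) != 3L)
    stop("`responses` must be a 3-d array (subject x item x session)",
         call. = FALSE)
  vals <- responses[!is.na(responses)]
  if (length(vals) && (any(vals != round(vals)) || any(vals < 0) ||
                       any(vals >= n_categories)))
    stop("non-missing responses must be integers in 0..C-1", call. = FALSE)
  d <- dim(responses)
  if (is.null(item_labels)) item_labels <- paste0("item", seq_len(d[2]))
  if (is.null(session_labels)) session_labels <- paste0("s", seq_len(d[3]))
  if (!is.null(covariates) && nrow(covariates) != d[1])
    stop("covariates must have one row per subject", call. = FALSE)
  obj <- structure(
    list(responses = responses, n_categories = as.integer(n_categories),
         item_labels = item_labels, session_labels = session_labels,
         covariates = covariates),
    class = "longitudinal_ordinal_data")
  if (check_monotone && !is_monotone_missing(obj))
    warning("observed sessions do not form a prefix for every subject",
            call. = FALSE)
  obj
}

#' @export
print.longitudinal_ordinal_data <- function(x, ...) {
  d <- dim(x$responses)
  cat("Longitudinal ordinal data:", d[1], "subjects x", d[2], "items x",
      d[3], "sessions,", x$n_categories, "categories\n")
  obs <- colSums(!is.na(x$responses[, 1L, , drop = FALSE]))
  cat("subjects observed per session:",
      paste(as.vector(obs), collapse = " "), "\n")
  invisible(x)
}

#' Check for monotone (prefix) missingness
#'
#' TRUE when, for every subject, the sessions with any observed item form a
#' prefix 1..L of the session sequence (no return after dropout).
#' @param data a `longitudinal_ordinal_data` object.
#' @return logical scalar.
#' @export
is_monotone_missing <- function(data) {
  obs <- apply(!is.na(data$responses), c(1L, 3L), any)  # subject x session
  all(apply(obs, 1L, function(o) {
    w <- which(o)
    length(w) == 0L || identical(w, seq_len(length(w)))
  }))
}

#' Number of subjects observed at each session
#' @param data a `longitudinal_ordinal_data` object.
#' @return integer vector of per-session counts (any observed item counts).
#' @export
n_per_session <- function(data) {
  as.integer(colSums(apply(!is.na(data$responses), c(1L, 3L), any)))
}

#' Flatten to a subject x (item, session) response matrix
#'
#' Columns are ordered session-major (all items of session 1, then session
#' 2, ...), the variable ordering used throughout the invariance models.
#' @param data a `longitudinal_ordinal_data` object.
#' @return integer matrix with `NA` for missing; column names `item@session`.
#' @export
flatten_responses <- function(data) {
  d <- dim(data$responses)
  m <- matrix(aperm(data$responses, c(1L, 2L, 3L)), nrow = d[1])
  colnames(m) <- as.vector(outer(data$item_labels, data$session_labels,
                                 paste, sep = "@"))
  m
}

#' Write a cohort as long-format CSV (with a JSON config sidecar)
#'
#' Emits columns `subject_id, session, item, response` with blank cells for
#' missing responses; rows for sessions after a subject's dropout are
#' omitted entirely.
#'
#' @param data a `longitudinal_ordinal_data` object.
#' @param path output CSV path.
#' @param config optional `synthetic_config` written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path, config = NULL) {
  d <- dim(data$responses)
  long <- data.frame(
    subject_id = rep(seq_len(d[1]), times = d[2] * d[3]),
    session = rep(seq_len(d[3]), each = d[1] * d[2]),
    item = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    response = as.vector(data$responses))
  # drop fully-missing subject-sessions (post-dropout), keep order stable
  obs_ss <- apply(!is.na(data$responses), c(1L, 3L), any)
  keep <- obs_ss[cbind(long$subject_id, long$session)]
  long <- long[keep, , drop = FALSE]
  long <- long[order(long$subject_id, long$session, long$item), ]
  utils::write.csv(long, path, row.names = FALSE, na = "")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(path)
}

#' Read a long-format cohort CSV
#'
#' @param path CSV with columns `subject_id, session, item, response`.
#' @param n_categories number of ordinal categories.
#' @return a `longitudinal_ordinal_data` object.
#' @export
read_cohort_csv <- function(path, n_categories = 4L) {
  long <- utils::read.csv(path)
  need <- c("subject_id", "session", "item", "response")
  if (!all(need %in% names(long)))
    stop("cohort CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  subj <- sort(unique(long$subject_id))
  arr <- array(NA_integer_,
               dim = c(length(subj), max(long$item), max(long$session)))
  arr[cbind(match(long$subject_id, subj), long$item, long$session)] <-
    as.integer(long$response)
  longitudinal_ordinal_data(arr, n_categories = n_categories)
}
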