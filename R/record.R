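#' Construct an ECG recording object
#'
#' An `ecg_record` holds one multi-lead recording as a leads-by-samples matrix
#' in millivolts, its sampling rate, and an optional multi-label target vector.
#'
#' @param signals numeric matrix, `n_leads x L`, millivolts (rows = leads).
#' @param fs sampling rate in Hz.
#' @param labels binary vector of length K (multi-label indicator), or `NULL`.
#' @param record_id opaque identifier string.
#' @param lead_names character vector of length `n_leads`; defaults to
#'   the standard 12-lead names when `n_leads == 12`, else `"L1", "L2", ...`.
#' @return an object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(matrix(0, 2, 5), fs = 100)
#' dim(rec$signals)
#' @export
ecg_record <- function(signals, fs, labels = NULL, record_id = "rec",
                       lead_names = NULL) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix (leads x samples)", call. = FALSE)
  if (nrow(signals) < 2L)
    stop("at least 2 leads are required, got ", nrow(signals), call. = FALSE)
  if (ncol(signals) < 1L)
    stop("signals must contain at least one sample", call. = FALSE)
  bad <- first_nonfinite(signals)
  if (!is.null(bad))
    stop(sprintf("non-finite sample at lead %d, sample %d", bad[1L], bad[2L]),
         call. = FALSE)
  stop_if_not_scalar_num(fs, "fs", lo = .Machine$double.eps)
  if (!is.null(labels)) {
    labels <- as.numeric(labels)
    if (length(labels) < 1L || !all(labels %in% c(0, 1)))
      stop("`labels` must be a 0/1 vector of length >= 1", call. = FALSE)
  }
  if (is.null(lead_names)) {
    lead_names <- if (nrow(signals) == 12L) STANDARD_12_LEADS
    else paste0("L", seq_len(nrow(signals)))
  }
  if (length(lead_names) != nrow(signals))
    stop("`lead_names` length must equal the number of leads", call. = FALSE)
  structure(
    list(signals = unname(signals), fs = as.numeric(fs), labels = labels,
         record_id = as.character(record_id),
         lead_names = as.character(lead_names)),
    class = "ecg_record")
}

#' Standard 12-lead order used throughout the package
#' @keywords internal
STANDARD_12_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                       "V1", "V2", "V3", "V4", "V5", "V6")

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d leads x %d samples @ %g Hz (%.2f s)\n",
              x$record_id, nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs))
  if (!is.null(x$labels))
    cat("  labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Per-lead z-score normalization
#'
#' Standardizes every lead over its own samples (mean 0, sd 1). Constant leads
#' map to all zeros. This is the preprocessing applied before encoding.
#'
#' @param record an [ecg_record()].
#' @return an `ecg_record` with normalized signals.
#' @export
normalize_record <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  s <- record$signals
  mu <- rowMeans(s)
  sd <- sqrt(rowMeans(s^2) - mu^2)
  sd[sd < 1e-12] <- Inf          # constant lead -> zeros
  record$signals <- (s - mu) / sd
  record
}
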