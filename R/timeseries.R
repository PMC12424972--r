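#' Parcel timeseries container
#'
#' Holds a frames x parcels BOLD signal matrix together with its repetition
#' time, the per-frame framewise-displacement (FD) trace and the retained
#' (low-motion) frame mask used by every downstream step.
#'
#' @param data numeric matrix, frames x parcels; column names are parcel ids.
#' @param tr repetition time in seconds.
#' @param fd numeric per-frame framewise displacement in mm; defaults to zero
#'   motion.
#' @param retained logical per-frame mask; defaults to all frames retained.
#' @return An object of class `parcel_timeseries`.
#' @export
parcel_timeseries <- function(data, tr, fd = NULL, retained = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 2L) stop("need more than one parcel")
  if (!all(is.finite(data))) stop("timeseries contains non-finite values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar (seconds)")
  n <- nrow(data)
  if (is.null(fd)) fd <- numeric(n)
  if (length(fd) != n) stop("fd length must equal the frame count")
  if (!all(is.finite(fd)) || any(fd < 0)) stop("fd must be finite and non-negative")
  if (is.null(retained)) retained <- rep(TRUE, n)
  retained <- as.logical(retained)
  if (length(retained) != n) stop("retained length must equal the frame count")
  structure(list(data = data, tr = tr, fd = as.numeric(fd), retained = retained),
            class = "parcel_timeseries")
}

#' @export
print.parcel_timeseries <- function(x, ...) {
  cat(sprintf("parcel_timeseries: %d frames x %d parcels, TR %.3g s, %d retained (%.1f min)\n",
              nrow(x$data), ncol(x$data), x$tr, sum(x$retained),
              sum(x$retained) * x$tr / 60))
  invisible(x)
}

#' Nuisance confound set
#'
#' Frames x q matrix of confound regressors (typically white-matter, CSF and
#' global-signal means plus 12 motion parameters).
#'
#' @param confounds numeric matrix, frames x q.
#' @param labels optional character vector of q regressor names.
#' @return An object of class `nuisance_set`.
#' @export
nuisance_set <- function(confounds, labels = colnames(confounds)) {
  confounds <- as.matrix(confounds)
  storage.mode(confounds) <- "double"
  if (ncol(confounds) < 1L) stop("need at least one confound")
  if (!all(is.finite(confounds))) stop("confounds contain non-finite values")
  if (is.null(labels)) labels <- paste0("confound", seq_len(ncol(confounds)))
  if (length(labels) != ncol(confounds)) stop("one label per confound column")
  structure(list(confounds = confounds, labels = as.character(labels)),
            class = "nuisance_set")
}

#' Preprocessing configuration
#'
#' Defaults follow common resting-state practice for this pipeline: censor at
#' FD > 0.3 mm, bandpass 0.008-0.09 Hz with a second-order Butterworth filter
#' applied forward and backward, and require at least 10 minutes of retained
#' data before computing connectivity.
#'
#' @param fd_threshold censoring threshold in mm.
#' @param band_low,band_high passband edges in Hz.
#' @param filter_order Butterworth order (>= 1).
#' @param min_retained_minutes minimum retained data to allow connectivity.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(fd_threshold = 0.3, band_low = 0.008,
                              band_high = 0.09, filter_order = 2L,
                              min_retained_minutes = 10) {
  if (fd_threshold <= 0) stop("fd_threshold must be positive")
  if (!(0 < band_low && band_low < band_high)) stop("need 0 < band_low < band_high")
  if (filter_order < 1L) stop("filter_order must be >= 1")
  structure(list(fd_threshold = fd_threshold, band_low = band_low,
                 band_high = band_high, filter_order = as.integer(filter_order),
                 min_retained_minutes = min_retained_minutes),
            class = "preprocess_config")
}

#' Read a parcel timeseries from delimited text
#'
#' @param path frames x parcels delimited file with a header row of parcel ids.
#' @param tr repetition time in seconds.
#' @param fd_path optional single-column FD trace file (no header).
#' @param sep field separator.
#' @return a `parcel_timeseries`.
#' @export
read_parcel_timeseries <- function(path, tr, fd_path = NULL, sep = "\t") {
  data <- as.matrix(read.delim(path, sep = sep, check.names = FALSE))
  fd <- NULL
  if (!is.null(fd_path)) fd <- scan(fd_path, quiet = TRUE)
  parcel_timeseries(data, tr = tr, fd = fd)
}

#' Write a parcel timeseries to delimited text
#' @param ts a `parcel_timeseries`.
#' @param path output path for the signal matrix.
#' @param fd_path optional output path for the FD trace.
#' @param sep field separator.
#' @export
write_parcel_timeseries <- function(ts, path, fd_path = NULL, sep = "\t") {
  utils::write.table(ts$data, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(fd_path)) writeLines(format(ts$fd, trim = TRUE), fd_path)
  invisible(path)
}
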