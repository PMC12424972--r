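#' Motion-censoring mask
#'
#' Flags frames whose framewise displacement exceeds the threshold; retained
#' frames are exactly those with FD <= threshold.
#'
#' @param fd numeric per-frame FD in mm.
#' @param threshold censoring threshold in mm (default 0.3).
#' @return logical mask, TRUE for retained frames.
#' @export
censor_mask <- function(fd, threshold = 0.3) {
  if (!all(is.finite(fd)) || any(fd < 0)) stop("fd must be finite and non-negative")
  if (threshold <= 0) stop("threshold must be positive")
  mask <- fd <= threshold
  if (!any(mask)) stop("all frames exceed the FD threshold: no usable data")
  mask
}

#' Apply a censoring mask to a timeseries
#' @param ts a `parcel_timeseries`.
#' @param threshold FD threshold in mm.
#' @return the timeseries with its `retained` mask set from the FD trace.
#' @export
apply_censoring <- function(ts, threshold = 0.3) {
  ts$retained <- ts$retained & censor_mask(ts$fd, threshold)
  if (!any(ts$retained)) stop("all frames censored: no usable data")
  ts
}

# least-squares fit on retained rows, residuals formed for all rows;
# pivoted QR drops aliased columns so rank-deficient designs (duplicated
# confounds) leave the residuals unchanged
.residualize <- function(data, design, retained) {
  fit <- qr(design[retained, , drop = FALSE])
  beta <- qr.coef(fit, data[retained, , drop = FALSE])
  beta[!is.finite(beta)] <- 0
  data - design %*% beta
}

#' Detrend and demean a timeseries on low-motion frames
#'
#' Fits an intercept + linear trend per parcel on the retained frames only and
#' subtracts the fit from every frame, so high-motion frames never influence
#' the trend estimate.
#'
#' @param ts a `parcel_timeseries`.
#' @return the detrended, demeaned timeseries.
#' @export
detrend_demean <- function(ts) {
  if (sum(ts$retained) < 3L) stop("need at least 3 retained frames to detrend")
  n <- nrow(ts$data)
  design <- cbind(1, seq_len(n) - (n + 1) / 2)
  ts$data <- .residualize(ts$data, design, ts$retained)
  ts
}

#' Regress nuisance confounds out of a timeseries
#'
#' Each parcel column is replaced by its least-squares residual against the
#' confound matrix (plus an intercept). Betas are estimated on retained frames
#' only and applied to all frames; duplicated or collinear confounds resolve
#' to the minimum-norm solution.
#'
#' @param ts a `parcel_timeseries`.
#' @param nuisance a `nuisance_set` with the same frame count.
#' @return the denoised timeseries.
#' @export
nuisance_regress <- function(ts, nuisance) {
  if (nrow(nuisance$confounds) != nrow(ts$data))
    stop("confound frame count must match the timeseries")
  design <- cbind(1, nuisance$confounds)
  ts$data <- .residualize(ts$data, design, ts$retained)
  ts
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies the configured Butterworth bandpass forward and backward
#' (zero-phase) to every parcel column. The frame count is unchanged. Censored
#' frames should be interpolated first ([interpolate_censored()]) so spikes do
#' not ring through the filter.
#'
#' @param ts a `parcel_timeseries`.
#' @param cfg a `preprocess_config` (band edges in Hz, filter order).
#' @return the filtered timeseries.
#' @export
bandpass_filter <- function(ts, cfg = preprocess_config()) {
  nyq <- 1 / (2 * ts$tr)
  if (cfg$band_high >= nyq)
    stop(sprintf("band_high (%.3g Hz) must be below Nyquist (%.3g Hz)", cfg$band_high, nyq))
  bf <- signal::butter(cfg$filter_order, c(cfg$band_low, cfg$band_high) / nyq,
                       type = "pass")
  pad <- 3 * (max(length(bf$a), length(bf$b)) - 1)
  if (nrow(ts$data) <= 3 * pad)
    stop("timeseries too short for stable zero-phase filtering")
  ts$data <- apply(ts$data, 2, function(col) signal::filtfilt(bf, col))
  ts
}

#' Interpolate censored frames
#'
#' Replaces censored frames by linear interpolation over the retained frames
#' (nearest retained value at the sequence boundaries) so that subsequent
#' filtering is well behaved. The retained mask is preserved: interpolated
#' frames are still excluded from connectivity.
#'
#' @param ts a `parcel_timeseries`.
#' @return the timeseries with censored frames filled in.
#' @export
interpolate_censored <- function(ts) {
  keep <- ts$retained
  if (all(keep)) return(ts)
  if (sum(keep) < 2L) stop("need at least 2 retained frames to interpolate")
  idx <- seq_len(nrow(ts$data))
  ts$data <- apply(ts$data, 2, function(col) {
    stats::approx(idx[keep], col[keep], xout = idx, method = "linear",
                  rule = 2)$y
  })
  ts
}

#' Pearson functional connectivity
#'
#' Pairwise Pearson correlation of all parcel timeseries over retained frames
#' only. Refuses to run if less than `min_retained_minutes` of retained data
#' are available (subject exclusion rule) or if any parcel has zero variance.
#'
#' @param ts a `parcel_timeseries`.
#' @param cfg a `preprocess_config`; set `min_retained_minutes = 0` to disable
#'   the duration screen.
#' @param parc optional `parcellation` attached to the result.
#' @return a `connectivity_matrix`: symmetric P x P with unit diagonal.
#' @export
compute_connectivity <- function(ts, cfg = preprocess_config(), parc = NULL) {
  mins <- sum(ts$retained) * ts$tr / 60
  if (mins < cfg$min_retained_minutes)
    stop(sprintf("only %.2f retained minutes; %.2f required", mins,
                 cfg$min_retained_minutes))
  x <- ts$data[ts$retained, , drop = FALSE]
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts$data)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance parcel(s) over retained frames: ",
         paste(bad, collapse = ", "))
  }
  r <- cor(x)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  connectivity_matrix(r, parc)
}

#' Full preprocessing chain
#'
#' Censor by FD, detrend/demean on retained frames, regress nuisance
#' confounds, interpolate censored frames, bandpass filter, then correlate
#' over retained (non-interpolated) frames only.
#'
#' @param ts a `parcel_timeseries`.
#' @param nuisance optional `nuisance_set`.
#' @param cfg a `preprocess_config`.
#' @param parc optional `parcellation` for the result.
#' @return a `connectivity_matrix`.
#' @export
preprocess_to_connectivity <- function(ts, nuisance = NULL,
                                       cfg = preprocess_config(), parc = NULL) {
  ts <- apply_censoring(ts, cfg$fd_threshold)
  ts <- detrend_demean(ts)
  if (!is.null(nuisance)) ts <- nuisance_regress(ts, nuisance)
  ts <- interpolate_censored(ts)
  ts <- bandpass_filter(ts, cfg)
  compute_connectivity(ts, cfg, parc)
}
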