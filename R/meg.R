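#' Canonical MEG frequency bands
#'
#' The six bands used throughout: Delta 2-4 Hz, Theta 4-8 Hz, Alpha 8-12 Hz,
#' Beta 12-30 Hz, low Gamma 30-48 Hz, high Gamma 52-86 Hz. The gap around
#' 50 Hz avoids mains interference.
#'
#' @return `data.frame` with columns `name`, `low`, `high` (Hz).
#' @export
meg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    low = c(2, 4, 8, 12, 30, 52),
    high = c(4, 8, 12, 30, 48, 86),
    stringsAsFactors = FALSE
  )
}

#' Multichannel sensor time series
#'
#' Light container for a resting-state recording: a channels x samples
#' matrix with its sampling rate and sensor type.
#'
#' @param data numeric matrix, channels x samples, no missing values.
#' @param fs sampling rate in Hz.
#' @param channel_type `"MAG"`, `"GRD"` or `"mixed"`.
#' @return object of class `sensor_ts`.
#' @export
sensor_ts <- function(data, fs, channel_type = "mixed") {
  data <- as.matrix(data)
  if (anyNA(data)) stop("time series must not contain missing samples", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be positive", call. = FALSE)
  structure(list(data = data, fs = fs, channel_type = channel_type),
            class = "sensor_ts")
}

#' @export
print.sensor_ts <- function(x, ...) {
  cat("sensor_ts: ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", x$channel_type, ")\n", sep = "")
  invisible(x)
}

# zero-phase order-5 Butterworth band-pass on a channels x samples matrix:
# high-pass at the low edge, then low-pass at the high edge, each applied
# forward-backward (no group delay; the amplitude response is squared).
bandpass_matrix <- function(x, fs, low, high) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  bh <- signal::butter(5, 2 * low / fs, type = "high")
  bl <- signal::butter(5, 2 * high / fs, type = "low")
  t(apply(x, 1, function(ch)
    signal::filtfilt(bl, signal::filtfilt(bh, ch))))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-5 Butterworth high-pass at the band's low edge followed by an
#' order-5 low-pass at the high edge, each applied forward-backward
#' (zero-phase), so epochs stay aligned across bands at the price of a
#' squared amplitude response. Applied to the continuous (un-epoched) data.
#'
#' @param ts a [sensor_ts()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return filtered [sensor_ts()] of the same shape.
#' @export
bandpass <- function(ts, low, high) {
  stopifnot(inherits(ts, "sensor_ts"))
  out <- ts
  out$data <- bandpass_matrix(ts$data, ts$fs, low, high)
  out
}

#' Theoretical composite band-pass amplitude response
#'
#' Exact magnitude of the zero-phase high-pass/low-pass cascade used by
#' [bandpass()] at given frequencies, from the digital transfer functions
#' (each filter contributes its squared magnitude because it runs forward
#' and backward).
#'
#' @param freq frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz.
#' @return amplitude ratios at `freq`.
#' @export
bandpass_response <- function(freq, fs, low, high) {
  bh <- signal::butter(5, 2 * low / fs, type = "high")
  bl <- signal::butter(5, 2 * high / fs, type = "low")
  mag <- function(b, f) {
    z <- exp(1i * 2 * pi * f / fs)
    abs(signal::polyval(rev(b$b), z) / signal::polyval(rev(b$a), z))
  }
  (mag(bh, freq) * mag(bl, freq))^2
}

#' Cut a recording into fixed-length epochs
#'
#' Splits the recording into consecutive `epoch_s`-second segments;
#' `floor(duration / epoch_s)` epochs are produced and any trailing
#' remainder is dropped. The bad-epoch mask starts all-false.
#'
#' @param ts a [sensor_ts()].
#' @param epoch_s epoch length in seconds; `fs * epoch_s` must be integral.
#' @return object of class `epoched_series`: list with `epochs` (list of
#'   channels x samples matrices), `bad` (logical mask), `fs`, `channel_type`.
#' @export
epoch_series <- function(ts, epoch_s = 2) {
  stopifnot(inherits(ts, "sensor_ts"))
  spe <- ts$fs * epoch_s
  if (abs(spe - round(spe)) > 1e-9)
    stop("fs * epoch_s must be an integer number of samples", call. = FALSE)
  spe <- as.integer(round(spe))
  n_ep <- ncol(ts$data) %/% spe
  if (n_ep < 1)
    stop("recording shorter than one epoch", call. = FALSE)
  epochs <- lapply(seq_len(n_ep), function(e)
    ts$data[, ((e - 1) * spe + 1):(e * spe), drop = FALSE])
  structure(list(epochs = epochs, bad = rep(FALSE, n_ep),
                 fs = ts$fs, channel_type = ts$channel_type),
            class = "epoched_series")
}

#' Flag artifact-contaminated epochs
#'
#' Robust stand-in for an automatic artifact detector: an epoch is flagged
#' bad when the log of its total variance (summed over channels) exceeds the
#' median by more than 3 scaled median absolute deviations (consistency
#' constant 1.4826) across epochs. A degenerate recording with identical
#' epochs flags nothing.
#'
#' @param es an [epoch_series()] result with at least 3 epochs.
#' @return the same object with `bad` updated.
#' @export
mark_bad_epochs <- function(es) {
  stopifnot(inherits(es, "epoched_series"))
  if (length(es$epochs) < 3)
    stop("need at least 3 epochs to flag outliers", call. = FALSE)
  v <- vapply(es$epochs, function(e) log(sum(apply(e, 1, stats::var))),
              numeric(1))
  thr <- stats::median(v) + 3 * stats::mad(v)
  es$bad <- v > thr
  es
}

#' Concatenate the good epochs back into a continuous series
#'
#' @param es an [epoch_series()] result.
#' @return a [sensor_ts()] of the non-bad epochs in original order;
#'   errors if every epoch is bad.
#' @export
concatenate_good <- function(es) {
  stopifnot(inherits(es, "epoched_series"))
  keep <- which(!es$bad)
  if (!length(keep)) stop("all epochs are marked bad", call. = FALSE)
  sensor_ts(do.call(cbind, es$epochs[keep]), fs = es$fs,
            channel_type = es$channel_type)
}

#' Clip outlier samples channel-wise
#'
#' Per channel, samples outside `median +/- 3 * (1.4826 * MAD)` are replaced
#' by the nearer boundary; everything else is untouched. When the MAD is zero
#' (a channel constant except for isolated spikes), the boundary collapses to
#' the median, so any deviating sample is clipped to the median — the
#' continuous limit of the rule. Applied after band-pass filtering, where
#' residual high-frequency spikes are most visible.
#'
#' @param ts a [sensor_ts()].
#' @return the clipped [sensor_ts()], with attribute `n_clipped`: per-channel
#'   count of replaced samples.
#' @export
clip_outlier_samples <- function(ts) {
  stopifnot(inherits(ts, "sensor_ts"))
  x <- ts$data
  counts <- integer(nrow(x))
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ]
    med <- stats::median(v)
    s <- stats::mad(v)           # includes the 1.4826 consistency constant
    lo <- med - 3 * s
    hi <- med + 3 * s
    out <- v < lo | v > hi
    counts[ch] <- sum(out)
    x[ch, ] <- pmin(pmax(v, lo), hi)
  }
  ts$data <- x
  attr(ts, "n_clipped") <- counts
  ts
}

#' Sensor covariance of a band-limited recording
#'
#' Sample covariance across channels (per-channel mean removed, `n - 1`
#' denominator), on the absolute signal scale: band power is deliberately
#' not relativized to total power, because relative power could cancel true
#' group differences; overall signal-strength differences due to head
#' position are instead handled downstream via the squared sensor-distance
#' confound.
#'
#' @param ts a [sensor_ts()] with at least 2 samples.
#' @param band optional band label carried into the result.
#' @return object of class `band_features`: list with `cov` (channels x
#'   channels), `variance` (its diagonal), `band`.
#' @export
band_covariance <- function(ts, band = NULL) {
  stopifnot(inherits(ts, "sensor_ts"))
  if (ncol(ts$data) < 2)
    stop("need at least 2 samples for a covariance", call. = FALSE)
  C <- stats::cov(t(ts$data))
  structure(list(cov = C, variance = diag(C), band = band),
            class = "band_features")
}

#' Vectorize band features
#'
#' `mode = "variance"` returns the covariance diagonal (length = number of
#' channels, the per-sensor band power). `mode = "covariance"` returns the
#' strict upper triangle in fixed row-major order — pairs (1,2), (1,3), ...,
#' (1,p), (2,3), ... — of length `p (p - 1) / 2`, e.g. 5151 for 102
#' magnetometer-like channels and 20706 for 204 gradiometer-like channels.
#'
#' @param bf a [band_covariance()] result or a square symmetric matrix.
#' @param mode `"variance"` or `"covariance"`.
#' @return numeric feature vector.
#' @export
vectorize_features <- function(bf, mode = c("covariance", "variance")) {
  mode <- match.arg(mode)
  C <- if (inherits(bf, "band_features")) bf$cov else as.matrix(bf)
  if (mode == "variance") return(diag(C))
  tC <- t(C)
  tC[lower.tri(tC)]   # row-major strict upper triangle of C
}

#' Rebuild a symmetric matrix from its vectorized form
#'
#' Inverse of [vectorize_features()] in covariance mode, given the diagonal.
#'
#' @param v strict upper triangle in row-major order.
#' @param variance the diagonal.
#' @return symmetric `p x p` matrix.
#' @export
unvectorize_features <- function(v, variance) {
  p <- length(variance)
  if (length(v) != p * (p - 1) / 2)
    stop("length mismatch: expected p(p-1)/2 off-diagonal entries", call. = FALSE)
  C <- matrix(0, p, p)
  tC <- t(C)
  tC[lower.tri(tC)] <- v
  C <- t(tC)
  C <- C + t(C)
  diag(C) <- variance
  C
}

#' Full per-band MEG feature extraction
#'
#' Fixed pipeline for one recording and one band: band-pass the continuous
#' data, epoch into 2-s segments, flag and drop bad epochs, re-concatenate,
#' clip residual outlier samples, and compute the sensor covariance. Returns
#' the requested feature vector.
#'
#' @param ts a [sensor_ts()].
#' @param band band name from [meg_bands()].
#' @param mode `"covariance"` or `"variance"`.
#' @param epoch_s epoch length in seconds.
#' @return numeric feature vector (attribute `band_features` holds the full
#'   [band_covariance()] object).
#' @export
extract_band_features <- function(ts, band = "low_gamma",
                                  mode = c("covariance", "variance"),
                                  epoch_s = 2) {
  mode <- match.arg(mode)
  bands <- meg_bands()
  if (!band %in% bands$name) stop("unknown band: ", band, call. = FALSE)
  row <- bands[bands$name == band, ]
  filtered <- bandpass(ts, row$low, row$high)
  es <- mark_bad_epochs(epoch_series(filtered, epoch_s))
  cleaned <- clip_outlier_samples(concatenate_good(es))
  bf <- band_covariance(cleaned, band = band)
  out <- vectorize_features(bf, mode)
  attr(out, "band_features") <- bf
  out
}
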