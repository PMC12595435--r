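#' Multichannel band-limited signal container
#'
#' Light container for channels-by-samples recordings (EEG-like). Channels
#' containing nonfinite samples are dropped at construction (with a
#' warning); at least two finite channels must remain.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate Samples per second.
#' @param channel_labels Optional character vector of channel names.
#' @return A \code{multichannel_signal}.
#' @export
multichannel_signal <- function(data, sampling_rate, channel_labels = NULL) {
  data <- as.matrix(data)
  stopifnot(sampling_rate > 0)
  if (is.null(channel_labels))
    channel_labels <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  bad <- !apply(data, 1, function(r) all(is.finite(r)))
  if (any(bad)) {
    warning("dropping ", sum(bad), " channel(s) with nonfinite samples")
    data <- data[!bad, , drop = FALSE]
    channel_labels <- channel_labels[!bad]
  }
  if (nrow(data) < 2) stop("need at least 2 finite channels")
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = channel_labels),
            class = "multichannel_signal")
}

#' @export
print.multichannel_signal <- function(x, ...) {
  cat(sprintf("<multichannel_signal> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]) to each demeaned channel, so the pass band keeps
#' zero phase shift. Filter transients contaminate the edges; the returned
#' object carries an \code{edge_samples} attribute (two cycles of the low
#' cutoff per side) that downstream steps trim.
#'
#' @param x A \code{multichannel_signal}.
#' @param low,high Band edges in Hz, \code{0 < low < high < Nyquist}.
#' @return A filtered \code{multichannel_signal} with attribute
#'   \code{edge_samples}.
#' @export
bandpass <- function(x, low, high) {
  stopifnot(inherits(x, "multichannel_signal"))
  nyq <- x$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  filt <- t(apply(x$data, 1, function(ch)
    signal::filtfilt(bf, ch - mean(ch))))
  out <- multichannel_signal(filt, x$sampling_rate, x$channel_labels)
  attr(out, "edge_samples") <- ceiling(2 * x$sampling_rate / low)
  attr(out, "band") <- c(low, high)
  out
}

#' Instantaneous phases via the Hilbert transform
#'
#' Analytic-signal phase of each (demeaned) channel; expects band-limited
#' input for a meaningful instantaneous phase (not enforced). Edge samples
#' flagged by [bandpass()] are trimmed here.
#'
#' @param x A \code{multichannel_signal} (typically from [bandpass()]).
#' @return Matrix of phases in \eqn{(-\pi, \pi]}, time in rows, channels in
#'   columns.
#' @export
instantaneous_phase <- function(x) {
  stopifnot(inherits(x, "multichannel_signal"))
  if (any(apply(x$data, 1, stats::sd) == 0))
    stop("flat channel: zero variance")
  ph <- apply(x$data, 1, function(ch) Arg(analytic_signal(ch - mean(ch))))
  edge <- attr(x, "edge_samples") %||% 0L
  if (edge > 0 && nrow(ph) > 2 * edge)
    ph <- ph[(edge + 1):(nrow(ph) - edge), , drop = FALSE]
  ph
}

# analytic signal x + i * H(x) via the one-sided FFT spectrum
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' ES proximity of a multichannel recording
#'
#' The end-to-end estimate of a network's proximity to explosive
#' synchronization from signals alone: band-pass each channel (default
#' alpha band, 8-13 Hz), extract instantaneous Hilbert phases, collapse
#' them to the instantaneous order parameter across channels, slide a
#' lagged-ACF window along it (defaults: lag \code{round(sampling_rate /
#' 10)} samples — 50 at 500 Hz, about one alpha cycle — 10-s windows, 5-s
#' step), and report the kurtosis of the window-ACF distribution. Values
#' near 3 are Gaussian-like (far from ES); heavy tails (> 3) indicate
#' critical flickering characteristic of ES proximity.
#'
#' @param x A \code{multichannel_signal}.
#' @param band Length-2 Hz vector (default \code{c(8, 13)}).
#' @param lag ACF lag in samples (default \code{round(sampling_rate / 10)}).
#' @param window_length,step Moving-window parameters in seconds.
#' @param min_duration Recordings shorter than this (s, default 180) are
#'   flagged low-confidence rather than rejected.
#' @return An \code{es_proximity_report}; [glance()] gives the kurtosis
#'   and bookkeeping, [tidy()] the per-window ACF values.
#' @examples
#' set.seed(1)
#' x <- multichannel_signal(matrix(rnorm(8 * 5000), 8), sampling_rate = 250)
#' rep <- es_proximity(x, band = c(8, 13), window_length = 2, step = 1)
#' glance(rep)
#' @export
es_proximity <- function(x, band = c(8, 13), lag = NULL,
                         window_length = 10, step = 5, min_duration = 180) {
  stopifnot(inherits(x, "multichannel_signal"))
  if (is.null(lag)) lag <- round(x$sampling_rate / 10)
  dur <- ncol(x$data) / x$sampling_rate
  ph <- instantaneous_phase(bandpass(x, band[1], band[2]))
  r <- order_parameter(ph, x$sampling_rate)
  w <- windowed_acf(r, window_length = window_length, step = step, lag = lag)
  if (all(!is.finite(w$acf)))
    stop("degenerate coherence: every window has zero order-parameter ",
         "variance (identical channels?)")
  structure(list(windowed = w,
                 kurtosis = attr(w, "kurtosis"),
                 n_windows = attr(w, "n_windows"),
                 n_missing = attr(w, "n_missing"),
                 band = band, lag = lag,
                 window_length = window_length, step = step,
                 sampling_rate = x$sampling_rate,
                 n_channels = nrow(x$data),
                 low_confidence = attr(w, "low_confidence") ||
                   dur < min_duration),
            class = "es_proximity_report")
}

#' @export
print.es_proximity_report <- function(x, ...) {
  cat(sprintf(
    "<es_proximity_report> kurtosis %.3f over %d windows (band %g-%g Hz, lag %d)%s\n",
    x$kurtosis, x$n_windows - x$n_missing, x$band[1], x$band[2], x$lag,
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' @describeIn es_proximity One-row summary.
#' @export
glance.es_proximity_report <- function(x, ...) {
  tibble::tibble(kurtosis = x$kurtosis,
                 n_windows = x$n_windows, n_missing = x$n_missing,
                 band_low = x$band[1], band_high = x$band[2], lag = x$lag,
                 n_channels = x$n_channels,
                 low_confidence = x$low_confidence)
}

#' @describeIn es_proximity Per-window ACF values.
#' @export
tidy.es_proximity_report <- function(x, ...) tibble::as_tibble(x$windowed)

#' @describeIn es_proximity Windowed-ACF trace (see
#'   [autoplot.windowed_acf()]).
#' @param object An \code{es_proximity_report}.
#' @export
autoplot.es_proximity_report <- function(object, ...) {
  autoplot(object$windowed, ...)
}
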