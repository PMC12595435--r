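#' Instantaneous Kuramoto order parameter
#'
#' \eqn{r(t) = |N^{-1} \sum_j e^{i\theta_j(t)}|}: 0 for incoherent phases, 1
#' for full synchrony.
#'
#' @param phases Matrix of phases (radians), time in rows, oscillators (>= 2)
#'   in columns.
#' @param sampling_rate Samples per second of the phase series.
#' @return An \code{op_series}: a numeric vector of \code{r(t)} in [0, 1]
#'   with attributes \code{sampling_rate} and \code{n_oscillators}.
#' @examples
#' ph <- cbind(seq(0, 10, 0.01), seq(0, 10, 0.01) + pi / 3)
#' r <- order_parameter(ph, sampling_rate = 100)
#' head(r)
#' @export
order_parameter <- function(phases, sampling_rate) {
  phases <- as.matrix(phases)
  if (ncol(phases) < 2) stop("need at least 2 oscillators")
  if (!all(is.finite(phases))) stop("phases must be finite")
  r <- sqrt(rowMeans(cos(phases))^2 + rowMeans(sin(phases))^2)
  op_series(r, sampling_rate, ncol(phases))
}

#' Construct an order-parameter series
#'
#' @param values Numeric vector in [0, 1].
#' @param sampling_rate Samples per second (> 0).
#' @param n_oscillators Number of oscillators/channels the series summarizes.
#' @return An \code{op_series} numeric vector with metadata attributes.
#' @export
op_series <- function(values, sampling_rate, n_oscillators) {
  stopifnot(sampling_rate > 0, n_oscillators >= 2,
            all(values >= 0 & values <= 1 + 1e-12))
  structure(as.numeric(values), sampling_rate = sampling_rate,
            n_oscillators = n_oscillators, class = "op_series")
}

as_op_series <- function(x, sampling_rate = NULL, n_oscillators = NULL) {
  if (inherits(x, "op_series")) return(x)
  if (inherits(x, "sl_trajectory"))
    return(op_series(x$r, x$sampling_rate, x$n_oscillators))
  stopifnot(!is.null(sampling_rate), !is.null(n_oscillators))
  op_series(x, sampling_rate, n_oscillators)
}

#' Pair correlation function of an order-parameter series
#'
#' The PCF is the N-scaled temporal variance of the instantaneous order
#' parameter, \eqn{N (\langle r^2\rangle_t - \langle r\rangle_t^2)}
#' (population moments). It measures the size of collective synchronization
#' fluctuations and peaks at the critical coupling, which is how this
#' package identifies critical points (see [find_critical_point()]).
#'
#' @param x An \code{op_series}, an \code{sl_trajectory}, or a numeric
#'   vector (then supply \code{n_oscillators}).
#' @param n_oscillators N used for the scaling (taken from \code{x} when
#'   available).
#' @param min_samples Guard: refuse fewer samples than this.
#' @return Scalar PCF (>= 0).
#' @examples
#' r <- op_series(rep(c(0.4, 0.6), 200), 100, 100)
#' pcf(r)  # 100 * 0.01 = 1
#' @export
pcf <- function(x, n_oscillators = NULL, min_samples = 100) {
  if (is.null(n_oscillators)) {
    x <- as_op_series(x)
    n_oscillators <- attr(x, "n_oscillators")
  }
  v <- as.numeric(x)
  if (length(v) < min_samples)
    stop("need at least ", min_samples, " samples for a PCF estimate")
  n_oscillators * (mean(v^2) - mean(v)^2)
}

#' Pearson (non-excess) kurtosis
#'
#' \eqn{m_4 / m_2^2} with central sample moments; 3 for a Gaussian, greater
#' than 3 for heavy tails, and never below 1 (the bound is attained only by
#' symmetric two-point samples). No small-sample bias correction is applied.
#'
#' @param x Numeric sample, length >= 4, nonzero variance.
#' @return Scalar kurtosis.
#' @examples
#' kurtosis_pearson(rep(c(-1, 1), 10))  # 1
#' @export
kurtosis_pearson <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("need at least 4 finite values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("degenerate sample: zero variance")
  mean((x - m)^4) / m2^2
}

#' Moving-window lagged autocorrelation and its kurtosis
#'
#' Slides a window along the series and computes, per window, the Pearson
#' autocorrelation of the mean-removed window at a single lag (the biased,
#' divide-by-n estimator of [stats::acf()], so every value lies in
#' \eqn{[-1, 1]}). The kurtosis of the resulting across-window distribution
#' is the explosive-synchronization proximity statistic: networks close to
#' an explosive transition flicker between coherent and incoherent episodes
#' near their critical point, producing occasional extreme window ACFs and
#' hence a heavy-tailed (kurtosis > 3) distribution.
#'
#' The default lag, \code{round(sampling_rate / 10)} samples, spans about
#' one cycle of a ~10 Hz (alpha-band-like) oscillation at any sampling rate
#' (50 samples at 500 Hz).
#'
#' @param x An \code{op_series}, \code{sl_trajectory}, or numeric vector
#'   (then supply \code{sampling_rate}).
#' @param window_length Window length, seconds (default 10).
#' @param step Window advance, seconds (default 5, i.e. 50% overlap).
#' @param lag Lag in samples; default \code{round(sampling_rate / 10)}.
#' @param sampling_rate Required when \code{x} is a bare numeric vector.
#' @param min_windows Fewer windows than this flags the report
#'   low-confidence (default 30).
#' @return A \code{windowed_acf} tibble with columns \code{window},
#'   \code{t_center} (s, series clock), \code{acf}; zero-variance windows
#'   are \code{NA} and excluded from the kurtosis. Attributes carry the
#'   parameters; [glance()] returns kurtosis, window counts, and the
#'   low-confidence flag.
#' @examples
#' set.seed(1)
#' w <- windowed_acf(rnorm(5000), sampling_rate = 100, window_length = 1,
#'                   step = 0.5, lag = 5)
#' glance(w)
#' @export
windowed_acf <- function(x, window_length = 10, step = 5, lag = NULL,
                         sampling_rate = NULL, min_windows = 30) {
  if (is.null(sampling_rate)) {
    x <- as_op_series(x)
    sampling_rate <- attr(x, "sampling_rate")
  }
  v <- as.numeric(x)
  if (is.null(lag)) lag <- round(sampling_rate / 10)
  n_w <- round(window_length * sampling_rate)
  n_s <- max(1L, round(step * sampling_rate))
  if (n_w <= 2 * lag)
    stop("window too short: window_length * sampling_rate must exceed 2 * lag")
  if (length(v) < n_w + n_s)
    stop("series too short for 2 windows of ", window_length, " s")
  starts <- seq(1L, length(v) - n_w + 1L, by = n_s)
  acfs <- vapply(starts, function(s) {
    w <- v[s:(s + n_w - 1L)]
    if (stats::var(w) < 1e-20) return(NA_real_)  # zero up to roundoff
    stats::acf(w, lag.max = lag, plot = FALSE, demean = TRUE)$acf[lag + 1L]
  }, numeric(1))
  ok <- acfs[is.finite(acfs)]
  kurt <- if (length(ok) >= 4 && diff(range(ok)) > 1e-10)
    kurtosis_pearson(ok) else NA_real_
  out <- tibble::tibble(
    window = seq_along(starts),
    t_center = (starts - 1 + (n_w - 1) / 2) / sampling_rate,
    acf = acfs)
  structure(out,
            class = c("windowed_acf", class(out)),
            window_length = window_length, step = step, lag = lag,
            sampling_rate = sampling_rate, kurtosis = kurt,
            n_windows = length(acfs), n_missing = sum(!is.finite(acfs)),
            low_confidence = length(ok) < min_windows)
}

#' @describeIn windowed_acf One-row summary: the ES-proximity kurtosis and
#'   window bookkeeping.
#' @export
glance.windowed_acf <- function(x, ...) {
  tibble::tibble(kurtosis = attr(x, "kurtosis"),
                 n_windows = attr(x, "n_windows"),
                 n_missing = attr(x, "n_missing"),
                 lag = attr(x, "lag"),
                 window_length = attr(x, "window_length"),
                 step = attr(x, "step"),
                 low_confidence = attr(x, "low_confidence"))
}

#' @describeIn windowed_acf Windowed-ACF values along the series clock.
#' @param object A \code{windowed_acf}.
#' @export
autoplot.windowed_acf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_center, .data$acf)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = sprintf("ACF(lag %d)", attr(object, "lag")),
                  title = sprintf("windowed ACF — kurtosis %.2f",
                                  attr(object, "kurtosis")))
}

#' Critical coupling from a sweep: the peak-PCF point
#'
#' The critical coupling S* is the grid point with maximal PCF (optionally
#' after 3-point moving-average smoothing). Ties break toward smaller S. A
#' peak on a grid endpoint is flagged: the sweep is too narrow to bracket
#' the transition.
#'
#' @param sweep A \code{coupling_sweep} from [sweep_coupling()], or any data
#'   frame with columns \code{s} and \code{pcf} (one row per grid point;
#'   extra rows per realization are averaged).
#' @param smooth Apply 3-point moving-average smoothing before the argmax?
#' @return One-row tibble: \code{s_star}, \code{pcf_peak}, \code{endpoint},
#'   \code{flat} (no peak: all PCFs equal).
#' @export
find_critical_point <- function(sweep, smooth = FALSE) {
  df <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(sweep), .data$s),
                         pcf = mean(.data$pcf, na.rm = TRUE), .groups = "drop")
  df <- dplyr::arrange(df, .data$s)
  if (nrow(df) < 3) stop("need a sweep of at least 3 grid points")
  y <- df$pcf
  if (smooth && length(y) >= 3)
    y <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2)) |>
      (\(z) ifelse(is.na(z), y, z))()
  flat <- diff(range(y)) == 0
  i <- which.max(y)  # which.max takes the first maximum: tie -> smaller S
  tibble::tibble(s_star = df$s[i], pcf_peak = df$pcf[i],
                 endpoint = i == 1L || i == nrow(df), flat = flat)
}

#' Detrended fluctuation analysis (DFA-1) Hurst exponent
#'
#' Integrates the mean-removed series to a profile, splits it into
#' non-overlapping boxes, removes a per-box linear trend, and regresses log
#' RMS fluctuation on log box size. 0.5 for white noise, about 1.5 for its
#' cumulative sum, H for fractional Gaussian noise. Used here as the
#' conventional long-range-correlation comparator that, unlike the windowed
#' ACF kurtosis, does not track proximity to an explosive transition.
#'
#' @param x Numeric series, >= 1000 finite samples.
#' @param box_sizes Box sizes in samples; default 12 log-spaced sizes from
#'   10 to length(x)/4.
#' @return Scalar DFA-1 exponent.
#' @examples
#' set.seed(1)
#' hurst_dfa(rnorm(5000))  # ~0.5
#' @export
hurst_dfa <- function(x, box_sizes = NULL) {
  if (!all(is.finite(x))) stop("series has nonfinite values")
  n <- length(x)
  if (n < 1000) stop("need at least 1000 samples for DFA")
  if (is.null(box_sizes))
    box_sizes <- unique(round(exp(seq(log(10), log(n / 4), length.out = 12))))
  prof <- cumsum(x - mean(x))
  fl <- vapply(box_sizes, function(b) {
    nb <- n %/% b
    idx <- seq_len(nb * b)
    m <- matrix(prof[idx], nrow = b)
    tt <- seq_len(b)
    # per-box linear detrend, all boxes at once
    X <- cbind(1, tt)
    res <- m - X %*% qr.solve(X, m)
    sqrt(mean(res^2))
  }, numeric(1))
  fit <- stats::lm(log(fl) ~ log(box_sizes))
  unname(stats::coef(fit)[2])
}

#' Spearman rank correlation with p-value
#'
#' Thin tidy wrapper around [stats::cor.test()] (method \code{"spearman"}):
#' exact p-values for small untied samples, asymptotic (t approximation)
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 5.
#' @return One-row tibble: \code{rho}, \code{p_value}, \code{n}.
#' @examples
#' rank_correlation(1:5, c(1, 3, 2, 5, 4))  # rho = 0.8
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
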