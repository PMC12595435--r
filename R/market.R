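#' Locate the in-recession price maximum and crisis trough
#'
#' The collapse clock starts at the highest index value inside the
#' recession window (t1) and the recovery clock at the lowest value (t2);
#' ties break to the earliest date. An episode whose maximum does not
#' precede its minimum is not a crash and is flagged.
#'
#' @param prices Tibble with columns \code{date} and \code{price} for one
#'   market, in date order.
#' @param recession_start,recession_end Window limits (coercible with
#'   \code{as.Date}).
#' @return One-row tibble: \code{t_max}, \code{t_min}, \code{p_max},
#'   \code{p_min}, \code{is_crash}.
#' @export
locate_extrema <- function(prices, recession_start, recession_end) {
  stopifnot(all(c("date", "price") %in% names(prices)))
  d <- as.Date(prices$date)
  win <- d >= as.Date(recession_start) & d <= as.Date(recession_end)
  if (!any(win)) stop("recession window contains no trading days")
  p <- prices$price[win]
  dd <- d[win]
  i_max <- which.max(p)  # first maximum on ties
  i_min <- which.min(p)
  tibble::tibble(t_max = dd[i_max], t_min = dd[i_min],
                 p_max = p[i_max], p_min = p[i_min],
                 is_crash = dd[i_max] < dd[i_min])
}

#' Market collapse and recovery rates with log-inverse times
#'
#' Over an evaluation span of \code{alpha} trading days (row counts, so
#' market closures are skipped naturally), the collapse rate is the share
#' of the peak-to-trough fall realized within \code{alpha} days of the
#' peak, and the recovery rate the share regained within \code{alpha} days
#' of the trough:
#' \deqn{R_1 = \frac{P(t_1) - P(t_1+\alpha)}{P(t_1) - P(t_2)}, \qquad
#'       R_2 = \frac{P(t_2+\alpha) - P(t_2)}{P(t_1) - P(t_2)},}
#' and the response and recovery times are \eqn{\ln(1/R_1)} and
#' \eqn{\ln(1/R_2)}: 0 for a full collapse (or recovery) within
#' \eqn{\alpha} days, larger the slower the move. Rates \eqn{\le 0} (price
#' above the peak, or still below the trough) leave the corresponding time
#' missing rather than clamped. Both rates are ratios of price
#' differences, so they are invariant to currency units and index scaling.
#'
#' @param prices Tibble with \code{date}, \code{price} for one market.
#' @param t_max,t_min Peak and trough dates from [locate_extrema()].
#' @param alpha Evaluation span in trading days (default 100).
#' @return One-row tibble: \code{r1}, \code{r2}, \code{response_time},
#'   \code{recovery_time}, \code{alpha}.
#' @examples
#' px <- tibble::tibble(date = as.Date("2008-01-01") + 0:3,
#'                      price = c(100, 60, 50, 90))
#' # alpha = 1 trading day, peak day 1, trough day 3
#' collapse_recovery_rates(px, px$date[1], px$date[3], alpha = 1)
#' @export
collapse_recovery_rates <- function(prices, t_max, t_min, alpha = 100) {
  stopifnot(alpha >= 1)
  d <- as.Date(prices$date)
  p <- prices$price
  if (any(p <= 0)) stop("prices must be positive")
  i1 <- match(as.Date(t_max), d)
  i2 <- match(as.Date(t_min), d)
  if (is.na(i1) || is.na(i2)) stop("t_max/t_min not found in the series")
  if (i1 + alpha > length(p) || i2 + alpha > length(p))
    stop("alpha = ", alpha, " trading days overruns the series end")
  drop_total <- p[i1] - p[i2]
  if (drop_total == 0) stop("flat market: P(t1) = P(t2)")
  r1 <- (p[i1] - p[i1 + alpha]) / drop_total
  r2 <- (p[i2 + alpha] - p[i2]) / drop_total
  tibble::tibble(
    r1 = r1, r2 = r2,
    response_time = if (r1 > 0) log(1 / r1) else NA_real_,
    recovery_time = if (r2 > 0) log(1 / r2) else NA_real_,
    alpha = alpha)
}

#' Per-market collapse/recovery table for a price panel
#'
#' Convenience wrapper running [locate_extrema()] and
#' [collapse_recovery_rates()] for every market of a tidy price panel.
#'
#' @param prices Tibble with \code{date}, \code{market_id}, \code{price}.
#' @param recession_start,recession_end Recession window (user input, e.g.
#'   from official recession indicators).
#' @param alpha Evaluation span, trading days.
#' @return Tibble, one row per market: extrema, rates, times;
#'   non-crash episodes carry \code{is_crash = FALSE} and missing rates.
#' @export
market_timing <- function(prices, recession_start, recession_end,
                          alpha = 100) {
  stopifnot(all(c("date", "market_id", "price") %in% names(prices)))
  prices |>
    dplyr::group_by(.data$market_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$date)
      ext <- locate_extrema(df, recession_start, recession_end)
      if (!ext$is_crash)
        return(dplyr::bind_cols(ext, tibble::tibble(
          r1 = NA_real_, r2 = NA_real_, response_time = NA_real_,
          recovery_time = NA_real_, alpha = alpha)))
      dplyr::bind_cols(ext,
        collapse_recovery_rates(df, ext$t_max, ext$t_min, alpha = alpha))
    }) |>
    dplyr::ungroup()
}

#' Baseline ES proximity of a stock market
#'
#' Estimates a market's proximity to explosive synchronization from its
#' baseline (pre-crisis) period, as the kurtosis of moving-window lagged
#' autocorrelations of a daily synchronization series (default lag 2
#' trading days, 60-day windows advancing 5 days).
#'
#' Two constructions of the daily series are supported. In \emph{panel}
#' mode (input has a \code{ticker} column) the series is the cross-
#' sectional sign coherence of constituent daily log-returns,
#' \eqn{r_t = |n^{-1}\sum_s \mathrm{sign}(\rho_{s,t})|} — an
#' order-parameter proxy measuring how uniformly stocks move together each
#' day. In \emph{index} mode the windowed ACF is taken directly on the
#' index's daily log-returns. Panel mode is preferred when constituents
#' are available; the mode is recorded in the output.
#'
#' @param prices Tibble with \code{date}, \code{market_id}, \code{price}
#'   and, for panel mode, \code{ticker}.
#' @param baseline_start,baseline_end Baseline period (>= 150 trading
#'   days).
#' @param lag ACF lag in trading days (default 2).
#' @param window_length,step Window parameters in trading days (defaults
#'   60 and 5).
#' @return Tibble, one row per market: \code{kurtosis}, \code{n_windows},
#'   \code{mode}, \code{low_confidence}.
#' @export
market_es_proximity <- function(prices, baseline_start, baseline_end,
                                lag = 2, window_length = 60, step = 5) {
  stopifnot(all(c("date", "market_id", "price") %in% names(prices)))
  panel <- "ticker" %in% names(prices)
  d <- as.Date(prices$date)
  base <- prices[d >= as.Date(baseline_start) & d <= as.Date(baseline_end), ]
  base |>
    dplyr::group_by(.data$market_id) |>
    dplyr::group_modify(function(df, key) {
      series <- if (panel) daily_sign_coherence(df)
                else index_return_series(df)
      if (length(series) < 150)
        stop("baseline has ", length(series),
             " trading days; need at least 150")
      if (stats::sd(series) == 0) stop("constant baseline series")
      w <- windowed_acf(series, window_length = window_length, step = step,
                        lag = lag, sampling_rate = 1)
      tibble::tibble(kurtosis = attr(w, "kurtosis"),
                     n_windows = attr(w, "n_windows"),
                     n_missing = attr(w, "n_missing"),
                     mode = if (panel) "panel" else "index",
                     low_confidence = attr(w, "low_confidence"))
    }) |>
    dplyr::ungroup()
}

# |mean of return signs| across constituents, per day
daily_sign_coherence <- function(df) {
  wide <- df |>
    dplyr::arrange(.data$date) |>
    dplyr::group_by(.data$ticker) |>
    dplyr::mutate(ret = c(NA, diff(log(.data$price)))) |>
    dplyr::ungroup() |>
    dplyr::filter(is.finite(.data$ret))
  out <- wide |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(r = abs(mean(sign(.data$ret))), .groups = "drop") |>
    dplyr::arrange(.data$date)
  out$r
}

index_return_series <- function(df) {
  df <- dplyr::arrange(df, .data$date)
  diff(log(df$price))
}
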