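#' Surrogate multichannel recording with known ES proximity
#'
#' Generates an EEG-like recording by running the oscillator network
#' itself at the critical coupling of a chosen feedback exponent
#' (\code{z_truth}), mapping node real parts to channels, decimating the
#' 1 kHz solver output to the target sampling rate, and adding white
#' sensor noise at a given SNR. Because the generator is the mechanistic
#' model rather than phenomenological noise, recovering \code{z_truth}
#' rank order through [es_proximity()] is a true round trip.
#'
#' @param n_channels Channels = oscillators (default 32).
#' @param sampling_rate Output rate, Hz (default 500; must divide the
#'   solver's 1000 Hz).
#' @param duration Recording length, seconds (default 180, the length of
#'   a resting-state baseline).
#' @param z_truth Feedback exponent used for generation (ground truth).
#' @param noise_snr Sensor-noise SNR in dB (\code{Inf} = clean).
#' @param topology Optional \code{sl_topology}; default a connected random
#'   graph with mean degree 8 drawn from \code{seed}.
#' @param s_star Optional known critical coupling; located (and cached per
#'   session) when missing.
#' @param omega Optional fixed per-node frequency vector (rad/s). Passing
#'   one pins the "subject": repeated recordings with different seeds then
#'   share the network's frequency configuration (and hence its critical
#'   coupling) and differ only in noise and initial state. Left
#'   \code{NULL}, each seed draws a fresh configuration.
#' @param omega_mean,omega_sd Frequency distribution of the oscillators,
#'   rad/s; defaults centred on the 10 Hz alpha rhythm.
#' @param seed Seed; fixtures are bit-reproducible given the spec.
#' @return A \code{multichannel_signal} with attribute \code{sidecar}
#'   (tibble: \code{z_truth}, \code{s_star}, \code{noise_snr},
#'   \code{seed}).
#' @export
make_surrogate_recording <- function(n_channels = 32, sampling_rate = 500,
                                     duration = 180, z_truth = 0,
                                     noise_snr = Inf, topology = NULL,
                                     s_star = NULL, omega = NULL,
                                     omega_mean = 2 * pi * 10,
                                     omega_sd = 2 * pi * 1, seed = 1L) {
  stopifnot(n_channels >= 2, duration > 0)
  dt <- 1e-3
  dec <- round(1 / dt / sampling_rate)
  if (abs(1 / dt / sampling_rate - dec) > 1e-9)
    stop("sampling_rate must divide the 1000 Hz solver rate")
  if (is.null(topology))
    topology <- generate_topology("random", n_channels,
                                  min(4 * n_channels,
                                      n_channels * (n_channels - 1) / 2),
                                  seed = seed)
  if (is.null(s_star))
    s_star <- cached_critical_coupling(topology, z_truth, omega_mean,
                                       omega_sd, seed)
  cfg <- sl_config(coupling = s_star, feedback_exponent = z_truth,
                   duration = duration, transient = 10, omega = omega,
                   omega_mean = omega_mean, omega_sd = omega_sd, dt = dt)
  tr <- simulate_network(topology, cfg, record_states = TRUE,
                         keep_every = dec, seed = seed)
  dat <- t(tr$states_re)  # channels x samples
  if (is.finite(noise_snr)) {
    sig_sd <- stats::sd(as.numeric(dat))
    noise_sd <- sig_sd / 10^(noise_snr / 20)
    dat <- dat + withr::with_seed(seed + 1L,
      matrix(stats::rnorm(length(dat), 0, noise_sd), nrow(dat)))
  }
  out <- multichannel_signal(dat, sampling_rate)
  attr(out, "sidecar") <- tibble::tibble(
    z_truth = z_truth, s_star = s_star, noise_snr = noise_snr,
    duration = duration, seed = seed)
  out
}

# session cache of critical couplings for surrogate generation
.sstar_cache <- new.env(parent = emptyenv())

cached_critical_coupling <- function(topology, z, omega_mean, omega_sd,
                                     seed) {
  key <- paste(topology$n_nodes, topology$n_links, topology$seed, z,
               signif(omega_mean, 6), signif(omega_sd, 6), sep = "|")
  if (!is.null(.sstar_cache[[key]])) return(.sstar_cache[[key]])
  cfg <- sl_config(coupling = 1, feedback_exponent = z, duration = 30,
                   transient = 5, omega_mean = omega_mean,
                   omega_sd = omega_sd)
  cp <- locate_critical_coupling(topology, z, config = cfg,
                                 seed = 10000L + round(100 * z))
  .sstar_cache[[key]] <- cp$s_star
  cp$s_star
}

#' Synthetic daily price panel with a controlled crash and rebound
#'
#' Geometric-random-walk index series per market with a gently rising
#' pre-crisis baseline, a crash segment (log-drift \code{-crash_speed} per
#' day until a fixed log depth is reached), a trough plateau of
#' \code{plateau_days}, a rebound segment (\code{+rebound_speed} per day
#' back to the pre-crash level), and, before the crash, constituent stocks
#' whose
#' cross-sectional coherence switches between high and low regimes
#' according to a two-state Markov chain. The regime separation scales
#' with \code{coherence_bistability} (0 = no regimes, Gaussian-like
#' windowed-ACF distribution; 1 = strongly bimodal coherence, heavy
#' tails), so the generator's bistability parameter is the ground-truth
#' ES proximity that [market_es_proximity()] should recover, and
#' \code{crash_speed}/\code{rebound_speed} are the ground truth for
#' [market_timing()].
#'
#' @param n_markets Number of markets.
#' @param n_days Trading days in the panel.
#' @param crash_day Index of the crash onset (interior).
#' @param crash_speed Per-market log-drop per day during the crash
#'   (scalar recycled; > 0).
#' @param rebound_speed Per-market log-gain per day during the rebound
#'   (> 0).
#' @param coherence_bistability Per-market ground-truth ES proximity in
#'   [0, 1].
#' @param crash_depth Total log drop of the crash (default 0.6, a ~45%
#'   drawdown).
#' @param plateau_days Days the index dwells at the trough before the
#'   rebound starts (default 20).
#' @param baseline_drift Pre-crisis log-drift per day (default 5e-4), so
#'   the in-recession maximum sits just before the crash as in real
#'   crises.
#' @param base_volatility Daily log-return SD outside drift segments
#'   (default 0.01).
#' @param n_stocks Constituents per market (default 40).
#' @param start_date First trading date (default 2006-01-02).
#' @param seed Seed.
#' @return A \code{market_panel} list: \code{$index} (date, market_id,
#'   price), \code{$stocks} (date, market_id, ticker, price),
#'   \code{$truth} (per-market ground truth incl. trough date).
#' @export
make_market_panel <- function(n_markets = 20, n_days = 900,
                              crash_day = 550, crash_speed = 0.02,
                              rebound_speed = 0.01,
                              coherence_bistability = 0.5,
                              crash_depth = 0.6, plateau_days = 20,
                              baseline_drift = 5e-4,
                              base_volatility = 0.01, n_stocks = 40,
                              start_date = as.Date("2006-01-02"),
                              seed = 1L) {
  stopifnot(n_markets >= 1, crash_day > 1, crash_day < n_days,
            all(crash_speed > 0), all(rebound_speed > 0),
            all(coherence_bistability >= 0 & coherence_bistability <= 1))
  crash_speed <- rep_len(crash_speed, n_markets)
  rebound_speed <- rep_len(rebound_speed, n_markets)
  bist <- rep_len(coherence_bistability, n_markets)
  dates <- start_date + seq_len(n_days) - 1

  withr::with_seed(seed, {
    per_market <- purrr::map(seq_len(n_markets), function(m) {
      L1 <- ceiling(crash_depth / crash_speed[m])
      L2 <- ceiling(crash_depth / rebound_speed[m])
      drift <- rep(baseline_drift, n_days)
      c1 <- crash_day:min(n_days, crash_day + L1 - 1)
      drift[c1] <- -crash_speed[m]
      plateau <- (crash_day + L1):min(n_days, crash_day + L1 +
                                        plateau_days - 1)
      if (plateau[1] <= n_days) drift[plateau[plateau <= n_days]] <- 0
      reb0 <- crash_day + L1 + plateau_days
      if (reb0 <= n_days) {
        c2 <- reb0:min(n_days, reb0 + L2 - 1)
        drift[c2] <- rebound_speed[m]
      }
      idx_ret <- drift + stats::rnorm(n_days, 0, base_volatility)
      price <- 100 * exp(cumsum(idx_ret))

      # two-state coherence regimes for the constituents
      dwell <- 20
      state <- integer(n_days)
      state[1] <- 1L
      for (t in 2:n_days)
        state[t] <- if (stats::runif(1) < 1 / dwell)
          3L - state[t - 1] else state[t - 1]
      # idiosyncratic vol: low in the coherent regime, scaled by bistability
      idio_sd <- ifelse(state == 1L,
                        base_volatility * (3 - 2.7 * bist[m]),
                        base_volatility * 3)
      common <- idx_ret
      stocks <- purrr::map(seq_len(n_stocks), function(s) {
        ret <- common + stats::rnorm(n_days, 0, idio_sd)
        tibble::tibble(date = dates,
                       market_id = sprintf("M%02d", m),
                       ticker = sprintf("M%02d_S%03d", m, s),
                       price = 10 * exp(cumsum(ret)))
      })
      list(index = tibble::tibble(date = dates,
                                  market_id = sprintf("M%02d", m),
                                  price = price),
           stocks = dplyr::bind_rows(stocks),
           truth = tibble::tibble(
             market_id = sprintf("M%02d", m),
             crash_speed = crash_speed[m],
             rebound_speed = rebound_speed[m],
             coherence_bistability = bist[m],
             crash_day = crash_day,
             trough_day = crash_day + L1 - 1,
             trough_date = dates[min(n_days, crash_day + L1 - 1)]))
    })
  })

  structure(list(index = dplyr::bind_rows(purrr::map(per_market, "index")),
                 stocks = dplyr::bind_rows(purrr::map(per_market, "stocks")),
                 truth = dplyr::bind_rows(purrr::map(per_market, "truth")),
                 seed = seed),
            class = "market_panel")
}

#' @export
print.market_panel <- function(x, ...) {
  cat(sprintf("<market_panel> %d markets x %d days (%d stocks each), seed %d\n",
              dplyr::n_distinct(x$index$market_id),
              dplyr::n_distinct(x$index$date),
              dplyr::n_distinct(x$stocks$ticker) /
                dplyr::n_distinct(x$index$market_id), x$seed))
  invisible(x)
}

#' @describeIn make_market_panel Ground-truth table.
#' @param x A \code{market_panel}.
#' @param ... Unused.
#' @export
tidy.market_panel <- function(x, ...) x$truth
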