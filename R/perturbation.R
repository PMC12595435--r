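#' Baseline zone of windowed-ACF values
#'
#' The baseline critical state is summarized by the mean of its windowed
#' ACF values and a half-width of three standard deviations; the network
#' has "lost" the baseline state when its windowed ACF leaves
#' \code{[mean - 3 SD, mean + 3 SD]} and has recovered when it returns.
#'
#' @param baseline_acf A \code{windowed_acf} restricted to the baseline
#'   period, or a numeric vector of baseline ACF values; at least 10
#'   non-missing windows.
#' @return One-row tibble: \code{mean}, \code{half_width} (3 SD),
#'   \code{lower}, \code{upper}, \code{n_windows}.
#' @export
baseline_zone <- function(baseline_acf) {
  v <- if (inherits(baseline_acf, "windowed_acf")) baseline_acf$acf
       else as.numeric(baseline_acf)
  v <- v[is.finite(v)]
  if (length(v) < 10)
    stop("need at least 10 baseline windows, got ", length(v))
  s <- stats::sd(v)
  if (s <= 0) stop("degenerate baseline: zero SD of ACF values")
  tibble::tibble(mean = mean(v), half_width = 3 * s,
                 lower = mean(v) - 3 * s, upper = mean(v) + 3 * s,
                 n_windows = length(v))
}

#' Time to loss and recovery of the baseline critical state
#'
#' Walks a windowed-ACF timeline spanning a perturbation and measures, on
#' window-center time stamps: the loss time (first post-onset window whose
#' ACF falls outside the baseline zone, minus the onset) and the recovery
#' time (first post-offset window that begins a run of \code{dwell}
#' consecutive in-zone windows, minus the offset). A network that never
#' leaves the zone has a censored loss and, by convention, recovery time 0
#' (it is already in zone at offset). Missing-ACF windows count as
#' out-of-zone for loss and break an in-zone run for recovery.
#'
#' @param acf_timeline A \code{windowed_acf} (or any data frame with
#'   columns \code{t_center} and \code{acf}) covering baseline,
#'   perturbation, and post-offset horizon (one series clock).
#' @param zone A [baseline_zone()] row.
#' @param onset,offset Perturbation window, seconds on the series clock.
#' @param dwell Consecutive in-zone windows required to declare recovery
#'   (default 3; 1 reproduces the literal crossing rule).
#' @return One-row tibble: \code{loss_time}, \code{recovery_time},
#'   \code{loss_censored}, \code{recovery_censored}.
#' @export
measure_response <- function(acf_timeline, zone, onset, offset, dwell = 3) {
  stopifnot(all(c("t_center", "acf") %in% names(acf_timeline)),
            offset > onset, dwell >= 1)
  tc <- acf_timeline$t_center
  if (onset < min(tc) || offset > max(tc))
    stop("perturbation window lies outside the ACF timeline")
  a <- acf_timeline$acf
  inzone <- is.finite(a) & a >= zone$lower & a <= zone$upper

  post_on <- which(tc > onset)
  exit <- post_on[!inzone[post_on]][1]
  loss_censored <- is.na(exit)
  loss_time <- if (loss_censored) NA_real_ else tc[exit] - onset

  if (loss_censored) {
    return(tibble::tibble(loss_time = NA_real_, recovery_time = 0,
                          loss_censored = TRUE, recovery_censored = FALSE))
  }
  post_off <- which(tc > offset)
  rec_idx <- NA_integer_
  run <- 0L
  for (i in post_off) {
    run <- if (inzone[i]) run + 1L else 0L
    if (run >= dwell) { rec_idx <- i - dwell + 1L; break }
  }
  recovery_censored <- is.na(rec_idx)
  tibble::tibble(
    loss_time = loss_time,
    recovery_time = if (recovery_censored) NA_real_
                    else max(tc[rec_idx] - offset, 0),
    loss_censored = FALSE,
    recovery_censored = recovery_censored)
}

#' Perturbation experiment across ES proximities
#'
#' The in-silico protocol behind the loss/recovery correlations: for each
#' feedback exponent Z, find the network's critical coupling (peak PCF;
#' cached across Z via \code{s_star}), then repeatedly (i) simulate a
#' baseline period at S*, (ii) apply a global pulse, (iii) follow the
#' windowed ACF through a post-offset horizon, and (iv) record the baseline
#' ACF kurtosis (the ES-proximity estimate) together with the loss and
#' recovery times of [measure_response()]. The summary correlates baseline
#' kurtosis with both times across all rows (Spearman): proximity to
#' explosive synchronization predicts fast loss and slow recovery.
#'
#' @param topology An \code{sl_topology}, or a one-off spec list
#'   \code{list(kind =, n_nodes =, n_links =, seed =)}.
#' @param z_grid Feedback exponents (default the seven-point grid
#'   \code{seq(0, 3, 0.5)}).
#' @param n_realizations Rows per Z (default 25).
#' @param pulse_strength,pulse_duration The square pulse (defaults 10 and
#'   5 s).
#' @param baseline Baseline length before onset, seconds (default 120,
#'   i.e. 23 baseline windows at the default windowing — enough for stable
#'   zone and kurtosis estimates; must keep at least 10 windows).
#' @param horizon Post-offset follow-up, seconds (default 300).
#' @param window_length,step,dwell Windowed-ACF and recovery parameters.
#' @param censored How censored times enter the summary correlations:
#'   \code{"exclude"} drops them, \code{"horizon"} scores them at the
#'   horizon (rank-preserving right-censoring; the default, since slow
#'   recoveries are exactly the informative ones).
#' @param s_star Optional named numeric vector of precomputed critical
#'   couplings (names = Z values), e.g. from a previous run's attribute
#'   \code{"s_star"}.
#' @param seed Master seed; everything else derives from it.
#' @return An \code{es_experiment}: [tidy()] gives per-row results
#'   (\code{z, realization, s_star, kurtosis, loss_time, recovery_time,
#'   loss_censored, recovery_censored, seed}), [glance()] the Spearman
#'   summaries \code{rho_loss, p_loss, rho_recovery, p_recovery} with row
#'   counts. Attribute \code{"s_star"} carries the per-Z critical
#'   couplings for reuse.
#' @export
run_es_experiment <- function(topology, z_grid = seq(0, 3, by = 0.5),
                              n_realizations = 25,
                              pulse_strength = 10, pulse_duration = 5,
                              baseline = 120, horizon = 300,
                              window_length = 10, step = 5, dwell = 3,
                              censored = c("horizon", "exclude"),
                              s_star = NULL, seed = 1L) {
  censored <- match.arg(censored)
  if (!inherits(topology, "sl_topology"))
    topology <- generate_topology(topology$kind, topology$n_nodes,
                                  topology$n_links,
                                  seed = topology$seed %||% seed)
  onset <- baseline
  offset <- baseline + pulse_duration
  duration <- baseline + pulse_duration + horizon

  ss <- numeric(length(z_grid))
  names(ss) <- as.character(z_grid)
  for (i in seq_along(z_grid)) {
    zc <- as.character(z_grid[i])
    if (!is.null(s_star) && zc %in% names(s_star)) {
      ss[i] <- s_star[[zc]]
    } else {
      cp <- locate_critical_coupling(topology, z_grid[i],
                                     seed = seed + 131L * i)
      ss[i] <- cp$s_star
    }
  }

  rows <- purrr::map_dfr(seq_along(z_grid), function(i) {
    z <- z_grid[i]
    purrr::map_dfr(seq_len(n_realizations), function(real) {
      run_seed <- seed + 7919L * i + 17L * real
      cfg <- sl_config(coupling = ss[i], feedback_exponent = z,
                       duration = duration, transient = 10)
      row <- tryCatch({
        tr <- simulate_network(topology, cfg,
                perturbation = perturbation(pulse_strength, onset, offset),
                seed = run_seed)
        w <- windowed_acf(tr, window_length = window_length, step = step)
        base <- w[w$t_center < onset, , drop = FALSE]
        zone <- baseline_zone(base)
        kurt <- kurtosis_pearson(base$acf[is.finite(base$acf)])
        timing <- measure_response(w, zone, onset, offset, dwell = dwell)
        dplyr::bind_cols(
          tibble::tibble(z = z, realization = real, s_star = ss[i],
                         kurtosis = kurt),
          timing,
          tibble::tibble(seed = run_seed, failed = FALSE))
      }, error = function(e) {
        tibble::tibble(z = z, realization = real, s_star = ss[i],
                       kurtosis = NA_real_, loss_time = NA_real_,
                       recovery_time = NA_real_, loss_censored = NA,
                       recovery_censored = NA, seed = run_seed,
                       failed = TRUE)
      })
      row
    })
  })

  summ <- tryCatch(summarize_es_experiment(rows, horizon, censored),
                   error = function(e) {
                     warning("summary refused: ", conditionMessage(e),
                             call. = FALSE)
                     NULL
                   })
  structure(list(rows = rows, summary = summ,
                 censored = censored, horizon = horizon),
            class = "es_experiment", s_star = ss)
}

summarize_es_experiment <- function(rows, horizon, censored) {
  ok <- rows[!rows$failed & is.finite(rows$kurtosis), , drop = FALSE]
  loss <- ok$loss_time
  if (censored == "horizon") loss[ok$loss_censored] <- horizon
  keep_l <- is.finite(loss)
  rec <- ok$recovery_time
  if (censored == "horizon") rec[ok$recovery_censored] <- horizon
  keep_r <- is.finite(rec)
  if (sum(keep_l) < 10 || sum(keep_r) < 10)
    stop("summary requires at least 10 usable rows for each correlation")
  cl <- rank_correlation(ok$kurtosis[keep_l], loss[keep_l])
  cr <- rank_correlation(ok$kurtosis[keep_r], rec[keep_r])
  tibble::tibble(rho_loss = cl$rho, p_loss = cl$p_value, n_loss = cl$n,
                 rho_recovery = cr$rho, p_recovery = cr$p_value,
                 n_recovery = cr$n,
                 n_loss_censored = sum(ok$loss_censored),
                 n_recovery_censored = sum(ok$recovery_censored))
}

#' @export
print.es_experiment <- function(x, ...) {
  cat("<es_experiment>", nrow(x$rows), "rows over Z in {",
      paste(unique(x$rows$z), collapse = ", "), "}\n")
  if (is.null(x$summary)) cat("  (no summary: too few usable rows)\n")
  else print(x$summary)
  invisible(x)
}

#' @describeIn run_es_experiment Per-realization rows.
#' @param x An \code{es_experiment}.
#' @param ... Unused.
#' @export
tidy.es_experiment <- function(x, ...) x$rows

#' @describeIn run_es_experiment One-row Spearman summary.
#' @export
glance.es_experiment <- function(x, ...) x$summary

#' @describeIn run_es_experiment Baseline kurtosis against loss and
#'   recovery time (censored times at the horizon), one panel each.
#' @param object An \code{es_experiment}.
#' @export
autoplot.es_experiment <- function(object, ...) {
  df <- object$rows |>
    dplyr::filter(!.data$failed) |>
    dplyr::mutate(
      loss_time = ifelse(.data$loss_censored, object$horizon,
                         .data$loss_time),
      recovery_time = ifelse(.data$recovery_censored, object$horizon,
                             .data$recovery_time)) |>
    tidyr::pivot_longer(c("loss_time", "recovery_time"),
                        names_to = "response", values_to = "time")
  ggplot2::ggplot(df, ggplot2::aes(.data$kurtosis, .data$time,
                                   colour = factor(.data$z))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = "baseline ACF kurtosis (ES proximity)", y = "time (s)",
                  colour = "Z")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
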