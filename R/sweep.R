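#' Sweep the coupling strength across its synchronization transition
#'
#' Runs the network at each coupling in \code{s_grid} and tabulates, per
#' grid point and realization, the mean order parameter, the PCF, and the
#' mean and kurtosis of the windowed lagged ACF. Ascending (\code{"up"})
#' sweeps start each grid point from a fresh random incoherent state — the
#' forward branch, and the stationary statistics used to find the peak-PCF
#' critical point. Descending (\code{"down"}) sweeps start from a coherent
#' state and carry the final state of one grid point into the next, the
#' adiabatic protocol that traces the upper branch of a hysteresis loop.
#' \code{"both"} returns the paired curves; their gap (see
#' [hysteresis_area()]) widens with the feedback exponent Z as the
#' transition turns explosive.
#'
#' @param topology An \code{sl_topology}.
#' @param config An \code{sl_config}; its \code{coupling} entry is ignored.
#' @param s_grid Ascending coupling values.
#' @param n_realizations Realizations per grid point (distinct seeds).
#' @param direction \code{"up"}, \code{"down"}, or \code{"both"}.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param acf_window,acf_step Windowing (s) for the per-point windowed ACF;
#'   defaults 2 and 1 suit the short per-point runs of a sweep.
#' @return A \code{coupling_sweep} tibble: \code{direction}, \code{s},
#'   \code{realization}, \code{mean_r}, \code{pcf}, \code{acf_mean},
#'   \code{acf_kurtosis}, \code{seed}, \code{failed}. Simulation failures at
#'   single grid points are recorded, not propagated.
#' @examples
#' \donttest{
#' topo <- generate_topology("random", 30, 60, seed = 1)
#' cfg <- sl_config(coupling = NA, duration = 10, transient = 2)
#' sw <- sweep_coupling(topo, cfg, s_grid = c(0.2, 0.6, 1, 1.4), seed = 1)
#' find_critical_point(sw)
#' }
#' @export
sweep_coupling <- function(topology, config, s_grid, n_realizations = 1,
                           direction = c("up", "down", "both"), seed = 1L,
                           acf_window = 2, acf_step = 1) {
  direction <- match.arg(direction)
  stopifnot(length(s_grid) >= 1, !is.unsorted(s_grid), n_realizations >= 1)
  dirs <- if (direction == "both") c("up", "down") else direction

  rows <- purrr::map_dfr(dirs, function(dir) {
    grid <- if (dir == "down") rev(s_grid) else s_grid
    purrr::map_dfr(seq_len(n_realizations), function(real) {
      run_seed <- seed + 7919L * real + if (dir == "down") 104729L else 0L
      z_carry <- if (dir == "down")
        complex(modulus = sqrt(max(mean(rep_len(config$lambda,
                                                topology$n_nodes)), 0.25)),
                argument = 0)[rep(1, topology$n_nodes)]
      else NULL
      out <- vector("list", length(grid))
      for (i in seq_along(grid)) {
        cfg_i <- config
        cfg_i$coupling <- grid[i]
        tr <- tryCatch(
          simulate_network(topology, cfg_i, seed = run_seed + i,
                           z0 = z_carry),
          error = function(e) e)
        if (inherits(tr, "error")) {
          out[[i]] <- tibble::tibble(
            direction = dir, s = grid[i], realization = real,
            mean_r = NA_real_, pcf = NA_real_, acf_mean = NA_real_,
            acf_kurtosis = NA_real_, seed = run_seed + i, failed = TRUE)
          next
        }
        if (dir == "down") z_carry <- tr$z_final
        wa <- tryCatch(windowed_acf(tr, window_length = acf_window,
                                    step = acf_step),
                       error = function(e) NULL)
        out[[i]] <- tibble::tibble(
          direction = dir, s = grid[i], realization = real,
          mean_r = mean(tr$r), pcf = pcf(tr),
          acf_mean = if (is.null(wa)) NA_real_ else
            mean(wa$acf, na.rm = TRUE),
          acf_kurtosis = if (is.null(wa)) NA_real_ else
            attr(wa, "kurtosis"),
          seed = run_seed + i, failed = FALSE)
      }
      dplyr::bind_rows(out)
    })
  })
  rows <- dplyr::arrange(rows, .data$direction, .data$s, .data$realization)
  structure(rows, class = c("coupling_sweep", class(rows)),
            n_oscillators = topology$n_nodes,
            feedback_exponent = config$feedback_exponent,
            direction = direction)
}

#' @describeIn sweep_coupling Mean order parameter and PCF against coupling,
#'   one panel each, up/down branches coloured.
#' @param object A \code{coupling_sweep}.
#' @param ... Unused.
#' @export
autoplot.coupling_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$direction, .data$s) |>
    dplyr::summarise(mean_r = mean(.data$mean_r, na.rm = TRUE),
                     pcf = mean(.data$pcf, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_longer(c("mean_r", "pcf"), names_to = "statistic")
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$value,
                                   colour = .data$direction)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "coupling S", y = NULL)
}

#' Area between the ascending and descending synchronization curves
#'
#' Trapezoid-rule area between the up and down branches of a
#' \code{direction = "both"} sweep — the hysteresis size, which grows with
#' the feedback exponent Z.
#'
#' @param sweep A \code{coupling_sweep} containing both directions.
#' @return Scalar area (>= 0 up to simulation noise).
#' @export
hysteresis_area <- function(sweep) {
  df <- tibble::as_tibble(sweep) |>
    dplyr::group_by(.data$direction, .data$s) |>
    dplyr::summarise(mean_r = mean(.data$mean_r, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "direction", values_from = "mean_r")
  if (!all(c("up", "down") %in% names(df)))
    stop("hysteresis_area needs a direction = 'both' sweep")
  df <- dplyr::arrange(df, .data$s)
  gap <- df$down - df$up
  sum(diff(df$s) * (gap[-1] + gap[-length(gap)]) / 2)
}

#' Locate the critical coupling of a network at a given ES proximity
#'
#' Two-stage search for the peak-PCF critical point: a coarse geometric
#' ascending sweep brackets the synchronization jump (the first coupling
#' whose mean order parameter exceeds \code{r_jump}), then a fine linear
#' sweep over the bracket is handed to [find_critical_point()]. The
#' fluctuation-driven jump of a feedback network (Z > 0) moves to larger S
#' roughly geometrically in Z, which is why the coarse stage is geometric.
#'
#' @param topology An \code{sl_topology}.
#' @param feedback_exponent Z.
#' @param config Base \code{sl_config} (coupling ignored); default is a
#'   30 s / 5 s-transient probe configuration.
#' @param s_min,s_max,coarse_factor Geometric coarse grid parameters.
#' @param n_fine Fine grid size across the bracket.
#' @param n_realizations Realizations per fine grid point.
#' @param r_jump Mean-r threshold declaring the synchronized branch.
#' @param seed Master seed.
#' @return One-row tibble from [find_critical_point()] (columns
#'   \code{s_star}, \code{pcf_peak}, \code{endpoint}, \code{flat}) plus the
#'   fine \code{coupling_sweep} as attribute \code{"sweep"}.
#' @export
locate_critical_coupling <- function(topology, feedback_exponent,
                                     config = NULL,
                                     s_min = 0.2, s_max = 400,
                                     coarse_factor = 1.35, n_fine = 13,
                                     n_realizations = 2, r_jump = 0.55,
                                     seed = 1L) {
  if (is.null(config))
    config <- sl_config(coupling = 1, feedback_exponent = feedback_exponent,
                        duration = 30, transient = 5)
  config$feedback_exponent <- feedback_exponent
  s <- s_min
  prev <- s_min
  jump_at <- NA_real_
  i <- 0L
  while (s <= s_max) {
    i <- i + 1L
    cfg <- config
    cfg$coupling <- s
    tr <- simulate_network(topology, cfg, seed = seed + i)
    if (mean(tr$r) > r_jump) { jump_at <- s; break }
    prev <- s
    s <- s * coarse_factor
  }
  if (is.na(jump_at))
    stop("no synchronization jump found below s_max = ", s_max)
  # extend half a coarse notch past the jump so the PCF peak is interior
  fine <- seq(prev / coarse_factor, jump_at * sqrt(coarse_factor),
              length.out = n_fine)
  sw <- sweep_coupling(topology, config, fine,
                       n_realizations = n_realizations, seed = seed + 1000L)
  cp <- find_critical_point(sw)
  attr(cp, "sweep") <- sw
  cp
}
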