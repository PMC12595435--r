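#' Configure a feedback-modified Stuart-Landau network simulation
#'
#' Collects every model parameter for [simulate_network()]. Each node j obeys
#' \deqn{\dot z_j = (\lambda_j + i\omega_j - |z_j|^2) z_j
#'       + S G_j(t)^Z \sum_k A_{jk} z_k(t-\tau_{jk})
#'       + \beta \xi_j(t) + u(t),}
#' where the adaptive feedback gain \eqn{G(t)} is, by default, the global
#' instantaneous Kuramoto order parameter \eqn{R(t)} computed from the
#' current phases (\code{feedback_mode = "order_parameter"}): global
#' synchrony feeds back into the local effective coupling
#' \eqn{k_j S R^Z}, suppressing it while the network is incoherent and
#' reinforcing it once synchrony builds. \eqn{Z = 0}
#' (\code{feedback_exponent}) is a conventionally coupled network with a
#' gradual (second-order) synchronization transition; raising \eqn{Z}
#' makes the transition increasingly abrupt and hysteretic — i.e. moves
#' the network toward explosive synchronization, and moves the
#' fluctuation-driven jump to larger S roughly geometrically in Z.
#' \code{feedback_mode = "amplitude"} instead uses the node's own
#' amplitude \eqn{G_j = |z_j|}; that variant is only stable at small
#' \eqn{Z} (the coupling drive grows as \eqn{|z|^{Z+1}} and escapes the
#' cubic damping for \eqn{Z \ge 2}) and is provided for exploration.
#'
#' @param coupling Global coupling strength S (dimensionless).
#' @param feedback_exponent Feedback exponent Z >= 0.
#' @param duration Simulated time returned, seconds (after the transient).
#' @param transient Initial interval discarded, seconds.
#' @param omega Per-node angular frequencies (rad/s), or \code{NULL} to draw
#'   i.i.d. Gaussian with \code{omega_mean}/\code{omega_sd} at simulation
#'   time (a fresh frequency configuration per realization).
#' @param omega_mean,omega_sd Mean and SD of drawn frequencies, rad/s.
#'   Defaults \code{2*pi*10} and \code{2*pi*1}: an alpha-band-like 10 Hz
#'   population with 1 Hz spread.
#' @param lambda Per-node bifurcation parameter (1/s); scalar recycled.
#'   The default 1 puts every node in the self-oscillatory regime with
#'   uncoupled limit-cycle amplitude \eqn{\sqrt\lambda = 1}.
#' @param delay Link delay \eqn{\tau_{jk}} in seconds: a scalar applied to
#'   every link (default 10 ms) or a full per-link matrix. Must be an
#'   integer multiple of \code{dt}.
#' @param noise_scale Noise variance rate \eqn{\beta} (default 0.05): each
#'   of the real and imaginary parts of every node receives independent
#'   Gaussian increments of variance \code{noise_scale * dt} per step,
#'   i.e. white noise of variance \eqn{\beta} per unit time.
#' @param dt Integration step, seconds (default 1 ms, ~100 steps per 10 Hz
#'   cycle).
#' @param coupling_mode \code{"direct"} (default) couples through the
#'   delayed neighbour states \eqn{z_k(t-\tau)}; \code{"diffusive"} through
#'   \eqn{z_k(t-\tau) - z_j(t)}. The direct form supports the full
#'   incoherent-to-synchronized transition at these parameters; strong
#'   diffusive coupling instead drives the network into amplitude death
#'   (see the methods vignette).
#' @param feedback_mode \code{"order_parameter"} (default): global gain
#'   \eqn{G = R(t)}; \code{"amplitude"}: per-node gain \eqn{G_j = |z_j|}
#'   (small-Z exploration only).
#' @param seed Default seed used by [simulate_network()] when none is given.
#'
#' @return An object of class \code{sl_config} (a list of the above).
#' @export
sl_config <- function(coupling, feedback_exponent = 0, duration = 60,
                      transient = 10, omega = NULL,
                      omega_mean = 2 * pi * 10, omega_sd = 2 * pi * 1,
                      lambda = 1, delay = 0.010, noise_scale = 0.05,
                      dt = 1e-3,
                      coupling_mode = c("direct", "diffusive"),
                      feedback_mode = c("order_parameter", "amplitude"),
                      seed = 1L) {
  coupling_mode <- match.arg(coupling_mode)
  feedback_mode <- match.arg(feedback_mode)
  stopifnot(dt > 0, duration > 0, transient >= 0, noise_scale >= 0,
            feedback_exponent >= 0, coupling >= 0)
  structure(list(coupling = coupling, feedback_exponent = feedback_exponent,
                 duration = duration, transient = transient,
                 omega = omega, omega_mean = omega_mean, omega_sd = omega_sd,
                 lambda = lambda, delay = delay, noise_scale = noise_scale,
                 dt = dt, coupling_mode = coupling_mode,
                 feedback_mode = feedback_mode, seed = seed),
            class = "sl_config")
}

#' Specify a global pulsatile perturbation
#'
#' A square pulse u(t) of strength \code{strength} applied identically to
#' every node between \code{onset} and \code{offset} (seconds, on the
#' simulation clock that starts at 0 with the transient).
#'
#' @param strength Pulse amplitude p (>= 0).
#' @param onset,offset Pulse start and end, seconds; \code{offset > onset}.
#' @return An object of class \code{sl_perturbation}.
#' @export
perturbation <- function(strength = 10, onset, offset) {
  stopifnot(strength >= 0, offset > onset, onset >= 0)
  structure(list(strength = strength, onset = onset, offset = offset),
            class = "sl_perturbation")
}

#' Simulate the oscillator network
#'
#' Integrates the network of [sl_config()] on a topology from
#' [generate_topology()] with stochastic Euler-Maruyama (compiled; delays
#' via a ring buffer whose pre-history is the initial state). Initial phases
#' are uniform on \eqn{(-\pi, \pi]}, initial amplitudes 0.5. Runs are
#' bit-reproducible for a fixed seed.
#'
#' @param topology An \code{sl_topology}.
#' @param config An \code{sl_config}.
#' @param perturbation An [perturbation()] or \code{NULL}. Onset/offset are
#'   relative to the start of the *returned* series (i.e. after the
#'   transient).
#' @param record_states Keep per-node complex states (memory permitting)?
#' @param keep_every Thinning for recorded states, in steps.
#' @param seed Overrides \code{config$seed}.
#' @param z0 Optional complex vector of initial node states (length
#'   \code{n_nodes}); by default phases are drawn uniform with amplitude
#'   0.5. Used e.g. to carry state across a descending coupling sweep.
#'
#' @return An \code{sl_trajectory}: order-parameter series \code{r} with
#'   \code{sampling_rate = 1/dt}, start time \code{t0 = transient}, and, if
#'   requested, state matrices \code{states_re}/\code{states_im} (time in
#'   rows, nodes in columns). Use [tidy()] for a \code{(time, r)} tibble and
#'   [trajectory_phases()]/[trajectory_amplitudes()] for node-level series.
#'
#' @examples
#' topo <- generate_topology("random", 20, 40, seed = 1)
#' cfg <- sl_config(coupling = 0.5, duration = 5, transient = 1)
#' traj <- simulate_network(topo, cfg, seed = 1)
#' head(tidy(traj))
#' @export
simulate_network <- function(topology, config, perturbation = NULL,
                             record_states = FALSE, keep_every = 1L,
                             seed = NULL, z0 = NULL) {
  stopifnot(inherits(topology, "sl_topology"), inherits(config, "sl_config"))
  if (is.null(seed)) seed <- config$seed
  n <- topology$n_nodes
  dt <- config$dt
  total <- config$transient + config$duration
  n_steps <- round(total / dt)
  transient_steps <- round(config$transient / dt)

  edges <- topology_edges(topology)
  edge_delay <- delay_steps(config$delay, edges, topology, dt)

  lambda <- rep_len(config$lambda, n)
  pert <- c(0, -1, -1)
  if (!is.null(perturbation)) {
    stopifnot(inherits(perturbation, "sl_perturbation"))
    if (perturbation$offset > config$duration)
      stop("perturbation window must lie within the simulated duration")
    pert <- c(perturbation$strength,
              transient_steps + round(perturbation$onset / dt),
              transient_steps + round(perturbation$offset / dt))
  }

  withr::with_seed(seed, {
    omega <- config$omega
    if (is.null(omega))
      omega <- stats::rnorm(n, config$omega_mean, config$omega_sd)
    omega <- rep_len(omega, n)
    th0 <- stats::runif(n, -pi, pi)
    if (is.null(z0)) z0 <- complex(modulus = 0.5, argument = th0)
    stopifnot(length(z0) == n)
    raw <- sl_integrate_cpp(
      edges$src, edges$dst, edge_delay, n, omega, lambda,
      config$coupling, config$feedback_exponent,
      sqrt(config$noise_scale * dt), dt, n_steps, transient_steps,
      pert[1], pert[2], pert[3],
      Re(z0), Im(z0),
      config$coupling_mode == "diffusive",
      is.null(config$feedback_mode) || config$feedback_mode == "amplitude",
      record_states, as.integer(keep_every), 1e3)
  })

  structure(list(r = raw$r, t0 = raw$t0, sampling_rate = 1 / dt,
                 n_oscillators = n, omega = omega,
                 z_final = complex(real = raw$z_final_re,
                                   imaginary = raw$z_final_im),
                 states_re = raw$states_re, states_im = raw$states_im,
                 keep_every = if (record_states) keep_every else NA_integer_,
                 config = config, perturbation = perturbation, seed = seed),
            class = "sl_trajectory")
}

delay_steps <- function(delay, edges, topology, dt) {
  if (is.matrix(delay)) {
    stopifnot(dim(delay) == dim(topology$adjacency))
    d <- delay[cbind(edges$dst + 1L, edges$src + 1L)]
  } else {
    d <- rep_len(delay, length(edges$src))
  }
  steps <- d / dt
  if (any(abs(steps - round(steps)) > 1e-8))
    stop("every delay must be an integer multiple of dt")
  as.integer(round(steps))
}

#' @export
print.sl_trajectory <- function(x, ...) {
  cat(sprintf(
    "<sl_trajectory> N = %d, S = %g, Z = %g: %d samples at %g Hz (t0 = %g s)\n",
    x$n_oscillators, x$config$coupling, x$config$feedback_exponent,
    length(x$r), x$sampling_rate, x$t0))
  cat(sprintf("  mean r = %.3f\n", mean(x$r)))
  invisible(x)
}

#' @describeIn simulate_network Tibble with columns \code{time} (s; the
#'   series clock starts at 0 when the transient ends, the same clock used
#'   by perturbation onsets and windowed-ACF centers) and \code{r}
#'   (instantaneous order parameter).
#' @param x An \code{sl_trajectory}.
#' @param ... Unused.
#' @export
tidy.sl_trajectory <- function(x, ...) {
  tibble::tibble(time = (seq_along(x$r) - 1) / x$sampling_rate,
                 r = x$r)
}

#' @describeIn simulate_network Order-parameter trace r(t); the
#'   perturbation window, if any, is shaded.
#' @param object An \code{sl_trajectory}.
#' @export
autoplot.sl_trajectory <- function(object, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time, .data$r)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "order parameter r(t)",
                  title = sprintf("N = %d, S = %.3g, Z = %g",
                                  object$n_oscillators,
                                  object$config$coupling,
                                  object$config$feedback_exponent))
  if (!is.null(object$perturbation))
    p <- p + ggplot2::annotate("rect",
      xmin = object$perturbation$onset, xmax = object$perturbation$offset,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  p
}

#' @describeIn simulate_network One-row summary of the run.
#' @export
glance.sl_trajectory <- function(x, ...) {
  tibble::tibble(n_oscillators = x$n_oscillators,
                 coupling = x$config$coupling,
                 feedback_exponent = x$config$feedback_exponent,
                 duration = x$config$duration,
                 mean_r = mean(x$r), var_r = stats::var(x$r),
                 seed = x$seed)
}

#' Node-level phases and amplitudes of a recorded trajectory
#'
#' Require \code{record_states = TRUE} in [simulate_network()].
#'
#' @param trajectory An \code{sl_trajectory}.
#' @return A matrix (time in rows, nodes in columns) of phases in
#'   \eqn{(-\pi, \pi]} or amplitudes \eqn{|z_j| \ge 0}.
#' @export
trajectory_phases <- function(trajectory) {
  stopifnot(!is.null(trajectory$states_re))
  atan2(trajectory$states_im, trajectory$states_re)
}

#' @rdname trajectory_phases
#' @export
trajectory_amplitudes <- function(trajectory) {
  stopifnot(!is.null(trajectory$states_re))
  sqrt(trajectory$states_re^2 + trajectory$states_im^2)
}
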