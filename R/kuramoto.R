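#' Configuration of the delay-coupled Kuramoto simulation
#'
#' The model evolves one phase per cortical node,
#' `dtheta_i/dt = 2*pi*f + k * sum_j C_ij * sin(theta_j(t - tau_ij) - theta_i(t))`,
#' with delays `tau_ij = L_ij / v` proportional to fiber length. The
#' conduction velocity can be given directly or through the mean delay
#' `mean_delay_ms = mean(L) / v` over connected edges (give exactly one).
#'
#' @param coupling global coupling constant `k`.
#' @param mean_delay_ms mean interaction delay in ms (alternative to
#'   `conduction_velocity_m_s`).
#' @param conduction_velocity_m_s conduction velocity in m/s.
#' @param natural_frequency_hz oscillator natural frequency (default 60 Hz,
#'   gamma band).
#' @param dt_ms integration step (default 0.2 ms).
#' @param noise_sd_rad_s SD of white phase noise in rad/s (0 = deterministic
#'   Heun; the stochastic variant uses 1.25).
#' @param duration_s total simulated duration including the transient.
#' @param transient_discard_s initial coupled dynamics discarded (default 20 s).
#' @param seed integer seed for initial phases and noise.
#' @param record_every keep every `record_every`-th integration step in the
#'   returned trajectory (default 1).
#' @return A `kuramoto_config` list.
#' @export
kuramoto_config <- function(coupling, mean_delay_ms = NULL,
                            conduction_velocity_m_s = NULL,
                            natural_frequency_hz = 60, dt_ms = 0.2,
                            noise_sd_rad_s = 0, duration_s = 60,
                            transient_discard_s = 20, seed = 1,
                            record_every = 1L) {
  if (is.null(mean_delay_ms) == is.null(conduction_velocity_m_s))
    stop("give exactly one of mean_delay_ms or conduction_velocity_m_s")
  if (dt_ms <= 0) stop("dt_ms must be positive")
  if (duration_s <= transient_discard_s)
    stop("duration_s must exceed transient_discard_s")
  if (natural_frequency_hz <= 0) stop("natural frequency must be positive")
  structure(list(coupling = coupling, mean_delay_ms = mean_delay_ms,
                 conduction_velocity_m_s = conduction_velocity_m_s,
                 natural_frequency_hz = natural_frequency_hz, dt_ms = dt_ms,
                 noise_sd_rad_s = noise_sd_rad_s, duration_s = duration_s,
                 transient_discard_s = transient_discard_s, seed = seed,
                 record_every = as.integer(record_every)),
            class = "kuramoto_config")
}

#' Interaction delays from fiber lengths
#'
#' Converts fiber lengths to per-edge delays `tau_ij = L_ij / v`. When the
#' configuration specifies a mean delay, the velocity is derived as
#' `v = mean(L) / mean_delay` with the mean taken over connected edges, so
#' the edge whose length equals the mean length gets exactly the mean delay.
#' Delays are discretized to integration steps by nearest-integer rounding
#' with a minimum of one step.
#'
#' @param sc a [structural_connectome()] (weights define which delays exist).
#' @param config a [kuramoto_config()].
#' @return A list with `delays_ms`, `delay_steps`, `velocity_m_s`,
#'   `mean_length_mm`.
#' @export
build_delays <- function(sc, config) {
  stopifnot(inherits(sc, "structural_connectome"),
            inherits(config, "kuramoto_config"))
  conn <- sc$weights > 0
  if (!any(conn)) stop("connectome has no edges")
  lbar <- mean(sc$lengths[conn])
  if (lbar <= 0) stop("mean fiber length is zero")
  v <- if (!is.null(config$conduction_velocity_m_s))
    config$conduction_velocity_m_s
  else (lbar / 1000) / (config$mean_delay_ms / 1000)   # mm -> m, ms -> s
  delays_ms <- matrix(0, nrow(sc$weights), ncol(sc$weights))
  delays_ms[conn] <- sc$lengths[conn] / v               # mm / (m/s) = ms
  steps <- matrix(0L, nrow(delays_ms), ncol(delays_ms))
  steps[conn] <- pmax(1L, as.integer(round(delays_ms[conn] / config$dt_ms)))
  list(delays_ms = delays_ms, delay_steps = steps, velocity_m_s = v,
       mean_length_mm = lbar)
}

#' Integrate the delay-coupled Kuramoto model
#'
#' Deterministic Heun integration (stochastic Heun when `noise_sd_rad_s > 0`)
#' of the delayed phase equations. Initial phases are uniform on `[0, 2*pi)`;
#' the delay history is filled by running the uncoupled system (`k = 0`) for
#' the maximal-delay duration; the first `transient_discard_s` seconds of
#' coupled dynamics are discarded. Identical seeds give bitwise-identical
#' trajectories.
#'
#' @param sc a normalized [structural_connectome()].
#' @param config a [kuramoto_config()].
#' @return A `phase_trajectory`: `phases` (N x T, wrapped to `[0, 2*pi)`),
#'   `sample_rate_hz`, `start_time_s`, `delays` (from [build_delays()]).
#' @export
simulate_kuramoto <- function(sc, config) {
  stopifnot(inherits(sc, "structural_connectome"),
            inherits(config, "kuramoto_config"))
  del <- build_delays(sc, config)
  dt <- config$dt_ms / 1000
  n_steps <- round(config$duration_s / dt)
  n_transient <- round(config$transient_discard_s / dt)
  set.seed(config$seed)
  n <- nrow(sc$weights)
  init <- stats::runif(n, 0, 2 * pi)
  phases <- cpp_kuramoto(sc$weights, del$delay_steps,
                         2 * pi * config$natural_frequency_hz,
                         config$coupling, dt, n_steps, n_transient,
                         config$noise_sd_rad_s, init, config$record_every)
  structure(list(phases = phases,
                 sample_rate_hz = 1 / (dt * config$record_every),
                 start_time_s = config$transient_discard_s,
                 delays = del, config = config),
            class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("Phase trajectory: %d nodes x %d samples at %g Hz (t0 = %g s)\n",
              nrow(x$phases), ncol(x$phases), x$sample_rate_hz,
              x$start_time_s))
  invisible(x)
}

#' Kuramoto order parameter, synchrony, and metastability
#'
#' `R(t) = |mean_n exp(i*theta_n(t))|` measures instantaneous phase
#' uniformity (0 incoherent, 1 fully synchronized). The temporal mean of
#' `R(t)` is the global synchrony; its temporal SD the global metastability.
#'
#' @param traj a `phase_trajectory` from [simulate_kuramoto()], or an
#'   N x T phase matrix.
#' @return An `order_parameter` list: `magnitude`, `ensemble_phase`,
#'   `synchrony`, `metastability`.
#' @export
order_parameter <- function(traj) {
  ph <- if (inherits(traj, "phase_trajectory")) traj$phases else as.matrix(traj)
  if (nrow(ph) < 1) stop("need at least one oscillator")
  z <- colMeans(exp(1i * ph))
  mag <- Mod(z)
  structure(list(magnitude = mag, ensemble_phase = Arg(z),
                 synchrony = mean(mag), metastability = stats::sd(mag)),
            class = "order_parameter")
}

#' @export
print.order_parameter <- function(x, ...) {
  cat(sprintf("Order parameter: synchrony %.3f, metastability %.3f (%d samples)\n",
              x$synchrony, x$metastability, length(x$magnitude)))
  invisible(x)
}
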