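#' One step of an Ornstein-Uhlenbeck process
#'
#' Sources and noise inputs follow `ds/dt = -s/tau + sigma * eps(t)` with
#' unit-variance Gaussian white noise `eps`.  The update is exact in
#' distribution: `s' = s * exp(-dt/tau) + sd_inc * N(0,1)` with
#' `sd_inc = sigma * sqrt(tau/2 * (1 - exp(-2 dt / tau)))`, so the
#' stationary variance is `sigma^2 * tau / 2` for any `dt`.
#'
#' @param s Current value(s); vectors advance independent processes.
#' @param dt Time step (ms).
#' @param tau Correlation time (ms).
#' @param sigma Noise amplitude.
#' @return Updated value(s).
#' @export
ou_step <- function(s, dt, tau = 10, sigma = 0.1) {
  if (dt <= 0) stop("ou_step: dt must be positive")
  if (tau <= 0) stop("ou_step: tau must be positive")
  decay <- exp(-dt / tau)
  s * decay + sigma * sqrt(tau / 2 * (1 - decay^2)) *
    stats::rnorm(length(s))
}

# per-step sd of the exact OU increment; shared with the compiled core
ou_increment_sd <- function(dt, tau, sigma) {
  sigma * sqrt(tau / 2 * (1 - exp(-2 * dt / tau)))
}

#' Animal position on the 1D track
#'
#' Piecewise-linear back-and-forth trajectory used by the track protocols:
#' the animal rests at position 0 until 10 s, then performs three runs
#' (10-25 s, 25-40 s, 40-50 s) with pauses at the endpoints.  The first
#' ramp is `(t - 10)/5`, making the trajectory continuous and reaching 1 at
#' 15 s.  Times are in ms; positions are normalized to \[0, 1\].
#'
#' @param t Time(s) in ms (vectorized).
#' @return Position(s) in \[0, 1\].
#' @export
position_1d <- function(t) {
  ts <- t / 1000
  pos <- numeric(length(ts))
  seg <- function(lo, hi) ts >= lo & ts < hi
  pos[seg(10, 15)]     <- (ts[seg(10, 15)] - 10) / 5
  pos[seg(15, 17.5)]   <- 1
  pos[seg(17.5, 22.5)] <- 1 - (ts[seg(17.5, 22.5)] - 17.5) / 5
  # [22.5, 25) and rest segments stay 0
  pos[seg(25, 35)]     <- (ts[seg(25, 35)] - 25) / 10
  pos[seg(35, 37.5)]   <- 1 - (ts[seg(35, 37.5)] - 35) / 2.5
  pos[seg(40, 44)]     <- 0.8 * (ts[seg(40, 44)] - 40) / 4
  pos[seg(44, 47)]     <- 0.8 - 0.4 * (ts[seg(44, 47)] - 44) / 3
  pos[ts >= 47]        <- 0.4 + 0.6 * (pmin(ts[ts >= 47], 50) - 47) / 3
  pos
}

#' Position within one Y-maze arm visit
#'
#' Each 10-s arm visit starts and ends at the junction: the animal waits
#' 2.5 s, moves out to the arm end (position 0.5), waits 2.5 s, and returns.
#'
#' @param t_cycle Time within the 10-s cycle, in ms (vectorized).
#' @return Position(s) in \[0, 0.5\].
#' @export
position_ymaze_cycle <- function(t_cycle) {
  ts <- t_cycle / 1000
  pos <- numeric(length(ts))
  ramp_out <- ts >= 2.5 & ts < 5
  hold     <- ts >= 5 & ts < 7.5
  ramp_in  <- ts >= 7.5 & ts < 10
  pos[ramp_out] <- 0.5 * (ts[ramp_out] - 2.5) / 2.5
  pos[hold]     <- 0.5
  pos[ramp_in]  <- 0.5 - 0.5 * (ts[ramp_in] - 7.5) / 2.5
  pos
}

#' Entorhinal input specification
#'
#' Describes the tuning of every EC input neuron: `"place"` neurons carry a
#' Gaussian receptive field along the track, `"grid"` neurons a periodic
#' von-Mises-like field with random phase and period, and `"distractor"`
#' neurons a position-independent slow source.  All modes share the theta
#' modulation and input noise during run and receive noise only during
#' immobility.
#'
#' @param mode Character vector (one entry per EC neuron) with values
#'   `"place"`, `"grid"`, or `"distractor"`.
#' @param center Receptive-field centers (place neurons).
#' @param center_arm Arm assignment per neuron (Y-maze; 0 = any arm).
#' @param A_F,sigma_F Amplitude and width of the place tuning.
#' @param A_grid,c_grid Amplitude and concentration of the grid tuning.
#' @param grid_phase,grid_period Per-neuron grid phase (\[0, 2pi\]) and
#'   spatial period (\[0.2, 0.6\]).
#' @param sigma_n Input-noise amplitude of the per-neuron OU noise.
#' @param tau_dist,sigma_dist Correlation time and amplitude of the
#'   distractor sources.
#' @return An object of class `"ec_spec"`.
#' @export
ec_spec <- function(mode, center = NULL, center_arm = NULL,
                    A_F = 5, sigma_F = 0.1, A_grid = 5, c_grid = 3,
                    grid_phase = NULL, grid_period = NULL,
                    sigma_n = 1, tau_dist = 500, sigma_dist = 0.02) {
  n <- length(mode)
  stopifnot(all(mode %in% c("place", "grid", "distractor")))
  if (is.null(center)) center <- numeric(n)
  if (is.null(center_arm)) center_arm <- integer(n)
  if (is.null(grid_phase)) grid_phase <- numeric(n)
  if (is.null(grid_period)) grid_period <- rep(1, n)
  stopifnot(length(center) == n, length(center_arm) == n,
            length(grid_phase) == n, length(grid_period) == n)
  structure(list(mode = mode, center = center, center_arm = center_arm,
                 A_F = A_F, sigma_F = sigma_F, A_grid = A_grid,
                 c_grid = c_grid, grid_phase = grid_phase,
                 grid_period = grid_period, sigma_n = sigma_n,
                 tau_dist = tau_dist, sigma_dist = sigma_dist),
            class = "ec_spec")
}

#' EC spec for the 1D track (place + distractor neurons)
#'
#' Place neurons have evenly spaced centers `i / n_place`; the remaining
#' neurons are distractors.
#'
#' @param n_place,n_dist Numbers of place-tuned and distractor neurons.
#' @param ... Passed on to [ec_spec()].
#' @export
ec_spec_track <- function(n_place = 300, n_dist = 200, ...) {
  ec_spec(mode = c(rep("place", n_place), rep("distractor", n_dist)),
          center = c(seq_len(n_place) / n_place, numeric(n_dist)), ...)
}

#' EC spec with grid-cell inputs
#'
#' Grid phases are drawn uniformly from \[0, 2pi\] and spatial periods
#' uniformly from \[0.2, 0.6\], independently per neuron.
#'
#' @param n_grid,n_dist Numbers of grid and distractor neurons.
#' @param ... Passed on to [ec_spec()].
#' @export
ec_spec_grid <- function(n_grid = 200, n_dist = 100, ...) {
  n <- n_grid + n_dist
  ec_spec(mode = c(rep("grid", n_grid), rep("distractor", n_dist)),
          grid_phase = c(stats::runif(n_grid, 0, 2 * pi), numeric(n_dist)),
          grid_period = c(stats::runif(n_grid, 0.2, 0.6), rep(1, n_dist)),
          ...)
}

#' EC spec for the Y-maze
#'
#' Each arm is covered by `n_per_arm` place neurons with centers sampled
#' uniformly from \[0, 0.5\]; a neuron is silent whenever the animal is on a
#' different arm.
#'
#' @param n_per_arm Place neurons per arm.
#' @param ... Passed on to [ec_spec()].
#' @export
ec_spec_ymaze <- function(n_per_arm = 150, ...) {
  n <- 3 * n_per_arm
  ec_spec(mode = rep("place", n),
          center = stats::runif(n, 0, 0.5),
          center_arm = rep(1:3, each = n_per_arm), ...)
}

#' Deterministic tuned input component of EC neurons
#'
#' The position-dependent part of the EC input current during run (without
#' theta, baseline, noise, or distractor sources).  Used by the reference
#' implementation and for testing the compiled core.
#'
#' @param spec An [ec_spec()] object.
#' @param pos Current position.
#' @param arm Current arm (Y-maze; 0 otherwise).
#' @return Vector of tuned drives (distractor entries are `NA`; their
#'   "tuning" is a stochastic source handled by the simulator).
#' @export
ec_tuned_input <- function(spec, pos, arm = 0L) {
  out <- rep(NA_real_, length(spec$mode))
  pl <- spec$mode == "place"
  out[pl] <- spec$A_F *
    exp(-0.5 * ((pos - spec$center[pl]) / spec$sigma_F)^2)
  if (arm > 0) {
    off <- pl & spec$center_arm != arm & spec$center_arm != 0L
    out[off] <- 0
  }
  gr <- spec$mode == "grid"
  if (any(gr)) {
    out[gr] <- spec$A_grid *
      exp(spec$c_grid * cos(2 * pi * pos / spec$grid_period[gr] -
                              spec$grid_phase[gr]))
  }
  out
}

#' Full EC input current (reference implementation)
#'
#' Assembles the per-neuron input current: during run the tuned term (or a
#' supplied distractor source) plus `0.5 * I_theta - 0.5` plus noise; during
#' immobility noise only (optionally plus a burst drive).
#'
#' @param spec An [ec_spec()] object.
#' @param pos,arm Behavioral state.
#' @param moving Logical.
#' @param theta_value Current theta drive `I_theta` (0 during immobility).
#' @param noise Per-neuron OU noise values.
#' @param s_dist Per-distractor-neuron source values.
#' @param burst Per-neuron burst drive (`s_burst * n_burst`), default 0.
#' @return Vector of input currents.
#' @export
ec_input_current <- function(spec, pos, arm, moving, theta_value,
                             noise = 0, s_dist = 0, burst = 0) {
  n <- length(spec$mode)
  if (!moving) return(rep(noise + burst, length.out = n))
  tuned <- ec_tuned_input(spec, pos, arm)
  di <- spec$mode == "distractor"
  tuned[di] <- s_dist
  tuned + 0.5 * theta_value - 0.5 + noise
}

#' Theta oscillation drive
#'
#' `I_theta(t) = A_theta * sin(2 pi f_theta t)` during run, 0 during
#' immobility.
#'
#' @param t Time(s) in ms.
#' @param moving Logical vector (recycled).
#' @param A_theta Amplitude.
#' @param f_theta Frequency in kHz (default 7 Hz).
#' @return Theta drive value(s).
#' @export
theta_drive <- function(t, moving = TRUE, A_theta = 10, f_theta = 7 / 1000) {
  A_theta * sin(2 * pi * f_theta * t) * as.numeric(moving)
}

#' Sample a trigger activation time course
#'
#' During immobility, triggers fire as a Poisson process (default 1 Hz),
#' each activation lasting `dur_immobile` ms.  An additional activation of
#' `dur_onset` ms is delivered at each listed onset time (the start of the
#' first run).  Returns the per-step trigger value (amplitude or 0).
#'
#' @param n_steps Number of integration steps.
#' @param dt Step (ms).
#' @param moving Logical vector of length `n_steps`.
#' @param rate_hz Poisson rate of immobile triggers (Hz).
#' @param dur_immobile Duration of each immobile activation (ms).
#' @param onsets_ms Times (ms) of forced activations.
#' @param dur_onset Duration of forced activations (ms).
#' @param amplitude Trigger amplitude.
#' @return Numeric vector of length `n_steps`.
#' @export
trigger_schedule <- function(n_steps, dt, moving, rate_hz = 1,
                             dur_immobile = 10, onsets_ms = numeric(0),
                             dur_onset = 100, amplitude = 10) {
  trig <- numeric(n_steps)
  p_on <- rate_hz / 1000 * dt
  starts <- which(!moving & stats::runif(n_steps) < p_on)
  len_i <- max(1L, round(dur_immobile / dt))
  for (s in starts) trig[s:min(n_steps, s + len_i - 1L)] <- amplitude
  len_o <- max(1L, round(dur_onset / dt))
  for (t0 in onsets_ms) {
    s <- floor(t0 / dt) + 1L
    if (s <= n_steps) trig[s:min(n_steps, s + len_o - 1L)] <- amplitude
  }
  trig
}

#' Sample a population-burst gate
#'
#' Burst onsets follow a Poisson process (default 1 Hz); each burst keeps
#' the gate open for exactly `dur_ms` ms.  The gate multiplies the
#' per-neuron OU burst drives in the EC input.
#'
#' @param n_steps Number of steps.
#' @param dt Step (ms).
#' @param active Logical vector: steps where bursts may start (the
#'   spontaneous-activity epochs).
#' @param rate_hz Poisson onset rate (Hz).
#' @param dur_ms Burst duration (ms).
#' @return Integer 0/1 vector of length `n_steps`.
#' @export
burst_schedule <- function(n_steps, dt, active = rep(TRUE, n_steps),
                           rate_hz = 1, dur_ms = 200) {
  gate <- integer(n_steps)
  starts <- which(active & stats::runif(n_steps) < rate_hz / 1000 * dt)
  len <- max(1L, round(dur_ms / dt))
  for (s in starts) gate[s:min(n_steps, s + len - 1L)] <- 1L
  gate
}
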