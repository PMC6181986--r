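#' Initialize the state of a recurrent network
#'
#' Compartment activations start at the zero-input fixed point `f(0)`,
#' synaptic traces at zero, short-term plasticity at its resting state
#' (`D = 1`, `F = U_STF`), and the running-mean activities (hence the
#' sliding thresholds) at zero.
#'
#' @param w_som Recurrent somatic weight matrix (n x n, zero diagonal).
#' @param w_dnd EC-to-dendrite weight matrix (n x n_ec).
#' @param v_dnd Dendritic inhibitory weights (n x n_inh).
#' @param v_som Fixed somatic inhibitory weight (scalar).
#' @param pool An [inhibitory_pool()] object.
#' @param p,pp,stp Parameter objects.
#' @return A list of class `"network_state"`.
#' @export
init_network_state <- function(w_som, w_dnd, v_dnd, v_som, pool,
                               p = neuron_params(),
                               pp = plasticity_params(),
                               stp = stp_params()) {
  n <- nrow(w_som)
  n_ec <- ncol(w_dnd)
  stopifnot(ncol(w_som) == n, nrow(w_dnd) == n,
            nrow(v_dnd) == n, ncol(v_dnd) == pool$n_inh,
            ncol(pool$theta_som) == n)
  f0 <- sigmoid_response(0, p$theta_f)
  structure(list(
    n = n, n_ec = n_ec,
    x = rep(f0, n), y = rep(f0, n),
    z = (1 + p$gamma * f0) * p$phi * rep(f0, n),
    I_som = numeric(n), I_dnd = numeric(n_ec),
    D_som = rep(1, n), F_som = rep(stp$U_STF, n),
    D_dnd = rep(1, n_ec), F_dnd = rep(stp$U_STF, n_ec),
    pool = pool,
    w_som = w_som, w_dnd = w_dnd, v_dnd = v_dnd, v_som = v_som,
    dw_som = matrix(0, n, n), dw_dnd = matrix(0, n, n_ec),
    dv_dnd = matrix(0, n, pool$n_inh),
    E_som = numeric(n), E_dnd = numeric(n),
    theta_som = numeric(n), theta_dnd = numeric(n)),
    class = "network_state")
}

#' Size-invariant fixed somatic inhibitory weight
#'
#' The pooled feedback inhibition received by each pyramidal cell is
#' `v_som / n_inh` times the summed pyramidal output traces, so its total
#' strength scales with both the CA3 count and the readout count.  This
#' helper rescales the reference weight (20 at 300 CA3 cells and 100
#' readouts) so that desk-scale networks keep the reference excitation-
#' inhibition balance.
#'
#' @param n_ca3 CA3 neuron count of the simulated network.
#' @param n_inh Inhibitory readout count.
#' @param v_ref,n_ref,n_inh_ref Reference weight and network size.
#' @return The scaled somatic inhibitory weight.
#' @export
scale_v_som <- function(n_ca3, n_inh = 100, v_ref = 20, n_ref = 300,
                        n_inh_ref = 100) {
  v_ref * (n_ref / n_ca3) * (n_inh / n_inh_ref)
}

#' Default stepping flags for the recurrent network
#'
#' @param plasticity_on Update long-term excitatory weights.
#' @param inh_plasticity_on Update dendritic inhibitory weights.
#' @param single_compartment Run the single-compartment control model (all
#'   inputs converge on the soma, output `z = phi * x`, BCM plasticity with
#'   somatic activity for both weight families).
#' @param stp_pyr_pool Apply short-term plasticity to the pyramidal-to-
#'   interneuron traces (off by default; the pool then uses plain
#'   first-order filtering).
#' @return A list of flags.
#' @export
network_flags <- function(plasticity_on = TRUE, inh_plasticity_on = TRUE,
                          single_compartment = FALSE,
                          stp_pyr_pool = FALSE) {
  list(plasticity_on = plasticity_on,
       inh_plasticity_on = inh_plasticity_on,
       single_compartment = single_compartment,
       stp_pyr_pool = stp_pyr_pool)
}

#' One Euler step of the recurrent network (reference implementation)
#'
#' Advances the full network state by `dt`.  Update order within a step:
#' (1) the inhibitory pool integrates the previous step's output rates;
#' (2) short-term plasticity and synaptic traces advance (recurrent traces
#' driven by the previous step's rates, dendritic traces by the supplied EC
#' rates); (3) compartment activations are computed with the partner
#' compartment's previous-step activity (the one-step delay); (4) output
#' rates; (5) plasticity.  Every term therefore uses information from time
#' `t - dt`.
#'
#' This pure-R stepper is the readable reference; [run_network()] executes
#' the same dynamics in compiled code.
#'
#' @param state A `"network_state"` object.
#' @param ec_rates EC firing rates at this step (kHz, length n_ec).
#' @param ext External somatic input per neuron (length n).
#' @param dt Step (ms).
#' @param p,pp Parameter objects.
#' @param stp_rec,stp_ec Short-term plasticity parameters of the recurrent
#'   and EC pathways (the baseline release probability differs between
#'   immobility and run).
#' @param flags A [network_flags()] list.
#' @return The updated state.
#' @export
step_network <- function(state, ec_rates, ext, dt,
                         p = neuron_params(), pp = plasticity_params(),
                         stp_rec = stp_params(), stp_ec = stp_params(),
                         flags = network_flags()) {
  if (any(!is.finite(state$x)) || any(!is.finite(state$z)))
    stop("step_network: non-finite state")
  if (length(ec_rates) != state$n_ec || length(ext) != state$n)
    stop("step_network: input length mismatch")
  z_prev <- state$z

  # (1) inhibitory pool from previous-step rates; with stp_pyr_pool the
  # interneurons instead read the recurrent traces themselves (shared
  # presynaptic resource including D*F), computed after the trace update
  if (!flags$stp_pyr_pool) {
    fb <- inhibitory_feedback(state$pool, z_prev, dt, p$tau_L)
    state$pool <- fb$pool
  }

  # (2) short-term plasticity and synaptic traces
  fac_som <- state$D_som * state$F_som
  state$I_som <- step_synaptic_trace(state$I_som, z_prev, dt, p$tau_L,
                                     fac_som)
  sr <- step_stp(state$D_som, state$F_som, z_prev, dt, stp_rec)
  state$D_som <- sr$D; state$F_som <- sr$F
  fac_dnd <- state$D_dnd * state$F_dnd
  state$I_dnd <- step_synaptic_trace(state$I_dnd, ec_rates, dt, p$tau_L,
                                     fac_dnd)
  se <- step_stp(state$D_dnd, state$F_dnd, ec_rates, dt, stp_ec)
  state$D_dnd <- se$D; state$F_dnd <- se$F
  if (flags$stp_pyr_pool) {
    state$pool$I_pyr <- state$I_som
    fb <- list(I_sominh = drop(state$pool$theta_som %*% state$I_som),
               I_dndinh = drop(state$pool$theta_dnd %*% state$I_som))
  }

  # (3,4) activations and output rates
  exc_som <- drop(state$w_som %*% state$I_som)
  exc_dnd <- drop(state$w_dnd %*% state$I_dnd)
  inh_som <- state$v_som * sum(fb$I_sominh)
  if (flags$single_compartment) {
    x <- sigmoid_response(exc_som + exc_dnd - inh_som + ext, p$theta_f)
    y <- x
    z <- p$phi * x
  } else {
    inh_dnd <- drop(state$v_dnd %*% fb$I_dndinh)
    act <- compartment_activations(exc_som, exc_dnd, inh_som, inh_dnd, ext,
                                   state$x, state$y, p)
    x <- act$x; y <- act$y
    z <- output_rate(x, y, p)
  }

  # (5) plasticity
  if (flags$plasticity_on) {
    th <- update_moving_thresholds(state$E_som, state$E_dnd, x, y, dt, pp)
    state$E_som <- th$E_som; state$E_dnd <- th$E_dnd
    state$theta_som <- th$theta_som; state$theta_dnd <- th$theta_dnd
    if (flags$single_compartment) {
      g <- pp$eta * x * (x - state$theta_som) * (1 - x)
      tg <- list(som = outer(g, state$I_som), dnd = outer(g, state$I_dnd))
    } else {
      tg <- two_compartment_update_terms(x, y, state$theta_som,
                                         state$theta_dnd,
                                         state$I_som, state$I_dnd, pp)
    }
    up <- step_weight_dynamics(state$w_som, state$dw_som, tg$som, dt, pp,
                               noise = TRUE, zero_diag = TRUE)
    state$w_som <- up$w; state$dw_som <- up$dw
    up <- step_weight_dynamics(state$w_dnd, state$dw_dnd, tg$dnd, dt, pp,
                               noise = TRUE)
    state$w_dnd <- up$w; state$dw_dnd <- up$dw
    if (!flags$single_compartment && flags$inh_plasticity_on) {
      tv <- inhibitory_update_term(x, y, fb$I_dndinh, pp)
      up <- step_weight_dynamics(state$v_dnd, state$dv_dnd, tv, dt, pp,
                                 noise = FALSE)
      state$v_dnd <- up$w; state$dv_dnd <- up$dw
    }
  }

  state$x <- x; state$y <- y; state$z <- z
  state
}

#' Run a recurrent-network simulation (compiled core)
#'
#' Executes the same dynamics as [step_network()] for a full behavioral
#' schedule in compiled code, generating the EC input currents, external
#' noise, trigger and theta drives, and weight fluctuations internally from
#' a dedicated random stream.
#'
#' @param state A `"network_state"` object (from [init_network_state()] or
#'   the `state` element of a previous run, enabling resumed simulations).
#' @param schedule A list describing each step: `moving` (0/1), `pos`,
#'   `arm` (integer), `theta` (theta drive value), `trig` (trigger
#'   amplitude), `burst` (0/1 burst gate), `plast_on` (0/1).  All vectors of
#'   length `n_steps`.
#' @param trig_pattern Per-neuron multiplier of the trigger drive (+1 for
#'   target neurons; -1 or 0 elsewhere).
#' @param ec An [ec_spec()] object.
#' @param p,pp Parameter objects.
#' @param U_immobile,U_run_rec Baseline release probabilities of recurrent
#'   synapses during immobility and run; EC synapses always use
#'   `U_immobile`.
#' @param tau_STD,tau_STF Short-term plasticity time constants (ms).
#' @param sigma_n_ext Amplitude of the external somatic OU noise.
#' @param tau_burst,sigma_burst OU parameters of the per-neuron burst
#'   drives gated by `schedule$burst`.
#' @param flags A [network_flags()] list.
#' @param dt Step (ms).
#' @param record_every Record traces every this many steps.
#' @param record_weights_at Step indices at which to snapshot `w_dnd` group
#'   sums (0 = none); final weights are always returned.
#' @param record_xy Also record compartment activations and dendritic
#'   inhibition (memory permitting).
#' @param seed Integer seed of the simulation's random stream.
#' @return A list of class `"network_record"` with the recorded time axis
#'   (ms), rate matrix `z` (n x n_rec), optional `x`, `y`, `inh_dnd`
#'   matrices, the behavior at recorded times, final weights, and the full
#'   final `state` for resuming.
#' @export
run_network <- function(state, schedule, trig_pattern, ec,
                        p = neuron_params(), pp = plasticity_params(),
                        U_immobile = 0.5, U_run_rec = 0.03,
                        tau_STD = 500, tau_STF = 200,
                        sigma_n_ext = 0.1, tau_burst = 100,
                        sigma_burst = 0.1,
                        flags = network_flags(), dt = 1,
                        record_every = 5L, record_weights_at = integer(0),
                        record_xy = FALSE, seed = 1L) {
  n_steps <- length(schedule$moving)
  stopifnot(length(schedule$pos) == n_steps,
            length(schedule$theta) == n_steps,
            length(schedule$trig) == n_steps,
            length(trig_pattern) == state$n)
  if (is.null(schedule$arm)) schedule$arm <- integer(n_steps)
  if (is.null(schedule$burst)) schedule$burst <- integer(n_steps)
  if (is.null(schedule$plast_on))
    schedule$plast_on <- rep(1L, n_steps)
  mode_code <- match(ec$mode, c("place", "grid", "distractor")) - 1L

  out <- simulate_network_cpp(
    list(w_som = state$w_som, w_dnd = state$w_dnd, v_dnd = state$v_dnd,
         v_som = state$v_som,
         theta_som_pool = state$pool$theta_som,
         theta_dnd_pool = state$pool$theta_dnd),
    list(x = state$x, y = state$y, z = state$z,
         I_som = state$I_som, I_dnd = state$I_dnd,
         I_pyr = state$pool$I_pyr,
         D_som = state$D_som, F_som = state$F_som,
         D_dnd = state$D_dnd, F_dnd = state$F_dnd,
         dw_som = state$dw_som, dw_dnd = state$dw_dnd,
         dv_dnd = state$dv_dnd,
         E_som = state$E_som, E_dnd = state$E_dnd),
    list(moving = as.integer(schedule$moving), pos = schedule$pos,
         arm = as.integer(schedule$arm), theta = schedule$theta,
         trig = schedule$trig, burst = as.integer(schedule$burst),
         plast_on = as.integer(schedule$plast_on),
         trig_pattern = trig_pattern),
    list(mode = mode_code, center = ec$center,
         center_arm = as.integer(ec$center_arm),
         A_F = ec$A_F, sigma_F = ec$sigma_F,
         A_grid = ec$A_grid, c_grid = ec$c_grid,
         grid_phase = ec$grid_phase, grid_period = ec$grid_period,
         sigma_n = ec$sigma_n, tau_dist = ec$tau_dist,
         sigma_dist = ec$sigma_dist,
         tau_burst = tau_burst, sigma_burst = sigma_burst),
    list(phi = p$phi, phi_input = p$phi_input, theta_f = p$theta_f,
         beta = p$beta, gamma = p$gamma, tau_L = p$tau_L,
         alpha = pp$alpha, eta = pp$eta, eta_inh = pp$eta_inh,
         c0 = pp$c0, theta_inh = pp$theta_inh, tau_w = pp$tau_w,
         eta_decay = pp$eta_decay, sigma_w = pp$sigma_w,
         tau_mean = pp$tau_mean,
         tau_STD = tau_STD, tau_STF = tau_STF,
         U_immobile = U_immobile, U_run_rec = U_run_rec,
         sigma_n_ext = sigma_n_ext, dt = dt),
    list(single_compartment = as.integer(flags$single_compartment),
         inh_plasticity_on = as.integer(flags$inh_plasticity_on),
         stp_pyr_pool = as.integer(flags$stp_pyr_pool),
         plasticity_master = as.integer(flags$plasticity_on),
         record_every = as.integer(record_every),
         record_weights_at = as.integer(record_weights_at),
         record_xy = as.integer(record_xy),
         seed = as.numeric(seed)))

  rec_idx <- out$rec_steps
  new_state <- state
  for (nm in c("x", "y", "z", "I_som", "I_dnd", "D_som", "F_som",
               "D_dnd", "F_dnd", "E_som", "E_dnd", "theta_som",
               "theta_dnd"))
    new_state[[nm]] <- drop(out$state[[nm]])
  for (nm in c("w_som", "w_dnd", "v_dnd", "dw_som", "dw_dnd", "dv_dnd"))
    new_state[[nm]] <- out$state[[nm]]
  new_state$pool$I_pyr <- drop(out$state$I_pyr)

  structure(list(
    time = rec_idx * dt,
    z = out$z, x = out$x, y = out$y, inh_dnd = out$inh_dnd,
    pos = schedule$pos[rec_idx], moving = schedule$moving[rec_idx],
    arm = schedule$arm[rec_idx],
    w_som = out$state$w_som, w_dnd = out$state$w_dnd,
    v_dnd = out$state$v_dnd,
    w_snapshots = out$w_snapshots,
    state = new_state, dt = dt, record_every = record_every,
    seed = seed),
    class = "network_record")
}
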