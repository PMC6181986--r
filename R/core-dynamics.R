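#' Sigmoidal response function
#'
#' The static nonlinearity shared by every compartment and input neuron,
#' `f(I) = 1 / (1 + exp(-(I - theta_f)))`.
#'
#' @param I Input drive (any numeric array); must be finite.
#' @param theta_f Threshold.
#' @return Activation in (0, 1), same shape as `I`.
#' @examples
#' sigmoid_response(5, theta_f = 5)  # 0.5 at threshold
#' @export
sigmoid_response <- function(I, theta_f = 5) {
  if (!all(is.finite(I))) stop("sigmoid_response: non-finite input drive")
  1 / (1 + exp(-(I - theta_f)))
}

#' Advance a synaptic trace by one Euler step
#'
#' Unweighted postsynaptic currents decay with time constant `tau_L` and
#' integrate the presynaptic rate, optionally scaled by the short-term
#' plasticity factor `D * F`:
#' `dI/dt = -I / tau_L + u * stp_factor`.
#'
#' @param I Current trace value(s).
#' @param u Presynaptic rate(s) (kHz), nonnegative.
#' @param dt Time step (ms), positive.
#' @param tau_L Decay constant (ms).
#' @param stp_factor Multiplicative release factor (`D * F`), default 1.
#' @return Updated trace, same shape as `I`.
#' @export
step_synaptic_trace <- function(I, u, dt, tau_L = 10, stp_factor = 1) {
  if (dt <= 0) stop("step_synaptic_trace: dt must be positive")
  if (any(u < 0)) stop("step_synaptic_trace: negative presynaptic rate")
  I + dt * (-I / tau_L + u * stp_factor)
}

#' Advance short-term depression and facilitation variables
#'
#' `D` recovers towards 1 with `tau_STD` and is consumed at rate `u * D * F`;
#' `F` relaxes towards the baseline release probability `U_STF` with
#' `tau_STF` and facilitates towards 1 in proportion to `U_STF * u`:
#' \deqn{dD/dt = (1 - D)/\tau_{STD} - u D F}
#' \deqn{dF/dt = (U_{STF} - F)/\tau_{STF} + U_{STF} (1 - F) u}
#'
#' @param D Depression variable(s) in \[0, 1\].
#' @param F Facilitation variable(s) in \[U_STF, 1\].
#' @param u Presynaptic rate(s) (kHz), nonnegative.
#' @param dt Time step (ms), positive.
#' @param p An object from [stp_params()].
#' @return A list with updated `D` and `F`.
#' @export
step_stp <- function(D, F, u, dt, p = stp_params()) {
  if (dt <= 0) stop("step_stp: dt must be positive")
  if (any(u < 0)) stop("step_stp: negative presynaptic rate")
  D_new <- D + dt * ((1 - D) / p$tau_STD - u * D * F)
  F_new <- F + dt * ((p$U_STF - F) / p$tau_STF + p$U_STF * (1 - F) * u)
  list(D = D_new, F = F_new)
}

#' Stationary point of the short-term plasticity variables
#'
#' Closed-form fixed point of the depression/facilitation flow under a
#' constant presynaptic rate `u`.  Useful for checking long simulations.
#'
#' @inheritParams step_stp
#' @return A list with `D` and `F` at stationarity.
#' @export
stp_fixed_point <- function(u, p = stp_params()) {
  F_star <- (p$U_STF / p$tau_STF + p$U_STF * u) / (1 / p$tau_STF + p$U_STF * u)
  D_star <- (1 / p$tau_STD) / (1 / p$tau_STD + u * F_star)
  list(D = D_star, F = F_star)
}

#' Compartment activations of the two-compartment neuron
#'
#' Somatic and dendritic activations are computed independently through the
#' shared sigmoid; each compartment's drive includes its weighted excitation,
#' minus inhibition, plus the threshold-modulation term `beta` times the
#' partner compartment's activation one delay step earlier, plus (soma only)
#' any external input:
#' \deqn{x = f(exc_{som} - inh_{som} + \beta y_{prev} + ext)}
#' \deqn{y = f(exc_{dnd} - inh_{dnd} + \beta x_{prev})}
#'
#' @param exc_som,exc_dnd Weighted excitatory drives per neuron.
#' @param inh_som,inh_dnd Weighted inhibitory drives per neuron.
#' @param ext External somatic input per neuron.
#' @param x_prev,y_prev Activations one delay step earlier.
#' @param p A [neuron_params()] object.
#' @return A list with activations `x` and `y`, each in (0, 1).
#' @export
compartment_activations <- function(exc_som, exc_dnd, inh_som = 0,
                                    inh_dnd = 0, ext = 0, x_prev, y_prev,
                                    p = neuron_params()) {
  n <- length(exc_som)
  if (length(exc_dnd) != n || length(x_prev) != n || length(y_prev) != n)
    stop("compartment_activations: drive/state length mismatch")
  x <- sigmoid_response(exc_som - inh_som + p$beta * y_prev + ext, p$theta_f)
  y <- sigmoid_response(exc_dnd - inh_dnd + p$beta * x_prev, p$theta_f)
  list(x = x, y = y)
}

#' Output firing rate of the two-compartment neuron
#'
#' Coincident activation of the two compartments (the calcium-spike
#' mechanism) multiplicatively amplifies somatic output:
#' `z = (1 + gamma * y) * phi * x`, bounded by `(1 + gamma) * phi`.
#'
#' @param x,y Compartment activations in \[0, 1\].
#' @param p A [neuron_params()] object.
#' @return Output rate(s) in kHz.
#' @export
output_rate <- function(x, y, p = neuron_params()) {
  (1 + p$gamma * y) * p$phi * x
}

#' Construct the fixed inhibitory feedback pool
#'
#' Inhibitory readouts pool the filtered outputs of all pyramidal cells
#' through fixed random projection weights.  Weights are sampled uniformly
#' from \[0, 1\] and normalized so that every column (presynaptic pyramidal
#' cell) sums to `1 / n_inh`, separately for the somatic-targeting and
#' dendritic-targeting populations.  The weights stay fixed for the whole
#' simulation.
#'
#' @param n_pyr Number of pyramidal neurons.
#' @param n_inh Number of inhibitory readouts per population.
#' @param dnd_gain Overall gain of the dendritic-targeting readouts: the
#'   columns of `theta_dnd` sum to `dnd_gain / n_inh` instead of
#'   `1 / n_inh`.  The absolute scale of the pooled readouts is not fixed
#'   by the circuit description (only the column-normalized shape is), and
#'   it sets the speed at which plastic dendritic inhibition can silence a
#'   dominating ensemble; the recurrent-network presets use a gain
#'   calibrated so that ensemble turnover happens within single traversals.
#' @return A list of class `"inhibitory_pool"` with matrices `theta_som` and
#'   `theta_dnd` (`n_inh` x `n_pyr`) and the pyramidal-output trace `I_pyr`
#'   (initialized to zero).
#' @export
inhibitory_pool <- function(n_pyr, n_inh, dnd_gain = 1) {
  stopifnot(n_pyr >= 1, n_inh >= 1, dnd_gain > 0)
  norm_cols <- function(m, s) sweep(m, 2, colSums(m) * n_inh / s, "/")
  theta_som <- norm_cols(matrix(stats::runif(n_inh * n_pyr), n_inh, n_pyr),
                         1)
  theta_dnd <- norm_cols(matrix(stats::runif(n_inh * n_pyr), n_inh, n_pyr),
                         dnd_gain)
  structure(list(theta_som = theta_som, theta_dnd = theta_dnd,
                 n_inh = n_inh, dnd_gain = dnd_gain,
                 I_pyr = numeric(n_pyr)),
            class = "inhibitory_pool")
}

#' Inhibitory feedback drives from the pool
#'
#' Advances the pooled pyramidal-output traces with the current pyramidal
#' rates and returns the per-readout inhibitory signals (the theta-weighted
#' sums of the filtered pyramidal outputs).
#'
#' @param pool An [inhibitory_pool()] object.
#' @param z Pyramidal output rates (kHz).
#' @param dt Time step (ms).
#' @param tau_L Trace decay constant (ms).
#' @return A list with the updated `pool` and vectors `I_sominh`, `I_dndinh`
#'   of length `n_inh`.
#' @export
inhibitory_feedback <- function(pool, z, dt, tau_L = 10) {
  g <- if (is.null(pool$dnd_gain)) 1 else pool$dnd_gain
  max_col <- max(abs(colSums(pool$theta_som) - 1 / pool$n_inh),
                 abs(colSums(pool$theta_dnd) - g / pool$n_inh))
  if (max_col > 1e-8)
    stop("inhibitory_feedback: pool weights are not column-normalized")
  pool$I_pyr <- step_synaptic_trace(pool$I_pyr, z, dt, tau_L)
  list(pool = pool,
       I_sominh = drop(pool$theta_som %*% pool$I_pyr),
       I_dndinh = drop(pool$theta_dnd %*% pool$I_pyr))
}
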