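#' Instantaneous update terms of the combined BCM/coincidence rule
#'
#' The target weight-change rates for somatic and dendritic excitatory
#' synapses.  Each combines a BCM term (postsynaptic activity times activity
#' minus the sliding threshold) with a coincidence term proportional to the
#' product of the two compartments' activations, gated by `(1 - activation)`
#' and multiplied by the presynaptic trace:
#' \deqn{\eta\,[(1-\alpha) x (x - \theta^{som}) + \alpha x y](1 - x)\, I^{som}_j}
#' and the dendritic analogue with `y` and `theta_dnd`.
#'
#' For multiple neurons, `x`, `y` and the thresholds are vectors over
#' neurons and `I_som`/`I_dnd` vectors over presynaptic sources; the result
#' is then the corresponding outer-product matrix (neurons x sources).
#'
#' @param x,y Compartment activations.
#' @param theta_som,theta_dnd Sliding thresholds per neuron.
#' @param I_som,I_dnd Presynaptic traces per source.
#' @param p A [plasticity_params()] object.
#' @return A list with `som` and `dnd` target terms.
#' @export
two_compartment_update_terms <- function(x, y, theta_som, theta_dnd,
                                         I_som, I_dnd,
                                         p = plasticity_params()) {
  g_som <- p$eta * ((1 - p$alpha) * x * (x - theta_som) + p$alpha * x * y) *
    (1 - x)
  g_dnd <- p$eta * ((1 - p$alpha) * y * (y - theta_dnd) + p$alpha * x * y) *
    (1 - y)
  if (length(x) > 1 || length(I_som) > 1) {
    list(som = outer(g_som, I_som), dnd = outer(g_dnd, I_dnd))
  } else {
    list(som = g_som * I_som, dnd = g_dnd * I_dnd)
  }
}

#' Instantaneous update term for dendritic inhibitory synapses
#'
#' Dendritic inhibition is modified by the same functional form as the
#' excitatory rule but with a fixed threshold `theta_inh` and its own
#' learning rate:
#' \deqn{\eta^{inh}[(1-\alpha) y (y - \theta^{inh}) + \alpha x y](1 - y)\, I^{inh}}
#'
#' @param x,y Compartment activations (vectors over neurons).
#' @param I_inh Presynaptic inhibitory traces (vector over readouts).
#' @param p A [plasticity_params()] object.
#' @return Target term; a matrix (neurons x readouts) when either argument
#'   has length > 1.
#' @export
inhibitory_update_term <- function(x, y, I_inh, p = plasticity_params()) {
  g <- p$eta_inh *
    ((1 - p$alpha) * y * (y - p$theta_inh) + p$alpha * x * y) * (1 - y)
  if (length(x) > 1 || length(I_inh) > 1) outer(g, I_inh) else g * I_inh
}

#' Alternative calcium-based BCM update terms
#'
#' A variant rule in which the coincidence signal enters through effective
#' calcium activities `z_som = (1 - alpha_som) x + alpha_som x y` and
#' `z_dnd = (1 - alpha_dnd) y + alpha_dnd x y`, each plugged into a plain
#' BCM bracket.  Sliding thresholds must be computed from the running means
#' of `z_som` and `z_dnd` (not of `x` and `y`).
#'
#' @param x,y Compartment activations.
#' @param theta_som,theta_dnd Sliding thresholds (from the z running means).
#' @param I_som,I_dnd Presynaptic traces.
#' @param alpha_som,alpha_dnd Mixing weights of the coincidence signal.
#' @param eta Learning rate.
#' @return A list with `som` and `dnd` target terms and the effective
#'   activities `z_som`, `z_dnd`.
#' @export
alt_calcium_bcm_terms <- function(x, y, theta_som, theta_dnd, I_som, I_dnd,
                                  alpha_som, alpha_dnd, eta = 1) {
  z_som <- (1 - alpha_som) * x + alpha_som * x * y
  z_dnd <- (1 - alpha_dnd) * y + alpha_dnd * x * y
  list(som = eta * z_som * (z_som - theta_som) * (1 - x) * I_som,
       dnd = eta * z_dnd * (z_dnd - theta_dnd) * (1 - y) * I_dnd,
       z_som = z_som, z_dnd = z_dnd)
}

#' Update running mean activities and sliding thresholds
#'
#' The per-neuron mean activities low-pass filter the activations with time
#' constant `tau_mean`; the sliding thresholds are `c0 * E^2` at all times.
#'
#' @param E_som,E_dnd Running mean activities.
#' @param x,y Current activations (or effective calcium activities for the
#'   alternative rule).
#' @param dt Time step (ms).
#' @param p A [plasticity_params()] object.
#' @return A list with `E_som`, `E_dnd`, `theta_som`, `theta_dnd`.
#' @export
update_moving_thresholds <- function(E_som, E_dnd, x, y, dt,
                                     p = plasticity_params()) {
  if (dt <= 0) stop("update_moving_thresholds: dt must be positive")
  E_som <- E_som + dt * (x - E_som) / p$tau_mean
  E_dnd <- E_dnd + dt * (y - E_dnd) / p$tau_mean
  list(E_som = E_som, E_dnd = E_dnd,
       theta_som = p$c0 * E_som^2, theta_dnd = p$c0 * E_dnd^2)
}

#' One step of the second-order stochastic weight dynamics
#'
#' Weight changes are delayed through first-order variables `dw` that relax
#' towards the instantaneous target terms with time constant `tau_w`; the
#' weights themselves integrate `dw`, a passive decay, and (for excitatory
#' weights) spontaneous Gaussian fluctuations:
#' \deqn{\tau_w \, d(\Delta w)/dt = -\Delta w + target}
#' \deqn{dw/dt = \Delta w - \eta_{decay} w + \sigma_w \epsilon(t)}
#' After integration negative weights are clipped to zero and, when
#' `zero_diag = TRUE`, the diagonal (self-connections of a recurrent matrix)
#' is forced to zero.  The per-step noise standard deviation is
#' `sigma_w * sqrt(dt)` so the fluctuation strength is dt-invariant (with
#' `sigma_w` calibrated at a 1-ms step).
#'
#' @param w Weight matrix (or vector).
#' @param dw Second-order weight-change variable, same shape as `w`.
#' @param target Instantaneous target term, same shape as `w`.
#' @param dt Time step (ms).
#' @param p A [plasticity_params()] object.
#' @param noise Logical; apply the `sigma_w` fluctuations (excitatory
#'   weights).  Dendritic inhibitory weights evolve without noise.
#' @param zero_diag Logical; force a zero diagonal after the update.
#' @return A list with updated `w` and `dw`.
#' @export
step_weight_dynamics <- function(w, dw, target, dt, p = plasticity_params(),
                                 noise = TRUE, zero_diag = FALSE) {
  dw <- dw + dt * (target - dw) / p$tau_w
  w <- w + dt * (dw - p$eta_decay * w)
  if (noise && p$sigma_w > 0)
    w <- w + p$sigma_w * sqrt(dt) * stats::rnorm(length(w))
  w[w < 0] <- 0
  if (zero_diag) {
    if (is.matrix(w)) diag(w) <- 0 else w[] <- w
  }
  list(w = w, dw = dw)
}

#' Objective function of the combined learning rule
#'
#' The rule for the two-compartment neuron (at `beta = 0`) ascends
#' \deqn{L = (1-\alpha)(\tfrac12 E[x^2] + \tfrac12 E[y^2]
#'       - c_0 E[x]^3 - c_0 E[y]^3) + \alpha E[xy],}
#' i.e. it maximizes second moments and the cross-compartment correlation
#' while homeostatically penalizing the cubed mean activities.
#'
#' @param x_trace,y_trace Equal-length activation traces.
#' @param alpha Relative weight of the correlation term.
#' @param c0 Homeostatic penalty scale.
#' @return The scalar objective value.
#' @export
objective_value <- function(x_trace, y_trace, alpha, c0 = 70) {
  if (length(x_trace) == 0 || length(y_trace) == 0)
    stop("objective_value: empty traces")
  if (length(x_trace) != length(y_trace))
    stop("objective_value: traces of unequal length")
  (1 - alpha) * (0.5 * mean(x_trace^2) + 0.5 * mean(y_trace^2) -
                   c0 * mean(x_trace)^3 - c0 * mean(y_trace)^3) +
    alpha * mean(x_trace * y_trace)
}

#' Objective function with frozen sliding thresholds
#'
#' The same objective as [objective_value()] but with the homeostatic terms
#' written as `theta * E[x]` for externally supplied constant thresholds.
#' When `theta = c0 * E[x]^2` is evaluated at the operating point the two
#' forms take the same value; treating the thresholds as constants during
#' differentiation is what makes the finite-difference gradient of this
#' functional match the learning rule exactly.
#'
#' @inheritParams objective_value
#' @param theta_som,theta_dnd Frozen threshold values.
#' @return The scalar objective value.
#' @export
objective_value_frozen <- function(x_trace, y_trace, alpha,
                                   theta_som, theta_dnd) {
  if (length(x_trace) == 0 || length(y_trace) == 0)
    stop("objective_value_frozen: empty traces")
  (1 - alpha) * (0.5 * mean(x_trace^2) + 0.5 * mean(y_trace^2) -
                   theta_som * mean(x_trace) - theta_dnd * mean(y_trace)) +
    alpha * mean(x_trace * y_trace)
}
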