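#' Neuron parameters for the two-compartment rate model
#'
#' Bundles the cell-level constants of the two-compartment pyramidal neuron:
#' the sigmoidal activation threshold, the cross-compartment coupling gains,
#' and the maximal firing rates.  Time is in milliseconds and rates in kHz
#' throughout the package, so `phi = 0.08` corresponds to 80 Hz.
#'
#' @param phi Maximum somatic firing rate (kHz).
#' @param phi_input Maximum firing rate of input (EC) neurons (kHz).
#' @param theta_f Threshold of the sigmoidal response function (dimensionless
#'   drive units).
#' @param beta Gain of the cross-compartment threshold modulation: the
#'   activation of one compartment lowers the effective threshold of the
#'   other with weight `beta`, one delay step later.
#' @param gamma Calcium-spike gain amplification: the output rate is
#'   `(1 + gamma * y) * phi * x`, so dendritic activation multiplicatively
#'   boosts somatic output.
#' @param delta_t Cross-compartment delay (ms); with the default 1-ms Euler
#'   step this is exactly one integration step.
#' @param tau_L Decay constant of unweighted postsynaptic currents (ms).
#'
#' @return An object of class `"neuron_params"` (a named list).
#' @examples
#' p <- neuron_params()
#' output_rate(0.5, 0, p)  # 0.04 kHz = 40 Hz
#' @export
neuron_params <- function(phi = 0.08, phi_input = 0.08, theta_f = 5,
                          beta = 2.5, gamma = 1, delta_t = 1, tau_L = 10) {
  stopifnot(phi > 0, phi_input > 0, delta_t > 0, gamma >= 0, beta >= 0,
            tau_L > 0)
  structure(list(phi = phi, phi_input = phi_input, theta_f = theta_f,
                 beta = beta, gamma = gamma, delta_t = delta_t,
                 tau_L = tau_L),
            class = "neuron_params")
}

#' Long-term plasticity parameters
#'
#' Constants of the combined BCM/coincidence learning rule and of the
#' second-order weight dynamics (delayed weight changes, decay, spontaneous
#' fluctuations) and the sliding-threshold machinery.
#'
#' @param alpha Relative weight of the coincidence (CCA-like) term in the
#'   learning rule, in \[0, 1\]; `alpha = 0` reduces to plain BCM.
#' @param eta Learning rate of excitatory synapses.
#' @param eta_inh Learning rate of dendritic inhibitory synapses; set to 0 to
#'   disable inhibitory plasticity.
#' @param c0 Scale of the sliding threshold, `theta = c0 * E^2` where `E` is
#'   the running-mean activity.
#' @param theta_inh Fixed threshold of the inhibitory learning rule.
#' @param tau_w Time constant of the delayed (second-order) weight-change
#'   variables (ms).
#' @param eta_decay Passive weight decay rate (1/ms).
#' @param sigma_w Amplitude of the spontaneous weight fluctuations (standard
#'   deviation of the per-step Gaussian noise at a 1-ms step).
#' @param tau_mean Time constant of the running-mean activities used by the
#'   sliding thresholds (ms).
#'
#' @return An object of class `"plasticity_params"`.
#' @export
plasticity_params <- function(alpha = 0.9, eta = 1, eta_inh = 1, c0 = 70,
                              theta_inh = 0.5, tau_w = 1000,
                              eta_decay = 1e-7, sigma_w = 0.001,
                              tau_mean = 60000) {
  stopifnot(alpha >= 0, alpha <= 1, tau_w > 0, tau_mean > 0, eta_decay >= 0,
            sigma_w >= 0)
  structure(list(alpha = alpha, eta = eta, eta_inh = eta_inh, c0 = c0,
                 theta_inh = theta_inh, tau_w = tau_w,
                 eta_decay = eta_decay, sigma_w = sigma_w,
                 tau_mean = tau_mean),
            class = "plasticity_params")
}

#' Short-term plasticity parameters
#'
#' @param tau_STD Recovery time constant of the depression variable `D` (ms).
#' @param tau_STF Decay time constant of the facilitation variable `F` (ms).
#' @param U_STF Baseline release probability; `F` relaxes to this value at
#'   rest and facilitates towards 1 under presynaptic drive.
#'
#' @return An object of class `"stp_params"`.
#' @export
stp_params <- function(tau_STD = 500, tau_STF = 200, U_STF = 0.5) {
  stopifnot(tau_STD > 0, tau_STF > 0, U_STF > 0, U_STF <= 1)
  structure(list(tau_STD = tau_STD, tau_STF = tau_STF, U_STF = U_STF),
            class = "stp_params")
}
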