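#' Input generator for the single-cell protocols
#'
#' Builds the stateful input machinery of the single-cell experiments.
#' A small set of slow Ornstein-Uhlenbeck sources drives groups of input
#' neurons; each input neuron integrates its source mixture plus private
#' white noise into an input current and fires at
#' `phi_input * f(current)`.
#'
#' Conditions:
#' \describe{
#'   \item{`fig1_correlated` / `fig1_uncorrelated`}{50 somatic inputs
#'     (minority group A of 10, majority group B of 40) and 50 dendritic
#'     inputs (A' of 10, B' of 40).  B and B' always follow independent
#'     sources.  In the correlated condition A and A' share one source;
#'     in the uncorrelated condition they follow two independent sources.
#'     `literal_mapping = TRUE` instead applies the printed source
#'     assignment verbatim (which makes the "uncorrelated" label share
#'     group A's source).}
#'   \item{`fig3_separation`}{10 somatic inputs driven by the sum of two
#'     sources; 20 dendritic inputs split into groups A and B, each driven
#'     by one of the two sources.}
#'   \item{`fig3_stability`}{10 somatic inputs driven by source 1; 20
#'     dendritic inputs whose source assignment switches at the phase
#'     boundaries: initially all independent; then group A (1-10) follows
#'     source 1; finally group B (11-20) follows source 1 and group A
#'     returns to independent sources.}
#' }
#'
#' @param condition One of the condition strings above.
#' @param p A [neuron_params()] object (for `phi_input`, `theta_f`, `tau_L`).
#' @param tau_s,sigma_s OU source parameters.
#' @param sigma_n Private input-current noise amplitude.
#' @param phase_boundaries_ms For `fig3_stability`: the two switch times
#'   (ms).
#' @param literal_mapping Apply the printed source labels for the fig1
#'   conditions verbatim (see above).
#' @return A list with `n_som`, `n_dnd`, group index lists `groups_som`,
#'   `groups_dnd`, the phase boundaries and per-phase source-mixing
#'   matrices (`M_som`, `M_dnd`: inputs x sources), an initial `state`, and
#'   a `step(state, t, dt)` function returning the updated state with rates
#'   `u_som`, `u_dnd` and currents `I_input_som`, `I_input_dnd`.
#' @export
make_single_cell_inputs <- function(condition, p = neuron_params(),
                                    tau_s = 10, sigma_s = 0.1,
                                    sigma_n = 0.1,
                                    phase_boundaries_ms = c(3e5, 6e5),
                                    literal_mapping = FALSE,
                                    s0 = NULL) {
  cond <- match.arg(condition,
                    c("fig1_correlated", "fig1_uncorrelated",
                      "fig3_separation", "fig3_stability"))
  one_hot <- function(src, n_src) {
    M <- matrix(0, length(src), n_src)
    M[cbind(seq_along(src), src)] <- 1
    M
  }

  if (cond %in% c("fig1_correlated", "fig1_uncorrelated")) {
    n_som <- 50; n_dnd <- 50; n_src <- 4
    groups_som <- list(A = 1:10, B = 11:50)
    groups_dnd <- list(A = 1:10, B = 11:50)
    correlated <- cond == "fig1_correlated"
    if (literal_mapping) correlated <- !correlated
    src_Ap <- if (correlated) 1L else 2L
    boundaries <- numeric(0)
    M_som <- list(one_hot(c(rep(1L, 10), rep(3L, 40)), n_src))
    M_dnd <- list(one_hot(c(rep(src_Ap, 10), rep(4L, 40)), n_src))
  } else if (cond == "fig3_separation") {
    n_som <- 10; n_dnd <- 20; n_src <- 2
    groups_som <- list(C = 1:10)
    groups_dnd <- list(A = 1:10, B = 11:20)
    boundaries <- numeric(0)
    M_som <- list(matrix(1, n_som, n_src))  # soma driven by s1 + s2
    M_dnd <- list(one_hot(c(rep(1L, 10), rep(2L, 10)), n_src))
  } else {                                   # fig3_stability
    n_som <- 10; n_dnd <- 20; n_src <- 21
    groups_som <- list(C = 1:10)
    groups_dnd <- list(A = 1:10, B = 11:20)
    indep <- 2:21                            # source j+1 for input j
    boundaries <- phase_boundaries_ms
    M_som <- rep(list(one_hot(rep(1L, n_som), n_src)), 3)
    M_dnd <- list(one_hot(indep, n_src),
                  one_hot(c(rep(1L, 10), indep[11:20]), n_src),
                  one_hot(c(indep[1:10], rep(1L, 10)), n_src))
  }

  state <- list(s = if (is.null(s0)) numeric(n_src) else s0,
                I_input_som = numeric(n_som),
                I_input_dnd = numeric(n_dnd))
  phase_of <- function(t) 1L + sum(t >= boundaries)

  step <- function(state, t, dt) {
    s <- ou_step(state$s, dt, tau_s, sigma_s)
    ph <- phase_of(t)
    dr_som <- drop(M_som[[ph]] %*% s)
    dr_dnd <- drop(M_dnd[[ph]] %*% s)
    Is <- state$I_input_som +
      dt * (-state$I_input_som / p$tau_L + dr_som) +
      sigma_n * sqrt(dt) * stats::rnorm(n_som)
    Id <- state$I_input_dnd +
      dt * (-state$I_input_dnd / p$tau_L + dr_dnd) +
      sigma_n * sqrt(dt) * stats::rnorm(n_dnd)
    list(s = s, I_input_som = Is, I_input_dnd = Id,
         u_som = p$phi_input * sigmoid_response(Is, p$theta_f),
         u_dnd = p$phi_input * sigmoid_response(Id, p$theta_f))
  }

  list(condition = cond, n_som = n_som, n_dnd = n_dnd, n_src = n_src,
       groups_som = groups_som, groups_dnd = groups_dnd,
       tau_s = tau_s, sigma_s = sigma_s, sigma_n = sigma_n,
       boundaries = boundaries, M_som = M_som, M_dnd = M_dnd,
       state = state, step = step)
}
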