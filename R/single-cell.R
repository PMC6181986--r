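#' Simulate one or more two-compartment cells with shared inputs
#'
#' Runs the single-cell learning protocols: a small group of pyramidal
#' cells (usually one or two) receives the same somatic and dendritic input
#' streams from [make_single_cell_inputs()], optionally with an inhibitory
#' feedback unit, and all synapses evolve under the second-order stochastic
#' weight dynamics.  Two plasticity rules are available: the default
#' combined BCM + coincidence rule, and the alternative calcium-BCM rule in
#' which the coincidence signal enters through effective activities
#' `z_som`, `z_dnd` and the sliding thresholds track those activities.
#'
#' @param inputs A generator from [make_single_cell_inputs()].
#' @param duration_ms Simulated time (ms).
#' @param dt Step (ms).
#' @param n_cells Number of pyramidal cells.
#' @param p,pp Parameter objects.
#' @param rule `"combined"` or `"calcium_bcm"`.
#' @param alpha_som,alpha_dnd Mixing weights for the calcium-BCM rule
#'   (ignored by the combined rule, which uses `pp$alpha`).
#' @param inhibition `NULL`, or a list with `n_inh` (readouts) and `v_som`
#'   (fixed somatic inhibitory weight); dendritic inhibitory weights start
#'   at zero and follow the inhibitory plasticity rule with `pp$eta_inh`.
#' @param w_som_init,w_dnd_init Initial weights (`n_cells` x inputs);
#'   default uniform on \[0, 5\].
#' @param record_every Record activity traces every this many steps.
#' @param snapshot_every Record weight snapshots every this many steps.
#' @param record_inputs Also record the postsynaptic input traces (needed
#'   for the reference PCA/CCA analysis).
#' @param engine `"cpp"` (compiled, fast) or `"r"` (pure-R reference loop);
#'   the two implement identical dynamics and are cross-checked in the test
#'   suite.
#' @param seed Seed of the compiled engine's random stream; defaults to a
#'   draw from the R session's RNG (so `set.seed()` upstream makes the
#'   whole run reproducible).
#' @return A list of class `"cell_record"`.
#' @export
simulate_cells <- function(inputs, duration_ms, dt = 1, n_cells = 1,
                           p = neuron_params(beta = 0, gamma = 1),
                           pp = plasticity_params(alpha = 0.5, eta = 0.2,
                                                  sigma_w = 0.005),
                           rule = c("combined", "calcium_bcm"),
                           alpha_som = 0.5, alpha_dnd = 0.5,
                           inhibition = NULL,
                           w_som_init = NULL, w_dnd_init = NULL,
                           record_every = 100L, snapshot_every = 5000L,
                           record_inputs = FALSE,
                           engine = c("cpp", "r"), seed = NULL) {
  rule <- match.arg(rule)
  engine <- match.arg(engine)
  n_steps <- round(duration_ms / dt)
  ns <- inputs$n_som; nd <- inputs$n_dnd; K <- n_cells
  if (is.null(w_som_init))
    w_som_init <- matrix(stats::runif(K * ns, 0, 5), K, ns)
  if (is.null(w_dnd_init))
    w_dnd_init <- matrix(stats::runif(K * nd, 0, 5), K, nd)
  w_som <- w_som_init; w_dnd <- w_dnd_init
  dw_som <- matrix(0, K, ns); dw_dnd <- matrix(0, K, nd)

  use_inh <- !is.null(inhibition)
  if (use_inh) {
    n_inh <- inhibition$n_inh
    pool <- inhibition$pool
    if (is.null(pool)) pool <- inhibitory_pool(K, n_inh)
    v_som <- inhibition$v_som
    v_dnd <- matrix(0, K, n_inh)
    dv_dnd <- matrix(0, K, n_inh)
    I_pyr <- numeric(K)
  }

  if (engine == "cpp") {
    if (is.null(seed)) seed <- sample.int(2147483646L, 1)
    par <- list(dt = dt, n_steps = as.integer(n_steps), phi = p$phi,
                phi_input = p$phi_input, theta_f = p$theta_f,
                beta = p$beta, gamma = p$gamma, tau_L = p$tau_L,
                alpha = pp$alpha, eta = pp$eta, eta_inh = pp$eta_inh,
                c0 = pp$c0, theta_inh = pp$theta_inh, tau_w = pp$tau_w,
                eta_decay = pp$eta_decay, sigma_w = pp$sigma_w,
                tau_mean = pp$tau_mean,
                rule = if (rule == "combined") 0L else 1L,
                alpha_som = alpha_som, alpha_dnd = alpha_dnd,
                use_inh = as.integer(use_inh),
                v_som = if (use_inh) v_som else 0)
    if (use_inh) {
      par$theta_som_pool <- pool$theta_som
      par$theta_dnd_pool <- pool$theta_dnd
    }
    inp <- list(n_src = as.integer(inputs$n_src), tau_s = inputs$tau_s,
                sigma_s = inputs$sigma_s, sigma_n = inputs$sigma_n,
                boundaries = as.numeric(inputs$boundaries),
                M_som = inputs$M_som, M_dnd = inputs$M_dnd,
                s0 = inputs$state$s)
    out <- simulate_cells_cpp(
      inp, par,
      list(w_som_init = w_som_init, w_dnd_init = w_dnd_init,
           record_every = as.integer(record_every),
           snapshot_every = as.integer(snapshot_every),
           record_inputs = as.integer(record_inputs),
           seed = as.numeric(seed)))
    return(structure(list(
      time = drop(out$time), x = out$x, y = out$y, z = out$z,
      I_som = out$I_som, I_dnd = out$I_dnd,
      w_som = out$w_som, w_dnd = out$w_dnd,
      v_dnd = out$v_dnd,
      snapshots = list(time = drop(out$snap_t), w_som = out$snap_w_som,
                       w_dnd = out$snap_w_dnd, v_dnd = out$snap_v_dnd),
      groups_som = inputs$groups_som, groups_dnd = inputs$groups_dnd,
      condition = inputs$condition, rule = rule,
      params = list(neuron = p, plasticity = pp), dt = dt),
      class = "cell_record"))
  }

  in_state <- inputs$state
  I_som <- numeric(ns); I_dnd <- numeric(nd)
  f0 <- sigmoid_response(0, p$theta_f)
  x <- rep(f0, K); y <- rep(f0, K)
  z <- (1 + p$gamma * f0) * p$phi * x
  E_som <- numeric(K); E_dnd <- numeric(K)

  n_rec <- n_steps %/% record_every
  rec_x <- matrix(0, K, n_rec); rec_y <- matrix(0, K, n_rec)
  rec_z <- matrix(0, K, n_rec)
  rec_t <- numeric(n_rec)
  if (record_inputs) {
    rec_Isom <- matrix(0, ns, n_rec); rec_Idnd <- matrix(0, nd, n_rec)
  }
  n_snap <- n_steps %/% snapshot_every
  snap_w_som <- array(0, c(K, ns, n_snap))
  snap_w_dnd <- array(0, c(K, nd, n_snap))
  snap_v_dnd <- if (use_inh) array(0, c(K, n_inh, n_snap)) else NULL
  snap_t <- numeric(n_snap)

  sw <- pp$sigma_w * sqrt(dt)
  rw <- dt / pp$tau_w
  ri <- 0L; si <- 0L

  for (k in seq_len(n_steps)) {
    t_now <- (k - 1) * dt

    # inputs
    in_state <- inputs$step(in_state, t_now, dt)
    I_som <- I_som + dt * (-I_som / p$tau_L + in_state$u_som)
    I_dnd <- I_dnd + dt * (-I_dnd / p$tau_L + in_state$u_dnd)

    # inhibitory feedback from previous-step rates
    if (use_inh) {
      I_pyr <- I_pyr + dt * (-I_pyr / p$tau_L + z)
      I_sominh <- drop(pool$theta_som %*% I_pyr)
      I_dndinh <- drop(pool$theta_dnd %*% I_pyr)
      inh_som <- v_som * sum(I_sominh)
      inh_dnd <- drop(v_dnd %*% I_dndinh)
    } else {
      inh_som <- 0; inh_dnd <- 0
    }

    # activations (one-step delayed cross-compartment terms)
    x_new <- sigmoid_response(drop(w_som %*% I_som) - inh_som +
                                p$beta * y, p$theta_f)
    y_new <- sigmoid_response(drop(w_dnd %*% I_dnd) - inh_dnd +
                                p$beta * x, p$theta_f)
    z <- (1 + p$gamma * y_new) * p$phi * x_new

    # plasticity
    if (rule == "combined") {
      E_som <- E_som + dt * (x_new - E_som) / pp$tau_mean
      E_dnd <- E_dnd + dt * (y_new - E_dnd) / pp$tau_mean
      th_s <- pp$c0 * E_som^2; th_d <- pp$c0 * E_dnd^2
      xy <- x_new * y_new
      g_som <- pp$eta * ((1 - pp$alpha) * x_new * (x_new - th_s) +
                           pp$alpha * xy) * (1 - x_new)
      g_dnd <- pp$eta * ((1 - pp$alpha) * y_new * (y_new - th_d) +
                           pp$alpha * xy) * (1 - y_new)
    } else {
      zs <- (1 - alpha_som) * x_new + alpha_som * x_new * y_new
      zd <- (1 - alpha_dnd) * y_new + alpha_dnd * x_new * y_new
      E_som <- E_som + dt * (zs - E_som) / pp$tau_mean
      E_dnd <- E_dnd + dt * (zd - E_dnd) / pp$tau_mean
      th_s <- pp$c0 * E_som^2; th_d <- pp$c0 * E_dnd^2
      g_som <- pp$eta * zs * (zs - th_s) * (1 - x_new)
      g_dnd <- pp$eta * zd * (zd - th_d) * (1 - y_new)
    }
    dw_som <- dw_som + rw * (outer(g_som, I_som) - dw_som)
    w_som <- w_som + dt * (dw_som - pp$eta_decay * w_som) +
      sw * matrix(stats::rnorm(K * ns), K, ns)
    w_som[w_som < 0] <- 0
    dw_dnd <- dw_dnd + rw * (outer(g_dnd, I_dnd) - dw_dnd)
    w_dnd <- w_dnd + dt * (dw_dnd - pp$eta_decay * w_dnd) +
      sw * matrix(stats::rnorm(K * nd), K, nd)
    w_dnd[w_dnd < 0] <- 0
    if (use_inh) {
      g_v <- pp$eta_inh * ((1 - pp$alpha) * y_new * (y_new - pp$theta_inh) +
                             pp$alpha * x_new * y_new) * (1 - y_new)
      dv_dnd <- dv_dnd + rw * (outer(g_v, I_dndinh) - dv_dnd)
      v_dnd <- v_dnd + dt * (dv_dnd - pp$eta_decay * v_dnd)
      v_dnd[v_dnd < 0] <- 0
    }
    x <- x_new; y <- y_new

    if (k %% record_every == 0 && ri < n_rec) {
      ri <- ri + 1L
      rec_x[, ri] <- x; rec_y[, ri] <- y; rec_z[, ri] <- z
      rec_t[ri] <- k * dt
      if (record_inputs) {
        rec_Isom[, ri] <- I_som; rec_Idnd[, ri] <- I_dnd
      }
    }
    if (k %% snapshot_every == 0 && si < n_snap) {
      si <- si + 1L
      snap_w_som[, , si] <- w_som; snap_w_dnd[, , si] <- w_dnd
      if (use_inh) snap_v_dnd[, , si] <- v_dnd
      snap_t[si] <- k * dt
    }
  }

  structure(list(
    time = rec_t, x = rec_x, y = rec_y, z = rec_z,
    I_som = if (record_inputs) rec_Isom else NULL,
    I_dnd = if (record_inputs) rec_Idnd else NULL,
    w_som = w_som, w_dnd = w_dnd,
    v_dnd = if (use_inh) v_dnd else NULL,
    snapshots = list(time = snap_t, w_som = snap_w_som,
                     w_dnd = snap_w_dnd, v_dnd = snap_v_dnd),
    groups_som = inputs$groups_som, groups_dnd = inputs$groups_dnd,
    condition = inputs$condition, rule = rule,
    params = list(neuron = p, plasticity = pp), dt = dt),
    class = "cell_record")
}
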