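#' Build an experiment configuration
#'
#' Assembles the full parameter set of one of the built-in protocol
#' presets, applying optional overrides.  Presets:
#' \describe{
#'   \item{`fig1_correlated`, `fig1_uncorrelated`}{Single-cell learning
#'     with minority/majority input groups (correlated or uncorrelated
#'     minority pair).}
#'   \item{`fig2_sweep`}{Grid of single-cell runs over `alpha` and `beta`.}
#'   \item{`fig2c_altrule`}{Grid over `alpha_som`, `alpha_dnd` with the
#'     calcium-BCM rule.}
#'   \item{`fig3_separation`}{Two cells with a shared inhibitory unit.}
#'   \item{`fig3_stability`}{One cell with dendritic inhibition and a
#'     three-phase input-correlation switch.}
#'   \item{`fig4_track`}{Recurrent network on the 1D track (place +
#'     distractor EC inputs).}
#'   \item{`fig5_grid`}{1D track with grid-cell EC inputs.}
#'   \item{`fig6_replay`}{First run, spontaneous replay exposure with EC
#'     bursts, then a probe run.}
#'   \item{`fig7_ymaze`}{Three-arm maze over a three-sequence network.}
#'   \item{`fig8_branching`}{Branching-sequence network with pre/post
#'     spontaneous counting windows.}
#' }
#'
#' `scale` multiplies all phase durations (behavior is traversed faster;
#' the theta frequency and all time constants are untouched).  Network
#' sizes are part of the configuration and can be overridden for
#' desk-scale runs.
#'
#' @param preset Preset name (see above).
#' @param seed Integer seed; all randomness derives from it.
#' @param scale Duration scale factor in (0, 1].
#' @param dt Integration step (ms).
#' @param ... Named overrides of preset fields.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(preset, seed = 1L, scale = 1, dt = 1, ...) {
  presets <- c("fig1_correlated", "fig1_uncorrelated", "fig2_sweep",
               "fig2c_altrule", "fig3_separation", "fig3_stability",
               "fig4_track", "fig5_grid", "fig6_replay", "fig7_ymaze",
               "fig8_branching")
  preset <- match.arg(preset, presets)
  base <- list(preset = preset, seed = as.integer(seed), scale = scale,
               dt = dt)
  defaults <- switch(
    preset,
    fig1_correlated = ,
    fig1_uncorrelated = list(
      duration = 1.5e6, alpha = 0.5, beta = 0, gamma = 1, eta = 0.2,
      sigma_w = 0.005, phi = 0.08, phi_input = 0.08, w_init_max = 5),
    fig2_sweep = list(
      duration = 1.5e6, alphas = c(0, 0.25, 0.5, 0.75, 1),
      betas = c(0, 1, 2, 4), gamma = 1, eta = 0.2, sigma_w = 0.005),
    fig2c_altrule = list(
      duration = 1.5e6, alphas_som = c(0.1, 0.5, 0.9),
      alphas_dnd = c(0.1, 0.5, 0.9), eta = 0.2, sigma_w = 0.005),
    fig3_separation = list(
      duration = 9e5, alpha = 0.9, beta = 2.5, gamma = 1, eta = 0.2,
      eta_inh = 0.2, v_som = 20, n_inh = 1, w_init_max = 5),
    fig3_stability = list(
      phase_ms = c(3e5, 3e5, 6e5), alpha = 0.9, beta = 2.5, gamma = 1,
      eta = 0.2, eta_inh = 0.2, v_som = 20, n_inh = 1, w_init_max = 5),
    fig4_track = list(
      n_ca3 = 300, n_place = 300, n_dist = 200, n_inh = 100,
      w_max = 18, w_width = 5, w_dnd_max = 5, w_scale = 1,
      familiarity = "unfamiliar", v_som = NULL, v_som_ref = 26.7,
      dnd_gain = 40,
      alpha = 0.9, beta = 2.5, gamma = 1, eta = 1, eta_inh = 1,
      phi = 0.08, single_compartment = FALSE,
      trig_amp = 10, A_theta = 10, f_theta = 7 / 1000,
      record_every = 5L, n_bin = 50),
    fig5_grid = list(
      n_ca3 = 300, n_grid = 200, n_dist = 100, n_inh = 100,
      w_max = 18, w_width = 5, w_dnd_max = 5, w_scale = 1,
      familiarity = "unfamiliar", v_som = NULL, v_som_ref = 26.7,
      dnd_gain = 40,
      alpha = 0.9, beta = 2.5, gamma = 1, eta = 1, eta_inh = 1,
      phi = 0.08, single_compartment = FALSE,
      trig_amp = 10, A_theta = 10, f_theta = 7 / 1000,
      record_every = 5L, n_bin = 50),
    fig6_replay = list(
      n_ca3 = 300, n_place = 300, n_dist = 0, n_inh = 100,
      w_max = 18, w_width = 5, w_dnd_max = 5, w_scale = 1,
      familiarity = "unfamiliar", v_som = NULL, v_som_ref = 26.7,
      dnd_gain = 40,
      alpha = 0.9, beta = 2.5, gamma = 1, eta = 1, eta_inh = 1,
      phi = 0.08, exposure_ms = 6e5, remove_inhibition = FALSE,
      trig_amp = 10, A_theta = 10, f_theta = 7 / 1000,
      record_every = 5L, n_bin = 50),
    fig7_ymaze = list(
      n_group = 150, n_ec_per_arm = 150, n_inh = 100,
      w_max = 20, w_width = 5, w_ec_max = 2, v_som = NULL,
      v_som_ref = 26.7, dnd_gain = 40,
      alpha = 0.9, beta = 2.5, gamma = 1, eta = 1, eta_inh = 1,
      phi = 0.08, n_cycles = 6, n_trig = 10,
      trig_amp = 5, trig_dur = 200, A_theta = 10, f_theta = 7 / 1000,
      record_every = 5L, n_bin = 25),
    fig8_branching = list(
      n_root = 100, n_branch = 150, n_ec = 300, n_inh = 100,
      w_max = 18, w_prime_max = 14, w_width = 5, w_ec_max = 2,
      v_som = NULL, v_som_ref = 26.7, dnd_gain = 40, alpha = 0.9, beta = 2.5, gamma = 1, eta = 1,
      eta_inh = 1, phi = 0.08, immobile1_ms = 6e4, run_ms = 1.5e4,
      immobile2_ms = 6e4, second_experience = FALSE,
      trig_amp = 5, trig_dur = 500, trig_amp_immobile = 10,
      count_smooth_ms = 10, A_theta = 10, f_theta = 7 / 1000,
      record_every = 5L))
  cfg <- utils::modifyList(c(base, defaults), list(...))
  structure(cfg, class = "experiment_config")
}

# derive a well-separated child seed (< 2^31) for a simulation segment
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 104729 * k) %% 2147483647
}

# ---------------------------------------------------------------------------
# schedules
# ---------------------------------------------------------------------------

# 1D-track schedule: rest until 10 s, three runs until 50 s (all times
# multiplied by scale); Poisson triggers during rest plus a 100-ms trigger
# at first-run onset.
make_track_schedule <- function(cfg, with_trigger = TRUE) {
  sc <- cfg$scale; dt <- cfg$dt
  n_steps <- round(5e4 * sc / dt)
  t <- (seq_len(n_steps) - 1) * dt
  moving <- as.integer(t >= 1e4 * sc)
  pos <- position_1d(t / sc)
  theta <- theta_drive(t, moving, cfg$A_theta, cfg$f_theta)
  trig <- if (with_trigger) {
    trigger_schedule(n_steps, dt, moving, rate_hz = 1, dur_immobile = 10,
                     onsets_ms = 1e4 * sc, dur_onset = 100,
                     amplitude = cfg$trig_amp)
  } else numeric(n_steps)
  list(moving = moving, pos = pos, theta = theta, trig = trig)
}

# probe = the "third run" segment (40-50 s of the track trajectory)
make_probe_schedule <- function(cfg) {
  sc <- cfg$scale; dt <- cfg$dt
  n_steps <- round(1e4 * sc / dt)
  t <- (seq_len(n_steps) - 1) * dt
  pos <- position_1d(t / sc + 4e4)
  theta <- theta_drive(t, TRUE, cfg$A_theta, cfg$f_theta)
  list(moving = rep(1L, n_steps), pos = pos, theta = theta,
       trig = numeric(n_steps))
}

# spontaneous-activity exposure: immobile, Poisson triggers, EC bursts
make_exposure_schedule <- function(cfg, duration_ms) {
  dt <- cfg$dt
  n_steps <- round(duration_ms / dt)
  trig <- trigger_schedule(n_steps, dt, rep(FALSE, n_steps), rate_hz = 1,
                           dur_immobile = 10, amplitude = cfg$trig_amp)
  burst <- burst_schedule(n_steps, dt)
  list(moving = rep(0L, n_steps), pos = numeric(n_steps),
       theta = numeric(n_steps), trig = trig, burst = burst)
}

# Y-maze schedule: rest, then 10-s arm visits cycling through arms 1..3;
# 200-ms positive triggers at each first visit
make_ymaze_schedule <- function(cfg) {
  sc <- cfg$scale; dt <- cfg$dt
  rest_ms <- 1e4 * sc
  cyc_ms <- 1e4 * sc
  n_steps <- round((rest_ms + cfg$n_cycles * cyc_ms) / dt)
  t <- (seq_len(n_steps) - 1) * dt
  moving <- as.integer(t >= rest_ms)
  t_run <- pmax(t - rest_ms, 0)
  cyc <- floor(t_run / cyc_ms)
  pos <- position_ymaze_cycle((t_run - cyc * cyc_ms) / sc)
  arm <- ifelse(moving == 1L, (cyc %% 3) + 1L, 0L)
  theta <- theta_drive(t, moving, cfg$A_theta, cfg$f_theta)
  onsets <- rest_ms + (0:2) * cyc_ms
  trig <- trigger_schedule(n_steps, dt, moving, rate_hz = 1,
                           dur_immobile = 10, onsets_ms = onsets,
                           dur_onset = cfg$trig_dur,
                           amplitude = cfg$trig_amp)
  list(moving = moving, pos = pos, arm = as.integer(arm), theta = theta,
       trig = trig)
}

# branching-track experience: the 15-s first-run trajectory
make_branching_run_schedule <- function(cfg) {
  sc <- cfg$scale; dt <- cfg$dt
  n_steps <- round(cfg$run_ms * sc / dt)
  t <- (seq_len(n_steps) - 1) * dt
  pos <- position_1d(t / sc + 1e4)
  theta <- theta_drive(t, TRUE, cfg$A_theta, cfg$f_theta)
  trig <- trigger_schedule(n_steps, dt, rep(FALSE, n_steps), rate_hz = 0,
                           onsets_ms = 0, dur_onset = cfg$trig_dur,
                           amplitude = cfg$trig_amp)
  list(moving = rep(1L, n_steps), pos = pos, theta = theta, trig = trig)
}

# immobile counting window with Poisson triggers, optionally frozen weights
make_immobile_schedule <- function(cfg, duration_ms, plast_on = FALSE) {
  dt <- cfg$dt
  amp <- if (is.null(cfg$trig_amp_immobile)) cfg$trig_amp else
    cfg$trig_amp_immobile
  n_steps <- round(duration_ms / dt)
  trig <- trigger_schedule(n_steps, dt, rep(FALSE, n_steps), rate_hz = 1,
                           dur_immobile = 10, amplitude = amp)
  list(moving = rep(0L, n_steps), pos = numeric(n_steps),
       theta = numeric(n_steps), trig = trig,
       plast_on = rep(as.integer(plast_on), n_steps))
}

# ---------------------------------------------------------------------------
# preset runners
# ---------------------------------------------------------------------------

run_single_cell_preset <- function(cfg) {
  set.seed(cfg$seed)
  condition <- if (cfg$preset == "fig1_correlated") "fig1_correlated"
               else "fig1_uncorrelated"
  p <- neuron_params(phi = cfg$phi, phi_input = cfg$phi_input,
                     beta = cfg$beta, gamma = cfg$gamma)
  pp <- plasticity_params(alpha = cfg$alpha, eta = cfg$eta,
                          eta_inh = 0, sigma_w = cfg$sigma_w)
  inputs <- make_single_cell_inputs(condition, p)
  rec <- simulate_cells(inputs, cfg$duration * cfg$scale, dt = cfg$dt,
                        p = p, pp = pp,
                        w_som_init = matrix(stats::runif(inputs$n_som, 0,
                                                         cfg$w_init_max),
                                            1),
                        w_dnd_init = matrix(stats::runif(inputs$n_dnd, 0,
                                                         cfg$w_init_max),
                                            1),
                        record_inputs = TRUE)
  summaries <- list(
    contrast_som = weight_contrast(rec$w_som, rec$groups_som),
    contrast_dnd = weight_contrast(rec$w_dnd, rec$groups_dnd))
  list(record = rec, summaries = summaries, config = cfg)
}

run_fig3_preset <- function(cfg) {
  set.seed(cfg$seed)
  p <- neuron_params(beta = cfg$beta, gamma = cfg$gamma)
  pp <- plasticity_params(alpha = cfg$alpha, eta = cfg$eta,
                          eta_inh = cfg$eta_inh, sigma_w = 0.001)
  if (cfg$preset == "fig3_separation") {
    inputs <- make_single_cell_inputs("fig3_separation", p)
    n_cells <- 2L
    duration <- cfg$duration * cfg$scale
  } else {
    phases <- cfg$phase_ms * cfg$scale
    inputs <- make_single_cell_inputs(
      "fig3_stability", p,
      phase_boundaries_ms = cumsum(phases)[1:2])
    n_cells <- 1L
    duration <- sum(phases)
  }
  rec <- simulate_cells(
    inputs, duration, dt = cfg$dt, n_cells = n_cells, p = p, pp = pp,
    inhibition = list(n_inh = cfg$n_inh, v_som = cfg$v_som),
    w_som_init = matrix(stats::runif(n_cells * inputs$n_som, 0,
                                     cfg$w_init_max), n_cells),
    w_dnd_init = matrix(stats::runif(n_cells * inputs$n_dnd, 0,
                                     cfg$w_init_max), n_cells))
  summaries <- list(
    contrast_dnd = apply(rec$w_dnd, 1, weight_contrast, rec$groups_dnd))
  if (cfg$preset == "fig3_stability") {
    # mean group-A dendritic weight at each snapshot
    gA <- rec$groups_dnd$A
    summaries$groupA_trajectory <- apply(
      rec$snapshots$w_dnd[, gA, , drop = FALSE], 3, mean)
    summaries$snapshot_time <- rec$snapshots$time
  }
  list(record = rec, summaries = summaries, config = cfg)
}

# assemble weights/pool/state for the track-family networks
build_track_network <- function(cfg) {
  n <- cfg$n_ca3
  w_som <- build_chain_weights(n, cfg$w_max * cfg$w_scale, cfg$w_width)
  if (cfg$preset == "fig5_grid") {
    n_ec <- cfg$n_grid + cfg$n_dist
    ec <- ec_spec_grid(cfg$n_grid, cfg$n_dist)
  } else {
    n_ec <- cfg$n_place + cfg$n_dist
    ec <- ec_spec_track(cfg$n_place, cfg$n_dist)
  }
  w_dnd <- build_ec_weights(n, n_ec, cfg$w_dnd_max, cfg$w_width,
                            cfg$familiarity)
  pool <- inhibitory_pool(n, cfg$n_inh, cfg$dnd_gain)
  v_som <- if (is.null(cfg$v_som)) {
    scale_v_som(n, cfg$n_inh, v_ref = cfg$v_som_ref)
  } else cfg$v_som
  p <- neuron_params(phi = cfg$phi, beta = cfg$beta, gamma = cfg$gamma)
  pp <- plasticity_params(alpha = cfg$alpha, eta = cfg$eta,
                          eta_inh = cfg$eta_inh)
  state <- init_network_state(w_som, w_dnd,
                              matrix(0, n, cfg$n_inh), v_som, pool,
                              p, pp)
  list(state = state, ec = ec, p = p, pp = pp)
}

run_track_preset <- function(cfg) {
  set.seed(cfg$seed)
  net <- build_track_network(cfg)
  sched <- make_track_schedule(cfg)
  flags <- network_flags(single_compartment = cfg$single_compartment)
  trig_pattern <- c(rep(1, 10), rep(-1, cfg$n_ca3 - 10))
  rec <- run_network(net$state, sched, trig_pattern, net$ec,
                     p = net$p, pp = net$pp,
                     flags = flags, dt = cfg$dt,
                     record_every = cfg$record_every,
                     seed = derive_seed(cfg$seed, 1))
  pf <- information_per_spike(rec$z, rec$pos, rec$moving, cfg$n_bin)
  list(record = rec, summaries = list(place_fields = pf,
                                      info_per_spike = pf$info_mean),
       config = cfg)
}

run_replay_preset <- function(cfg) {
  set.seed(cfg$seed)
  net <- build_track_network(cfg)
  flags <- network_flags()
  trig_pattern <- c(rep(1, 10), rep(-1, cfg$n_ca3 - 10))
  dt <- cfg$dt; sc <- cfg$scale

  # learning: rest + first run (0-25 s of the track trajectory)
  n1 <- round(2.5e4 * sc / dt)
  t1 <- (seq_len(n1) - 1) * dt
  mov1 <- as.integer(t1 >= 1e4 * sc)
  learn <- list(moving = mov1, pos = position_1d(t1 / sc),
                theta = theta_drive(t1, mov1, cfg$A_theta, cfg$f_theta),
                trig = trigger_schedule(n1, dt, mov1, rate_hz = 1,
                                        dur_immobile = 10,
                                        onsets_ms = 1e4 * sc,
                                        dur_onset = 100,
                                        amplitude = cfg$trig_amp))
  rec_learn <- run_network(net$state, learn, trig_pattern, net$ec,
                           p = net$p, pp = net$pp, flags = flags, dt = dt,
                           record_every = cfg$record_every,
                           seed = derive_seed(cfg$seed, 1))

  # pre-exposure probe (plasticity stays on, as during any run)
  probe1 <- make_probe_schedule(cfg)
  rec_pre <- run_network(rec_learn$state, probe1, trig_pattern, net$ec,
                         p = net$p, pp = net$pp, flags = flags, dt = dt,
                         record_every = cfg$record_every,
                         seed = derive_seed(cfg$seed, 2))
  pf_pre <- information_per_spike(rec_pre$z, rec_pre$pos, rec_pre$moving,
                                  cfg$n_bin)

  # spontaneous exposure, continuing from the learned state (not from the
  # probe, so both arms of the comparison start identically)
  state_exp <- rec_learn$state
  pp_exp <- net$pp
  if (cfg$remove_inhibition) {
    state_exp$v_dnd[] <- 0
    pp_exp$eta_inh <- 0
  }
  expo <- make_exposure_schedule(cfg, cfg$exposure_ms * sc)
  rec_exp <- run_network(state_exp, expo, trig_pattern, net$ec,
                         p = net$p, pp = pp_exp, flags = flags, dt = dt,
                         record_every = cfg$record_every,
                         seed = derive_seed(cfg$seed, 3))

  probe2 <- make_probe_schedule(cfg)
  rec_post <- run_network(rec_exp$state, probe2, trig_pattern, net$ec,
                          p = net$p, pp = pp_exp, flags = flags, dt = dt,
                          record_every = cfg$record_every,
                          seed = derive_seed(cfg$seed, 4))
  pf_post <- information_per_spike(rec_post$z, rec_post$pos,
                                   rec_post$moving, cfg$n_bin)

  list(record = list(learn = rec_learn, pre = rec_pre, exposure = rec_exp,
                     post = rec_post),
       summaries = list(info_pre = pf_pre$info_mean,
                        info_post = pf_post$info_mean,
                        retention = pf_post$info_mean / pf_pre$info_mean),
       config = cfg)
}

run_ymaze_preset <- function(cfg) {
  set.seed(cfg$seed)
  ng <- cfg$n_group
  n <- 3 * ng
  w_som <- build_ymaze_weights(ng, cfg$w_max, cfg$w_width)
  ec <- ec_spec_ymaze(cfg$n_ec_per_arm)
  w_dnd <- build_uniform_ec_weights(n, 3 * cfg$n_ec_per_arm, cfg$w_ec_max)
  pool <- inhibitory_pool(n, cfg$n_inh, cfg$dnd_gain)
  v_som <- if (is.null(cfg$v_som)) {
    scale_v_som(n, cfg$n_inh, v_ref = cfg$v_som_ref)
  } else cfg$v_som
  p <- neuron_params(phi = cfg$phi, beta = cfg$beta, gamma = cfg$gamma)
  pp <- plasticity_params(alpha = cfg$alpha, eta = cfg$eta,
                          eta_inh = cfg$eta_inh)
  state <- init_network_state(w_som, w_dnd, matrix(0, n, cfg$n_inh),
                              v_som, pool, p, pp)
  trig_pattern <- numeric(n)
  for (g in 0:2) trig_pattern[g * ng + seq_len(cfg$n_trig)] <- 1
  sched <- make_ymaze_schedule(cfg)
  rec <- run_network(state, sched, trig_pattern, ec, p = p, pp = pp,
                     flags = network_flags(), dt = cfg$dt,
                     record_every = cfg$record_every,
                     seed = derive_seed(cfg$seed, 1))
  pf <- information_per_spike(rec$z, rec$pos, rec$moving, cfg$n_bin,
                             arm = rec$arm, pos_range = c(0, 0.5))
  # which chain group responds most strongly on each arm (assessment
  # cycles = second round of visits when available)
  n_assess <- min(cfg$n_cycles, 3)
  first_assess <- cfg$n_cycles - n_assess
  arm_winner <- integer(3)
  groups <- lapply(0:2, function(g) g * ng + seq_len(ng))
  sc <- cfg$scale
  cyc_ms <- 1e4 * sc
  for (a in 1:3) {
    cycles <- which((seq_len(cfg$n_cycles) - 1) %% 3 == (a - 1)) - 1
    cycles <- cycles[cycles >= first_assess]
    sel <- rep(FALSE, length(rec$time))
    for (cc in cycles) {
      t0 <- 1e4 * sc + cc * cyc_ms
      sel <- sel | (rec$time >= t0 & rec$time < t0 + cyc_ms)
    }
    gm <- vapply(groups, function(g) mean(rec$z[g, sel]), numeric(1))
    arm_winner[a] <- which.max(gm)
  }
  list(record = rec,
       summaries = list(place_fields = pf,
                        info_per_spike = pf$info_mean,
                        arm_winner = arm_winner,
                        n_distinct = length(unique(arm_winner))),
       config = cfg)
}

run_branching_preset <- function(cfg) {
  set.seed(cfg$seed)
  w_som <- build_branching_weights(cfg$n_root, cfg$n_branch, cfg$w_max,
                                   cfg$w_prime_max, cfg$w_width)
  branches <- list(A = attr(w_som, "branch_a"), B = attr(w_som, "branch_b"))
  n <- cfg$n_root + 2 * cfg$n_branch
  ec <- ec_spec(mode = rep("place", cfg$n_ec),
                center = stats::runif(cfg$n_ec))
  w_dnd <- build_uniform_ec_weights(n, cfg$n_ec, cfg$w_ec_max)
  pool <- inhibitory_pool(n, cfg$n_inh, cfg$dnd_gain)
  v_som <- if (is.null(cfg$v_som)) {
    scale_v_som(n, cfg$n_inh, v_ref = cfg$v_som_ref)
  } else cfg$v_som
  p <- neuron_params(phi = cfg$phi, beta = cfg$beta, gamma = cfg$gamma)
  pp <- plasticity_params(alpha = cfg$alpha, eta = cfg$eta,
                          eta_inh = cfg$eta_inh)
  state <- init_network_state(w_som, w_dnd, matrix(0, n, cfg$n_inh),
                              v_som, pool, p, pp)
  trig_pattern <- c(rep(1, 10), rep(-1, n - 10))
  dt <- cfg$dt; sc <- cfg$scale
  flags <- network_flags()

  # pre-learning spontaneous window (plasticity off during immobility)
  pre_sched <- make_immobile_schedule(cfg, cfg$immobile1_ms * sc)
  rec_pre <- run_network(state, pre_sched, trig_pattern, ec, p = p,
                         pp = pp, flags = flags, dt = dt,
                         record_every = cfg$record_every,
                         seed = derive_seed(cfg$seed, 1))
  cnt_pre <- count_branch_sequences(rec_pre$z, rec_pre$time, branches,
                                    smooth_ms = cfg$count_smooth_ms)

  # first experience
  run_sched <- make_branching_run_schedule(cfg)
  rec_run <- run_network(rec_pre$state, run_sched, trig_pattern, ec,
                         p = p, pp = pp, flags = flags, dt = dt,
                         record_every = cfg$record_every,
                         seed = derive_seed(cfg$seed, 2))
  mean_a <- mean(rec_run$z[branches$A, ])
  mean_b <- mean(rec_run$z[branches$B, ])
  trained <- if (mean_a >= mean_b) "A" else "B"

  # post-learning spontaneous window
  post_sched <- make_immobile_schedule(cfg, cfg$immobile2_ms * sc)
  rec_post <- run_network(rec_run$state, post_sched, trig_pattern, ec,
                          p = p, pp = pp, flags = flags, dt = dt,
                          record_every = cfg$record_every,
                          seed = derive_seed(cfg$seed, 3))
  cnt_post <- count_branch_sequences(rec_post$z, rec_post$time, branches,
                                     smooth_ms = cfg$count_smooth_ms)

  out <- list(counts_pre = cnt_pre$counts, counts_post = cnt_post$counts,
              trained_branch = trained,
              frac_pre = unname(cnt_pre$counts[trained] /
                                  max(sum(cnt_pre$counts), 1)),
              frac_post = unname(cnt_post$counts[trained] /
                                   max(sum(cnt_post$counts), 1)))
  records <- list(pre = rec_pre, run = rec_run, post = rec_post)

  if (isTRUE(cfg$second_experience)) {
    # novel input sequence: sensory objects beyond the shared first 20%
    # of the track are re-shuffled (centers > 0.2 resampled)
    ec2 <- ec
    resample <- ec2$center > 0.2
    ec2$center[resample] <- stats::runif(sum(resample))
    run2 <- make_branching_run_schedule(cfg)
    rec_run2 <- run_network(rec_post$state, run2, trig_pattern, ec2,
                            p = p, pp = pp, flags = flags, dt = dt,
                            record_every = cfg$record_every,
                            seed = derive_seed(cfg$seed, 4))
    mean_a2 <- mean(rec_run2$z[branches$A, ])
    mean_b2 <- mean(rec_run2$z[branches$B, ])
    out$trained_branch2 <- if (mean_a2 >= mean_b2) "A" else "B"
    records$run2 <- rec_run2
  }
  list(record = records, summaries = out, config = cfg)
}

#' Run a preset experiment
#'
#' Executes the protocol described by an [experiment_config()]: builds the
#' network or cell, the input generators and behavior schedule, runs the
#' seeded simulation, and computes the preset's summary statistics
#' (weight contrasts, information per spike, sequence counts, ...).
#'
#' @param cfg An [experiment_config()] object.
#' @return A list with `record` (simulation record(s)), `summaries`, and
#'   the `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  switch(cfg$preset,
         fig1_correlated = ,
         fig1_uncorrelated = run_single_cell_preset(cfg),
         fig2_sweep = sweep_contrast(cfg),
         fig2c_altrule = sweep_contrast(cfg),
         fig3_separation = ,
         fig3_stability = run_fig3_preset(cfg),
         fig4_track = ,
         fig5_grid = run_track_preset(cfg),
         fig6_replay = run_replay_preset(cfg),
         fig7_ymaze = run_ymaze_preset(cfg),
         fig8_branching = run_branching_preset(cfg))
}

#' Sweep the single-cell learning rule over coupling parameters
#'
#' Runs the correlated-minority single-cell protocol on a grid of
#' `(alpha, beta)` values (combined rule) or `(alpha_som, alpha_dnd)`
#' values (calcium-BCM rule) and records the weight-contrast statistic of
#' both compartments at each grid point.  Positive contrasts mark
#' CCA-dominant learning, negative PCA-dominant learning.
#'
#' @param cfg An [experiment_config()] for preset `"fig2_sweep"` or
#'   `"fig2c_altrule"`.
#' @return A list with `grid` (a data frame of parameters and contrasts)
#'   and the `config`.
#' @export
sweep_contrast <- function(cfg) {
  alt <- cfg$preset == "fig2c_altrule"
  if (alt) {
    grid <- expand.grid(alpha_som = cfg$alphas_som,
                        alpha_dnd = cfg$alphas_dnd)
  } else {
    grid <- expand.grid(alpha = cfg$alphas, beta = cfg$betas)
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    set.seed(derive_seed(cfg$seed, i))
    p <- neuron_params(beta = if (alt) 0 else grid$beta[i], gamma = 1)
    pp <- plasticity_params(alpha = if (alt) 0 else grid$alpha[i],
                            eta = cfg$eta, eta_inh = 0,
                            sigma_w = cfg$sigma_w)
    inputs <- make_single_cell_inputs("fig1_correlated", p)
    rec <- simulate_cells(
      inputs, cfg$duration * cfg$scale, dt = cfg$dt, p = p, pp = pp,
      rule = if (alt) "calcium_bcm" else "combined",
      alpha_som = if (alt) grid$alpha_som[i] else 0.5,
      alpha_dnd = if (alt) grid$alpha_dnd[i] else 0.5,
      w_som_init = matrix(stats::runif(inputs$n_som, 0, 5), 1),
      w_dnd_init = matrix(stats::runif(inputs$n_dnd, 0, 5), 1))
    c(contrast_som = weight_contrast(rec$w_som, rec$groups_som),
      contrast_dnd = weight_contrast(rec$w_dnd, rec$groups_dnd),
      mean_weight = mean(c(rec$w_som, rec$w_dnd)))
  })
  grid <- cbind(grid, do.call(rbind, res))
  list(grid = grid, summaries = list(grid = grid), config = cfg)
}
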