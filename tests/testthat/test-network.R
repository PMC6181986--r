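make_tiny_net <- function(n = 12, n_ec = 8, n_inh = 3, v_dnd0 = 0.5,
                          sigma_w = 0) {
  w_som <- build_chain_weights(n, 6, 2, noise = FALSE)
  w_dnd <- build_ec_weights(n, n_ec, 3, 2)
  pool <- inhibitory_pool(n, n_inh)
  p <- neuron_params()
  pp <- plasticity_params(sigma_w = sigma_w)
  st <- init_network_state(w_som, w_dnd, matrix(v_dnd0, n, n_inh), 20,
                           pool, p, pp)
  list(st = st, p = p, pp = pp,
       ec = ec_spec_track(n_ec, 0, sigma_n = 0))
}

test_that("network state initializes at the zero-input fixed point", {
  set.seed(21)
  nt <- make_tiny_net()
  p <- nt$p
  f0 <- sigmoid_response(0, p$theta_f)
  expect_equal(nt$st$x, rep(f0, 12))
  expect_equal(nt$st$z, rep((1 + p$gamma * f0) * p$phi * f0, 12))
  expect_equal(nt$st$D_som, rep(1, 12))
  expect_equal(nt$st$theta_som, rep(0, 12))
})

test_that("reference stepper and compiled core produce identical dynamics", {
  set.seed(22)
  nt <- make_tiny_net()
  n <- 12; n_ec <- 8
  n_steps <- 150
  t <- seq_len(n_steps) - 1
  moving <- as.integer(t >= 40)
  pos <- pmin(t / 120, 1)
  theta <- theta_drive(t, moving)
  trig <- ifelse(t < 15, 10, 0)
  pat <- c(rep(1, 3), rep(-1, n - 3))
  flags <- network_flags()
  p <- nt$p; pp <- nt$pp
  st_r <- nt$st
  for (k in seq_len(n_steps)) {
    ecr <- p$phi_input * sigmoid_response(
      ec_input_current(nt$ec, pos[k], 0, moving[k] == 1, theta[k], 0, 0, 0),
      p$theta_f)
    ext <- theta[k] + trig[k] * pat
    U <- if (moving[k] == 1) 0.03 else 0.5
    if (k > 1 && moving[k] == 1 && moving[k - 1] == 0) st_r$F_som[] <- 0.03
    st_r <- step_network(st_r, ecr, ext, 1, p, pp,
                         stp_rec = stp_params(U_STF = U),
                         stp_ec = stp_params(), flags = flags)
  }
  sched <- list(moving = moving, pos = pos, theta = theta, trig = trig)
  rec <- run_network(nt$st, sched, pat, nt$ec, p = p, pp = pp,
                     sigma_n_ext = 0, flags = flags,
                     record_every = n_steps, seed = 7)
  for (nm in c("x", "y", "z", "I_som", "I_dnd", "D_som", "F_som", "D_dnd",
               "F_dnd", "w_som", "w_dnd", "v_dnd", "E_som", "E_dnd"))
    expect_equal(rec$state[[nm]], st_r[[nm]], tolerance = 1e-10,
                 info = nm)
})

test_that("engines also agree for the single-compartment control model", {
  set.seed(23)
  nt <- make_tiny_net()
  n <- 12
  p1 <- neuron_params(phi = 0.1)
  flags <- network_flags(single_compartment = TRUE)
  n_steps <- 100
  sched <- list(moving = rep(0L, n_steps), pos = numeric(n_steps),
                theta = numeric(n_steps), trig = c(rep(10, 10),
                                                   numeric(n_steps - 10)))
  pat <- c(rep(1, 3), rep(-1, n - 3))
  st_r <- nt$st
  for (k in seq_len(n_steps)) {
    ecr <- p1$phi_input * sigmoid_response(
      ec_input_current(nt$ec, 0, 0, FALSE, 0, 0, 0, 0), p1$theta_f)
    ext <- sched$trig[k] * pat
    st_r <- step_network(st_r, ecr, ext, 1, p1, nt$pp, flags = flags)
  }
  rec <- run_network(nt$st, sched, pat, nt$ec, p = p1, pp = nt$pp,
                     sigma_n_ext = 0, flags = flags,
                     record_every = n_steps, seed = 3)
  expect_equal(rec$state$x, st_r$x, tolerance = 1e-10)
  expect_equal(rec$state$w_dnd, st_r$w_dnd, tolerance = 1e-10)
  # output rate of the single-compartment model is phi * x with phi = 0.1
  expect_equal(rec$state$z, 0.1 * rec$state$x, tolerance = 1e-12)
})

test_that("quiescent network sits at the closed-form resting output", {
  set.seed(24)
  n <- 6
  pool <- inhibitory_pool(n, 2)
  p <- neuron_params(beta = 0)
  pp <- plasticity_params(sigma_w = 0, eta = 0)
  st <- init_network_state(matrix(0, n, n), matrix(0, n, 4),
                           matrix(0, n, 2), 0, pool, p, pp)
  ec <- ec_spec_track(4, 0, sigma_n = 0)
  f0 <- sigmoid_response(0, p$theta_f)
  for (k in 1:50)
    st <- step_network(st, rep(0, 4), rep(0, n), 1, p, pp,
                       flags = network_flags(plasticity_on = FALSE))
  # with zero weights the only drive is the (tiny) resting feedback
  expect_equal(st$x, rep(f0, n), tolerance = 1e-3)
  expect_equal(st$z, (1 + p$gamma * st$y) * p$phi * st$x, tolerance = 1e-12)
})

test_that("rates remain within the theoretical bound during driven activity", {
  set.seed(25)
  nt <- make_tiny_net(sigma_w = 0.001)
  n_steps <- 400
  t <- seq_len(n_steps) - 1
  moving <- as.integer(t >= 100)
  sched <- list(moving = moving, pos = pmin(t / 300, 1),
                theta = theta_drive(t, moving),
                trig = ifelse(t < 20, 10, 0))
  pat <- c(rep(1, 3), rep(-1, 9))
  rec <- run_network(nt$st, sched, pat, nt$ec, p = nt$p, pp = nt$pp,
                     record_every = 2L, seed = 11)
  p <- nt$p
  expect_true(all(rec$z >= 0))
  expect_true(all(rec$z <= (1 + p$gamma) * p$phi + 1e-12))
  # weights stay nonnegative with zero recurrent diagonal
  expect_true(all(rec$state$w_som >= 0))
  expect_equal(diag(rec$state$w_som), rep(0, 12))
})

test_that("identical seed gives bit-identical records, different seed differs", {
  set.seed(26)
  nt <- make_tiny_net(sigma_w = 0.001)
  n_steps <- 200
  sched <- list(moving = rep(0L, n_steps), pos = numeric(n_steps),
                theta = numeric(n_steps), trig = numeric(n_steps))
  pat <- rep(0, 12)
  ec <- ec_spec_track(8, 0)  # noisy EC inputs
  r1 <- run_network(nt$st, sched, pat, ec, p = nt$p, pp = nt$pp,
                    record_every = 5L, seed = 42)
  r2 <- run_network(nt$st, sched, pat, ec, p = nt$p, pp = nt$pp,
                    record_every = 5L, seed = 42)
  r3 <- run_network(nt$st, sched, pat, ec, p = nt$p, pp = nt$pp,
                    record_every = 5L, seed = 43)
  expect_identical(r1$z, r2$z)
  expect_identical(r1$state$w_som, r2$state$w_som)
  expect_false(identical(r1$z, r3$z))
})

test_that("triggered activity propagates along a chain during immobility", {
  # a strong chain supports a traveling preplay wave; halving the weights
  # abolishes full-chain propagation
  run_chain <- function(w_scale) {
    set.seed(27)
    n <- 60
    w_som <- build_chain_weights(n, 18 * w_scale, 5)
    pool <- inhibitory_pool(n, 10)
    p <- neuron_params()
    pp <- plasticity_params(sigma_w = 0)
    st <- init_network_state(w_som, matrix(0, n, 10), matrix(0, n, 10),
                             4, pool, p, pp)
    ec <- ec_spec_track(10, 0)
    n_steps <- 1200
    sched <- list(moving = rep(0L, n_steps), pos = numeric(n_steps),
                  theta = numeric(n_steps),
                  trig = c(rep(10, 100), numeric(n_steps - 100)))
    pat <- c(rep(1, 6), rep(-1, n - 6))
    rec <- run_network(st, sched, pat, ec, p = p, pp = pp,
                       flags = network_flags(plasticity_on = FALSE),
                       record_every = 5L, seed = 5)
    den <- colSums(rec$z)
    com <- colSums(rec$z * seq_len(n)) / pmax(den, 1e-9)
    max(com[den / n > 0.002], 0)
  }
  expect_gt(run_chain(1), 45)      # wave reaches the far end
  expect_lt(run_chain(0.5), 20)    # weak chain: propagation fails
})
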