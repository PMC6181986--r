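test_that("excitatory update terms have the right structure and limits", {
  pp <- plasticity_params(alpha = 0.5, eta = 1)
  # saturation factor (1 - x) kills the somatic term at x = 1
  tg <- two_compartment_update_terms(1, 0.7, 0.2, 0.2, 2, 3, pp)
  expect_equal(tg$som, 0)
  # alpha = 0 reduces exactly to the BCM bracket
  pp0 <- plasticity_params(alpha = 0, eta = 1)
  x <- 0.6; th <- 0.25; I <- 1.7
  tg <- two_compartment_update_terms(x, 0.9, th, 0.1, I, 0, pp0)
  expect_equal(tg$som, x * (x - th) * (1 - x) * I, tolerance = 1e-12)
  # vectorized over neurons -> outer-product matrix
  pp2 <- plasticity_params(alpha = 0.3, eta = 0.7)
  xv <- c(0.2, 0.6); yv <- c(0.5, 0.1)
  Iv <- c(1, 2, 3)
  tg <- two_compartment_update_terms(xv, yv, c(0.1, 0.2), c(0.1, 0.2),
                                     Iv, Iv, pp2)
  expect_equal(dim(tg$som), c(2, 3))
  g1 <- 0.7 * ((1 - 0.3) * xv[1] * (xv[1] - 0.1) + 0.3 * xv[1] * yv[1]) *
    (1 - xv[1])
  expect_equal(tg$som[1, 2], g1 * Iv[2], tolerance = 1e-12)
})

test_that("inhibitory update term matches direct arithmetic", {
  pp <- plasticity_params(alpha = 0.9, eta_inh = 1, theta_inh = 0.5)
  expect_equal(inhibitory_update_term(0.8, 0, 2, pp), 0)
  pp0 <- plasticity_params(alpha = 0, eta_inh = 1, theta_inh = 0.5)
  expect_equal(inhibitory_update_term(0.3, 0.5, 2, pp0), 0)
  # hand-evaluated value
  x <- 0.8; y <- 0.6; I <- 2
  expected <- ((1 - 0.9) * y * (y - 0.5) + 0.9 * x * y) * (1 - y) * I
  expect_equal(inhibitory_update_term(x, y, I, pp), expected,
               tolerance = 1e-12)
})

test_that("alternative calcium-BCM rule reduces to its limiting cases", {
  # alpha = 0 -> plain BCM on x
  a <- alt_calcium_bcm_terms(0.6, 0.8, 0.2, 0.2, 1.5, 1.5, 0, 0, eta = 1)
  expect_equal(a$z_som, 0.6)
  expect_equal(a$som, 0.6 * (0.6 - 0.2) * (1 - 0.6) * 1.5,
               tolerance = 1e-12)
  # alpha = 1 -> effective activity is the product x * y
  b <- alt_calcium_bcm_terms(0.6, 0.8, 0.2, 0.2, 1.5, 1.5, 1, 1, eta = 1)
  expect_equal(b$z_som, 0.6 * 0.8)
  expect_equal(b$z_dnd, 0.6 * 0.8)
})

test_that("moving thresholds track the squared running mean", {
  pp <- plasticity_params(c0 = 70, tau_mean = 1000)
  # zero activity -> thresholds collapse to zero
  st <- update_moving_thresholds(0.4, 0.4, 0, 0, 1, pp)
  for (k in 1:20000)
    st <- update_moving_thresholds(st$E_som, st$E_dnd, 0, 0, 1, pp)
  expect_equal(st$theta_som, 0, tolerance = 1e-6)
  # constant x = 0.1 -> theta -> 70 * 0.01 = 0.7
  st <- update_moving_thresholds(0, 0, 0.1, 0.1, 1, pp)
  for (k in 1:40000)
    st <- update_moving_thresholds(st$E_som, st$E_dnd, 0.1, 0.1, 1, pp)
  expect_equal(st$theta_som, 0.7, tolerance = 1e-6)
  # step response reaches 1 - 1/e of the asymptote after tau_mean
  E <- 0
  for (k in 1:1000) {
    st1 <- update_moving_thresholds(E, 0, 1, 0, 1, pp); E <- st1$E_som
  }
  expect_equal(E, 1 - exp(-1), tolerance = 2e-3)
  # invariant: theta = c0 * E^2 after every step (exact)
  set.seed(5)
  E_s <- 0; E_d <- 0
  for (k in 1:100) {
    st2 <- update_moving_thresholds(E_s, E_d, runif(1), runif(1), 1, pp)
    E_s <- st2$E_som; E_d <- st2$E_dnd
    expect_identical(st2$theta_som, pp$c0 * E_s^2)
  }
})

test_that("second-order weight dynamics decay, track targets, and clip", {
  # pure decay: eta = 0 target, sigma_w = 0, decay rate 1e-3
  pp <- plasticity_params(eta_decay = 1e-3, sigma_w = 0, tau_w = 1000)
  w <- 2; dw <- 0
  for (k in 1:1000) {
    up <- step_weight_dynamics(w, dw, 0, 1, pp, noise = FALSE)
    w <- up$w; dw <- up$dw
  }
  expect_equal(w, 2 * exp(-1), tolerance = 2e-3)
  # constant target: w' approaches target - decay * w (cascade steady state)
  pp2 <- plasticity_params(eta_decay = 0, sigma_w = 0, tau_w = 100)
  w <- 0; dw <- 0; tgt <- 0.002
  for (k in 1:3000) {
    up <- step_weight_dynamics(w, dw, tgt, 1, pp2, noise = FALSE)
    w <- up$w; dw <- up$dw
  }
  # after the dw variable converges to tgt, w grows linearly at rate tgt
  expect_equal(dw, tgt, tolerance = 1e-8)
  # negative proposals are clipped to exactly zero
  pp3 <- plasticity_params(sigma_w = 0)
  up <- step_weight_dynamics(matrix(0.001, 2, 2), matrix(-1, 2, 2),
                             matrix(-1, 2, 2), 1, pp3, noise = FALSE)
  expect_true(all(up$w == 0))
  # recurrent diagonal forced to zero
  up <- step_weight_dynamics(matrix(1, 3, 3), matrix(0, 3, 3),
                             matrix(1, 3, 3), 1, pp3, noise = FALSE,
                             zero_diag = TRUE)
  expect_equal(diag(up$w), rep(0, 3))
})

test_that("objective function matches a term-by-term duplicate", {
  expect_equal(objective_value(rep(0, 10), rep(0, 10), 0.5), 0)
  set.seed(9)
  x <- runif(500); y <- runif(500)
  expect_equal(objective_value(x, y, 1), mean(x * y), tolerance = 1e-12)
  # independent term-by-term evaluation
  alpha <- 0.37; c0 <- 70
  terms <- c(0.5 * sum(x^2) / 500, 0.5 * sum(y^2) / 500,
             -c0 * (sum(x) / 500)^3, -c0 * (sum(y) / 500)^3)
  L <- (1 - alpha) * sum(terms) + alpha * sum(x * y) / 500
  expect_equal(objective_value(x, y, alpha, c0), L, tolerance = 1e-12)
  expect_error(objective_value(numeric(0), numeric(0), 0.5), "empty")
  # frozen-threshold form agrees at the operating point
  th_x <- c0 * mean(x)^2; th_y <- c0 * mean(y)^2
  expect_equal(objective_value_frozen(x, y, alpha, th_x, th_y),
               objective_value(x, y, alpha, c0), tolerance = 1e-12)
})

test_that("update rule is the gradient of the frozen-threshold objective", {
  # three-synapse toy neuron, beta = 0, fixed inputs, no decay/noise:
  # the expected update term equals the finite-difference dL/dw.
  set.seed(21)
  n_t <- 4000
  I_som <- matrix(abs(sin(outer(seq_len(n_t) / 40, c(1, 2.3, 3.7)))) + 0.1,
                  n_t, 3)
  I_dnd <- matrix(abs(cos(outer(seq_len(n_t) / 55, c(1.4, 2.9, 0.6)))) + 0.1,
                  n_t, 3)
  w_som <- c(1.2, 0.4, 2.1); w_dnd <- c(0.7, 1.6, 0.3)
  alpha <- 0.5; theta_f <- 5
  traces <- function(ws, wd) {
    list(x = sigmoid_response(I_som %*% ws, theta_f),
         y = sigmoid_response(I_dnd %*% wd, theta_f))
  }
  tr <- traces(w_som, w_dnd)
  th_som <- 70 * mean(tr$x)^2; th_dnd <- 70 * mean(tr$y)^2
  pp <- plasticity_params(alpha = alpha, eta = 1)
  for (j in 1:3) {
    # time-averaged analytic update term for somatic synapse j
    upd <- mean(two_compartment_update_terms(tr$x, tr$y, th_som, th_dnd,
                                             1, 1, pp)$som * I_som[, j])
    eps <- 1e-6
    wp <- w_som; wp[j] <- wp[j] + eps
    wm <- w_som; wm[j] <- wm[j] - eps
    tp <- traces(wp, w_dnd); tm <- traces(wm, w_dnd)
    grad <- (objective_value_frozen(tp$x, tp$y, alpha, th_som, th_dnd) -
             objective_value_frozen(tm$x, tm$y, alpha, th_som, th_dnd)) /
      (2 * eps)
    expect_equal(upd, grad, tolerance = 1e-3 * max(abs(grad), 1e-8))
  }
})

test_that("calcium-BCM rule yields CCA-like learning only when both mixing weights are high", {
  cfg <- experiment_config("fig2c_altrule", seed = 1,
                           alphas_som = c(0.1, 0.9),
                           alphas_dnd = c(0.1, 0.9))
  g <- run_experiment(cfg)$grid
  hihi <- g$alpha_som == 0.9 & g$alpha_dnd == 0.9
  expect_gt(g$contrast_som[hihi], 0)
  expect_gt(g$contrast_dnd[hihi], 0)
  expect_true(all(g$contrast_som[!hihi] < 0))
  expect_true(all(g$contrast_dnd[!hihi] < 0))
})
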