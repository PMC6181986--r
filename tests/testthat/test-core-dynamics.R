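test_that("sigmoid response matches closed-form values and saturates", {
  expect_equal(sigmoid_response(5, theta_f = 5), 0.5)
  expect_equal(sigmoid_response(7, theta_f = 5), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(sigmoid_response(-1e3), 0, tolerance = 1e-12)
  expect_equal(sigmoid_response(1e3), 1, tolerance = 1e-12)
  # strictly increasing
  I <- seq(-10, 20, by = 0.5)
  expect_true(all(diff(sigmoid_response(I)) > 0))
  expect_error(sigmoid_response(NaN), "non-finite")
})

test_that("synaptic trace decays exponentially and has fixed point tau_L * u", {
  # free decay from I0 = 1 with tau_L = 10 reaches e^-1 after 10 ms
  I <- 1
  for (k in 1:1000) I <- step_synaptic_trace(I, 0, dt = 0.01, tau_L = 10)
  expect_equal(I, exp(-1), tolerance = 1e-3)
  # constant drive fixed point
  I <- 0
  for (k in 1:5000) I <- step_synaptic_trace(I, 0.04, dt = 1, tau_L = 10)
  expect_equal(I, 10 * 0.04, tolerance = 1e-8)
  # zero is a fixed point
  expect_identical(step_synaptic_trace(0, 0, 1), 0)
  expect_error(step_synaptic_trace(1, 0, dt = -1), "dt")
})

test_that("synaptic trace is linear in the drive", {
  set.seed(42)
  u1 <- runif(200, 0, 0.1); u2 <- runif(200, 0, 0.1)
  Ia <- Ib <- Iab <- 0
  for (k in 1:200) {
    Ia <- step_synaptic_trace(Ia, u1[k], 1)
    Ib <- step_synaptic_trace(Ib, u2[k], 1)
    Iab <- step_synaptic_trace(Iab, u1[k] + u2[k], 1)
  }
  expect_equal(Iab, Ia + Ib, tolerance = 1e-12)
})

test_that("short-term plasticity relaxes to rest and to the analytic fixed point", {
  p <- stp_params(tau_STD = 500, tau_STF = 200, U_STF = 0.5)
  # rest state under zero drive
  D <- 0.2; F <- 0.9
  for (k in 1:20000) {
    s <- step_stp(D, F, 0, 1, p); D <- s$D; F <- s$F
  }
  expect_equal(D, 1, tolerance = 1e-6)
  expect_equal(F, p$U_STF, tolerance = 1e-6)
  # constant-rate fixed point vs closed-form stationarity solution
  fp <- stp_fixed_point(0.08, p)
  D <- 1; F <- p$U_STF
  for (k in 1:60000) {
    s <- step_stp(D, F, 0.08, 1, p); D <- s$D; F <- s$F
  }
  expect_equal(D, fp$D, tolerance = 1e-6)
  expect_equal(F, fp$F, tolerance = 1e-6)
  # the closed form satisfies the stationarity equations exactly
  expect_equal((1 - fp$D) / p$tau_STD - 0.08 * fp$D * fp$F, 0,
               tolerance = 1e-15)
  expect_equal((p$U_STF - fp$F) / p$tau_STF +
                 p$U_STF * (1 - fp$F) * 0.08, 0, tolerance = 1e-15)
})

test_that("STP variables stay in their invariant boxes under random drive", {
  set.seed(7)
  p <- stp_params()
  n_src <- 20
  D <- rep(1, n_src); F <- rep(p$U_STF, n_src)
  ok <- TRUE
  for (k in 1:5000) {
    u <- runif(n_src, 0, 0.16)  # up to the maximal output rate
    s <- step_stp(D, F, u, 1, p); D <- s$D; F <- s$F
    ok <- ok && all(D >= 0, D <= 1, F >= p$U_STF - 1e-12, F <= 1)
  }
  expect_true(ok)
})

test_that("compartment activations follow the threshold-modulated sigmoid", {
  p <- neuron_params(beta = 0, theta_f = 5)
  a <- compartment_activations(0, 0, x_prev = 0, y_prev = 0, p = p)
  expect_equal(a$x, 1 / (1 + exp(5)), tolerance = 1e-12)
  expect_equal(a$y, 1 / (1 + exp(5)), tolerance = 1e-12)
  # total somatic drive at threshold -> 0.5
  a <- compartment_activations(5, 0, x_prev = 0, y_prev = 0, p = p)
  expect_equal(a$x, 0.5)
  # increasing y_prev with beta > 0 strictly increases x
  pb <- neuron_params(beta = 2)
  xs <- sapply(seq(0, 1, by = 0.1), function(yp)
    compartment_activations(1, 0, x_prev = 0, y_prev = yp, p = pb)$x)
  expect_true(all(diff(xs) > 0))
  expect_error(compartment_activations(c(0, 0), 0, x_prev = 0, y_prev = 0),
               "mismatch")
})

test_that("with beta = gamma = 0 the compartments are fully decoupled", {
  p <- neuron_params(beta = 0, gamma = 0)
  a <- compartment_activations(1.3, 0.2, x_prev = 0.9, y_prev = 0.1, p = p)
  b <- compartment_activations(1.3, 7.5, x_prev = 0.9, y_prev = 0.8, p = p)
  expect_identical(a$x, b$x)
  expect_identical(output_rate(a$x, 0.1, p), output_rate(a$x, 0.9, p))
})

test_that("output rate implements calcium-spike gain amplification", {
  p <- neuron_params(phi = 0.08, gamma = 1)
  expect_equal(output_rate(0.5, 0, p), 0.04)
  expect_equal(output_rate(0.5, 1, p), 0.08)  # doubles with full dendrite
  # bound (1 + gamma) * phi
  expect_true(all(output_rate(runif(100), runif(100), p) <=
                    (1 + p$gamma) * p$phi))
  p0 <- neuron_params(gamma = 0)
  expect_equal(output_rate(0.3, 0.9, p0), p0$phi * 0.3)
})

test_that("inhibitory pool is column-normalized and matches a loop oracle", {
  set.seed(11)
  pool <- inhibitory_pool(17, 5)
  expect_equal(colSums(pool$theta_som), rep(1 / 5, 17), tolerance = 1e-12)
  expect_equal(colSums(pool$theta_dnd), rep(1 / 5, 17), tolerance = 1e-12)
  # zero rates and zero traces -> zero output
  fb <- inhibitory_feedback(pool, numeric(17), 1)
  expect_equal(fb$I_sominh, rep(0, 5))
  # after some drive, outputs equal the explicit double-loop sum
  z <- runif(17, 0, 0.16)
  for (k in 1:50) fb <- inhibitory_feedback(fb$pool, z, 1)
  oracle <- numeric(5)
  for (i in 1:5)
    for (j in 1:17)
      oracle[i] <- oracle[i] + pool$theta_som[i, j] * fb$pool$I_pyr[j]
  expect_equal(fb$I_sominh, oracle, tolerance = 1e-12)
  # unnormalized pool is rejected
  bad <- pool; bad$theta_som <- bad$theta_som * 2
  expect_error(inhibitory_feedback(bad, z, 1), "normalized")
})
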