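test_that("OU process has the right deterministic limit and moments", {
  # sigma = 0: pure exponential decay
  s <- 1
  for (k in 1:10) s <- ou_step(s, 1, tau = 10, sigma = 0)
  expect_equal(s, exp(-1), tolerance = 1e-12)
  # stationary variance sigma^2 * tau / 2 and lag-tau autocorrelation 1/e
  set.seed(123)
  n <- 2e5
  s <- numeric(n); cur <- 0
  for (k in 1:n) {
    cur <- ou_step(cur, 1, tau = 10, sigma = 0.1)
    s[k] <- cur
  }
  expect_equal(var(s), 0.1^2 * 10 / 2, tolerance = 0.1)
  ac <- cor(s[-(1:10)], s[1:(n - 10)])
  expect_equal(ac, exp(-1), tolerance = 0.05)
  expect_error(ou_step(0, dt = -1), "dt")
})

test_that("1D track trajectory hits the printed waypoints and is continuous", {
  expect_equal(position_1d(16e3), 1)      # plateau of run 1
  expect_equal(position_1d(17.4e3), 1)
  expect_equal(position_1d(44e3), 0.8)    # first turn of run 3
  expect_equal(position_1d(47e3), 0.4)    # second turn of run 3
  expect_equal(position_1d(50e3), 1)
  expect_equal(position_1d(5e3), 0)       # immobile
  # continuity at every segment boundary
  brk <- c(10, 15, 17.5, 22.5, 25, 35, 37.5, 40, 44, 47) * 1000
  eps <- 1e-6
  expect_equal(position_1d(brk - eps), position_1d(brk + eps),
               tolerance = 1e-8)
  # bounds
  t <- seq(0, 50e3, by = 7)
  expect_true(all(position_1d(t) >= 0 & position_1d(t) <= 1))
})

test_that("Y-maze cycle is piecewise linear with the printed plateau", {
  t <- seq(0, 9999, by = 1)
  p <- position_ymaze_cycle(t)
  expect_true(all(p[t >= 5000 & t < 7500] == 0.5))
  expect_true(all(p[t < 2500] == 0))
  expect_equal(position_ymaze_cycle(2500 + 1250), 0.25)
  # continuity
  brk <- c(2500, 5000, 7500)
  expect_equal(position_ymaze_cycle(brk - 1e-6),
               position_ymaze_cycle(brk + 1e-6), tolerance = 1e-8)
})

test_that("EC drive assembles tuned, theta, baseline and noise terms", {
  spec <- ec_spec_track(n_place = 10, n_dist = 0)
  # place mode at the field center, no noise, theta at zero phase:
  # current = A_F - 0.5
  cur <- ec_input_current(spec, pos = spec$center[4], arm = 0,
                          moving = TRUE, theta_value = 0, noise = 0)
  expect_equal(cur[4], 5 - 0.5, tolerance = 1e-12)
  # immobility: noise only
  cur <- ec_input_current(spec, 0.5, 0, moving = FALSE, theta_value = 10,
                          noise = 0.3)
  expect_equal(cur, rep(0.3, 10))
  # distractor entries take the supplied source value during run
  spec2 <- ec_spec_track(n_place = 2, n_dist = 2)
  cur <- ec_input_current(spec2, 0.5, 0, TRUE, 0, noise = 0,
                          s_dist = 0.7)
  expect_equal(cur[3:4], rep(0.7 - 0.5, 2))
})

test_that("grid tuning has the closed-form extrema and period", {
  set.seed(2)
  spec <- ec_spec_grid(n_grid = 5, n_dist = 0)
  pos <- seq(0, 1, by = 1e-4)
  for (i in c(1, 3)) {
    tuned <- spec$A_grid *
      exp(spec$c_grid * cos(2 * pi * pos / spec$grid_period[i] -
                              spec$grid_phase[i]))
    expect_lte(max(tuned), 5 * exp(3) + 1e-6)
    expect_gte(min(tuned), 5 * exp(-3) - 1e-6)
    # periodicity in pos
    p0 <- spec$grid_period[i]
    t1 <- ec_tuned_input(spec, 0.1)[i]
    t2 <- ec_tuned_input(spec, 0.1 + p0)[i]
    expect_equal(t1, t2, tolerance = 1e-9)
  }
})

test_that("Y-maze EC neurons are silent off their arm", {
  set.seed(3)
  spec <- ec_spec_ymaze(n_per_arm = 4)
  tuned <- ec_tuned_input(spec, pos = 0.25, arm = 2L)
  expect_true(all(tuned[spec$center_arm != 2] == 0))
  expect_true(any(tuned[spec$center_arm == 2] > 0))
})

test_that("grid parameters are drawn from the printed uniform ranges", {
  set.seed(99)
  spec <- ec_spec_grid(n_grid = 10000, n_dist = 0)
  ph <- spec$grid_phase; pe <- spec$grid_period
  expect_true(all(ph >= 0 & ph <= 2 * pi))
  expect_true(all(pe >= 0.2 & pe <= 0.6))
  # uniformity (Kolmogorov-Smirnov)
  expect_gt(suppressWarnings(ks.test(ph / (2 * pi), "punif"))$p.value, 1e-4)
  expect_gt(suppressWarnings(ks.test((pe - 0.2) / 0.4, "punif"))$p.value,
            1e-4)
})

test_that("theta drive is a sine during run and zero during immobility", {
  expect_equal(theta_drive(1000 / 28, TRUE), 10 * sin(pi / 2),
               tolerance = 1e-9)  # quarter period of 7 Hz
  expect_equal(theta_drive(123, FALSE), 0)
})

test_that("trigger schedule respects durations, onsets and statistics", {
  set.seed(8)
  n <- 60000
  trig <- trigger_schedule(n, 1, moving = rep(FALSE, n), rate_hz = 1,
                           dur_immobile = 10, amplitude = 10)
  expect_true(all(trig %in% c(0, 10)))
  r <- rle(trig)
  # every activation lasts at least 10 ms (consecutive onsets can merge)
  expect_true(all(r$lengths[r$values == 10] >= 10))
  # Poisson onset count within 4 sigma of rate * time
  n_on <- sum(r$values == 10)
  expect_lt(abs(n_on - 60), 4 * sqrt(60) + 1)
  # forced onset: deterministic activation at the requested time
  trig2 <- trigger_schedule(1000, 1, moving = rep(TRUE, 1000), rate_hz = 1,
                            onsets_ms = 500, dur_onset = 100,
                            amplitude = 5)
  expect_true(all(trig2[501:600] == 5))
  expect_true(all(trig2[1:500] == 0))  # no Poisson triggers while moving
})

test_that("burst gate opens for 200 ms per onset at about 1 Hz", {
  set.seed(10)
  n <- 3e5
  g <- burst_schedule(n, 1, rate_hz = 1, dur_ms = 200)
  r <- rle(g)
  expect_true(all(r$lengths[r$values == 1L] >= 200))
  # number of onsets approximately Poisson with mean 300
  onsets <- sum(diff(c(0L, g)) == 1L)
  expect_lt(abs(onsets - 300), 4 * sqrt(300))
})

test_that("single-cell input generator builds the printed group structure", {
  set.seed(4)
  p <- neuron_params()
  gen <- make_single_cell_inputs("fig1_correlated", p)
  expect_equal(gen$n_som, 50)
  expect_equal(gen$groups_som$A, 1:10)
  # correlated condition: groups A and A' share a source; B and B' do not
  st <- gen$state
  nT <- 6e4
  mA <- mD <- mB <- mBp <- numeric(nT)
  for (k in 1:nT) {
    st <- gen$step(st, (k - 1), 1)
    mA[k] <- mean(st$I_input_som[1:10])
    mD[k] <- mean(st$I_input_dnd[1:10])
    mB[k] <- mean(st$I_input_som[11:50])
    mBp[k] <- mean(st$I_input_dnd[11:50])
  }
  expect_gt(cor(mA, mD), 0.5)
  expect_lt(abs(cor(mB, mBp)), 0.1)
  # all rates bounded by phi_input
  expect_true(all(st$u_som >= 0 & st$u_som <= p$phi_input))
  expect_error(make_single_cell_inputs("nope"), "arg")
})

test_that("uncorrelated condition decorrelates the minority groups", {
  set.seed(6)
  gen <- make_single_cell_inputs("fig1_uncorrelated")
  st <- gen$state
  nT <- 6e4
  mA <- mD <- numeric(nT)
  for (k in 1:nT) {
    st <- gen$step(st, (k - 1), 1)
    mA[k] <- mean(st$I_input_som[1:10])
    mD[k] <- mean(st$I_input_dnd[1:10])
  }
  expect_lt(abs(cor(mA, mD)), 0.1)
})
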