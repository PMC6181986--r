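test_that("information per spike has the exact closed-form limits", {
  # flat rate map -> zero information
  z <- matrix(0.01, 3, 1000)
  pos <- rep(seq(0.01, 0.99, length.out = 50), 20)
  pf <- information_per_spike(z, pos, rep(TRUE, 1000), n_bin = 50)
  expect_equal(unname(pf$info), rep(0, 3), tolerance = 1e-12)
  # firing in exactly 1 of 50 equiprobable bins -> log2(50) bits
  z1 <- matrix(0, 1, 1000)
  z1[1, pos < 0.02] <- 0.08
  pf1 <- information_per_spike(z1, pos, rep(TRUE, 1000), n_bin = 50)
  expect_equal(unname(pf1$info[1]), log2(50), tolerance = 1e-9)
  # occupancy sums to one
  expect_equal(sum(pf1$occupancy), 1)
})

test_that("information per spike is invariant to uniform rate rescaling", {
  set.seed(31)
  z <- matrix(runif(5 * 2000, 0, 0.1), 5, 2000)
  pos <- runif(2000)
  pf1 <- information_per_spike(z, pos, rep(TRUE, 2000), 20)
  pf2 <- information_per_spike(z * 7.3, pos, rep(TRUE, 2000), 20)
  expect_equal(pf1$info, pf2$info, tolerance = 1e-12)
})

test_that("rate filter and immobility removal are applied", {
  set.seed(32)
  pos <- runif(3000)
  z <- rbind(matrix(runif(2 * 3000, 0, 0.1), 2),  # > 1 Hz, included
             matrix(1e-5, 1, 3000))               # 0.01 Hz, excluded
  pf <- information_per_spike(z, pos, rep(TRUE, 3000), 20)
  expect_equal(pf$included, c(TRUE, TRUE, FALSE))
  expect_length(pf$info, 2)
  # a cell firing only while immobile is excluded entirely
  mov <- c(rep(FALSE, 1500), rep(TRUE, 1500))
  z2 <- rbind(c(rep(0.1, 1500), rep(0, 1500)))
  pf2 <- information_per_spike(z2, pos, mov, 20)
  expect_false(any(pf2$included))
  expect_true(is.na(pf2$info_mean))  # defined empty result, no error
})

test_that("Y-maze binning nests position bins within arms", {
  pos <- rep(seq(0.01, 0.49, length.out = 25), 6)
  arm <- rep(1:3, each = 50)
  z <- matrix(0, 1, 150)
  z[1, arm == 2] <- 0.08  # fires on arm 2 only, uniformly
  pf <- information_per_spike(z, pos, rep(TRUE, 150), n_bin = 25,
                              arm = arm, pos_range = c(0, 0.5))
  expect_equal(pf$n_bin, 75)
  expect_equal(unname(pf$info[1]), log2(3), tolerance = 1e-9)
})

test_that("weight contrast is the printed group difference", {
  w <- c(rep(1, 10), rep(0.125, 40))
  expect_equal(weight_contrast(w, list(A = 1:10, B = 11:50)), 5)
  expect_equal(weight_contrast(rep(1, 20), list(A = 1:10, B = 11:20)), 0)
  expect_error(weight_contrast(w, list(A = 1:10, B = 10:20)), "overlap")
})

test_that("sequence counter detects a synthetic traveling bump", {
  # hand-built record: a Gaussian bump moving through branch A, nothing in B
  n <- 120; n_t <- 1500; dt <- 5
  t <- seq_len(n_t) * dt
  z <- matrix(0, n, n_t)
  br_a <- 41:80; br_b <- 81:120
  center <- 41 + (t / t[n_t]) * 39   # traverses branch A over 7.5 s
  for (k in seq_len(n_t))
    z[, k] <- 0.1 * exp(-0.5 * ((seq_len(n) - center[k]) / 3)^2)
  cnt <- count_branch_sequences(z, t, list(A = br_a, B = br_b),
                                max_lag_ms = 10000)
  expect_equal(unname(cnt$counts["A"]), 1L)
  expect_equal(unname(cnt$counts["B"]), 0L)
  # subthreshold record -> all counts zero
  cnt0 <- count_branch_sequences(z * 1e-4, t, list(A = br_a, B = br_b))
  expect_equal(unname(cnt0$counts), c(0L, 0L))
  # determinism: same record, same counts
  cnt2 <- count_branch_sequences(z, t, list(A = br_a, B = br_b),
                                 max_lag_ms = 10000)
  expect_identical(cnt$counts, cnt2$counts)
})

test_that("two bumps yield two counted events", {
  n <- 60; dt <- 5
  br <- 21:60
  one_pass <- function(n_t, speed_ms) {
    t <- seq_len(n_t) * dt
    center <- 21 + pmin(t / speed_ms, 1) * 39
    sapply(seq_len(n_t), function(k)
      0.1 * exp(-0.5 * ((seq_len(n) - center[k]) / 3)^2))
  }
  gap <- matrix(0, n, 300)
  z <- cbind(one_pass(300, 1200), gap, one_pass(300, 1200))
  t_all <- seq_len(ncol(z)) * dt
  cnt <- count_branch_sequences(z, t_all, list(A = br))
  expect_equal(unname(cnt$counts["A"]), 2L)
})

test_that("reference PCA extracts majority groups, CCA the correlated pair", {
  # synthetic traces mimicking the single-cell input design: minority
  # groups (1:10) share a latent source across pathways; majority groups
  # (11:50) are driven by independent pathway-specific sources
  set.seed(33)
  n_t <- 4000
  s_shared <- rnorm(n_t); s_b <- rnorm(n_t); s_bp <- rnorm(n_t)
  noise <- function() matrix(rnorm(n_t * 50, sd = 0.3), n_t, 50)
  I_som <- cbind(matrix(s_shared, n_t, 10), matrix(s_b, n_t, 40)) + noise()
  I_dnd <- cbind(matrix(s_shared, n_t, 10), matrix(s_bp, n_t, 40)) + noise()
  ref <- reference_pca_cca(I_som, I_dnd, n_components = 2)
  # PCA eigenvectors orthonormal, canonical correlations in [0, 1]
  expect_equal(unname(crossprod(ref$pca_som$loadings)), diag(2),
               tolerance = 1e-8)
  expect_true(all(ref$cca$cor >= 0 & ref$cca$cor <= 1))
  # PC1 loading mass concentrated on the majority group
  pc1 <- ref$pca_som$loadings[, 1]
  expect_gt(sum(pc1[11:50]^2), 0.8)
  # top canonical pair concentrated on the correlated minority groups
  cx <- ref$cca$xcoef[, 1]; cy <- ref$cca$ycoef[, 1]
  expect_gt(sum(cx[1:10]^2) / sum(cx^2), 0.8)
  expect_gt(sum(cy[1:10]^2) / sum(cy^2), 0.8)
  expect_gt(ref$cca$cor[1], 0.5)
  expect_error(reference_pca_cca(I_som[1:10, ], I_dnd), "unequal")
})

test_that("compiled normal sampler has standard-normal moments and tails", {
  x <- dendseq:::zig_rnorm_cpp(5e5, 20260101)
  expect_lt(abs(mean(x)), 5e-3)
  expect_lt(abs(sd(x) - 1), 5e-3)
  expect_lt(abs(mean(x^3)), 2e-2)
  expect_lt(abs(mean(x^4) - 3), 1.5e-1)
  expect_lt(abs(mean(abs(x) > 1.959964) - 0.05), 2e-3)
  expect_lt(abs(mean(abs(x) > 3.290527) - 0.001), 4e-4)
  # determinism by seed
  expect_identical(dendseq:::zig_rnorm_cpp(10, 7),
                   dendseq:::zig_rnorm_cpp(10, 7))
})
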