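# Spatial-frequency link map, the simplified PCNN recurrence, and
# ignition-count coefficient selection.

test_that("spatial-frequency map matches the per-window loop oracle", {
  set.seed(101)
  band <- matrix(rnorm(64), 8, 8)
  expect_equal(spatial_frequency_map(band), oracle_sf_map(band),
               tolerance = 1e-12)
  expect_true(all(spatial_frequency_map(band) >= 0))
  expect_true(all(spatial_frequency_map(matrix(4, 6, 6)) == 0))
  expect_error(spatial_frequency_map(matrix(0, 2, 5)), "3x3")
})

test_that("parameter validation catches bad kernels and decays", {
  expect_error(pcnn_params(alpha_l = -1), "alpha_l")
  w <- matrix(1, 3, 3)
  expect_error(pcnn_params(w = w), "zero center")
  w2 <- matrix(c(0, 1, 0, 2, 0, 1, 0, 1, 0), 3, 3)
  expect_error(pcnn_params(w = w2), "symmetric")
})

test_that("zero stimulus never fires and runs are deterministic", {
  p <- pcnn_params(n_iter = 60)
  O <- run_pcnn(matrix(0, 10, 10), matrix(0, 10, 10), p)
  expect_true(all(O == 0))
  set.seed(111)
  stim <- matrix(runif(100), 10, 10)
  beta <- matrix(runif(100), 10, 10)
  expect_identical(run_pcnn(stim, beta, p), run_pcnn(stim, beta, p))
  expect_error(run_pcnn(stim, beta[1:5, ]), "shape")
  expect_error(run_pcnn(stim, -beta), "nonnegative")
})

test_that("uncoupled ignition counts match the scalar recurrence oracle", {
  p <- pcnn_params(n_iter = 100)
  stimuli <- seq(0.02, 1, length.out = 25)
  # all pixels decouple when beta = 0: run them in one grid
  stim <- matrix(stimuli, 5, 5)
  O <- run_pcnn(stim, matrix(0, 5, 5), p)
  for (i in seq_along(stimuli)) {
    expect_identical(as.integer(O[i]), as.integer(oracle_pcnn_scalar(stimuli[i], p)))
  }
  # monotone in the stimulus
  counts <- vapply(stimuli, oracle_pcnn_scalar, numeric(1), params = p)
  expect_true(all(diff(counts) >= 0))
  expect_identical(as.vector(O)[order(stimuli)], sort(as.vector(O)))
})

test_that("ignition counts stay within the iteration budget", {
  p <- pcnn_params(n_iter = 40)
  set.seed(121)
  O <- run_pcnn(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8), p)
  expect_true(all(O >= 0 & O <= 40))
})

test_that("coefficient selection follows the ignition comparison", {
  ha <- matrix(c(1, 2, 3, 4), 2, 2)
  hb <- matrix(c(5, 6, 7, 8), 2, 2)
  oa <- matrix(c(3, 1, 2, 2), 2, 2)
  ob <- matrix(c(1, 3, 2, 2), 2, 2)
  expect_equal(fuse_high_bands(ha, hb, oa, ob),
               matrix(c(1, 6, 5, 6), 2, 2))
  # equal counts average; identical bands pass through regardless of counts
  expect_equal(fuse_high_bands(ha, hb, oa, oa), (ha + hb) / 2)
  expect_equal(fuse_high_bands(ha, ha, oa, ob), ha)
  expect_error(fuse_high_bands(ha, hb[1, , drop = FALSE], oa, ob), "shape")
})

test_that("fused band is bounded by the inputs and swap-invariant", {
  set.seed(131)
  ha <- matrix(rnorm(256), 16, 16)
  hb <- matrix(rnorm(256), 16, 16)
  p <- pcnn_params(n_iter = 50)
  f1 <- shearfuse:::fuse_high_pair(ha, hb, p)
  f2 <- shearfuse:::fuse_high_pair(hb, ha, p)
  expect_identical(f1, f2)
  expect_true(all(f1 >= pmin(ha, hb) - 1e-12))
  expect_true(all(f1 <= pmax(ha, hb) + 1e-12))
})
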