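# Discrete shearlet system: tiling, round trips, covariance, oracles.

test_that("system geometry follows the dyadic shear layout", {
  sys <- shearlet_system(64, 64, 2)
  expect_equal(length(sys$windows), 4 + 8)
  expect_equal(as.integer(table(sys$bands$scale)), c(4L, 8L))
  for (W in sys$windows) expect_equal(dim(W), c(64L, 64L))
  expect_gt(min(sys$weight), 0)

  sys3 <- shearlet_system(64, 64, 3)
  expect_equal(length(sys3$windows), 4 + 8 + 16)
  # seam directions appear once per |k| = 2^j
  expect_equal(sum(sys3$bands$cone == "seam"), 2L * 3L)
})

test_that("invalid geometry is rejected", {
  expect_error(shearlet_system(63, 64, 1), "even")
  expect_error(shearlet_system(8, 8, 1), "even|16")
  expect_error(shearlet_system(64, 64, 0), "scales")
  expect_error(shearlet_system(64, 64, 5), "scales")
  sys <- shearlet_system(32, 32, 1)
  expect_error(shearlet_decompose(matrix(0, 16, 16), sys), "shape")
  expect_error(shearlet_decompose(matrix(NA_real_, 32, 32), sys), "finite")
})

test_that("directional windows match the loop-based evaluation", {
  sys <- shearlet_system(32, 32, 1)
  # interior h-cone window (j = 0, k = 0) away from the Nyquist line,
  # where symmetrization is the identity
  i_h <- which(sys$bands$cone == "h" & sys$bands$k == 0)
  pts <- cbind(c(5, 12, 20, 28, 17), c(9, 25, 3, 30, 17))
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, 1]; q <- pts[r, 2]
    expect_equal(sys$windows[[i_h]][p, q],
                 oracle_hwindow(32, 32, 1, 0, 0, p, q), tolerance = 1e-14)
  }
})

test_that("a decomposition coefficient equals the frequency-domain inner product", {
  set.seed(11)
  f <- matrix(rnorm(16 * 16), 16, 16)
  sys <- shearlet_system(16, 16, 1)
  co <- shearlet_decompose(f, sys)
  Fc <- oracle_dft2(f)
  samples <- list(c(0, 3, 7), c(1, 1, 1), c(2, 16, 16), c(3, 5, 12),
                  c(4, 9, 2), c(0, 12, 13), c(2, 4, 9))
  for (s in samples) {
    b <- s[1]; m1 <- s[2]; m2 <- s[3]
    W <- if (b == 0) sys$phi else sys$windows[[b]]
    ref <- oracle_shear_coeff(Fc, W, m1, m2)
    val <- if (b == 0) co$low[m1, m2] else co$high[[b]][m1, m2]
    expect_equal(val, Re(ref), tolerance = 1e-10)
    expect_lt(abs(Im(ref)), 1e-10)
  }
})

test_that("round trip reconstructs to floating-point precision", {
  set.seed(5)
  for (case in list(c(64, 64, 1), c(64, 64, 3), c(64, 128, 2), c(128, 128, 2))) {
    sys <- shearlet_system(case[1], case[2], case[3])
    f <- matrix(rnorm(case[1] * case[2]), case[1], case[2])
    g <- shearlet_reconstruct(shearlet_decompose(f, sys), sys)
    expect_lt(sqrt(sum((g - f)^2) / sum(f^2)), 1e-10)
  }
})

test_that("decompose commutes exactly with cyclic shifts", {
  set.seed(7)
  sys <- shearlet_system(64, 64, 2)
  f <- matrix(rnorm(64 * 64), 64, 64)
  c0 <- shearlet_decompose(f, sys)
  c1 <- shearlet_decompose(cyclic_shift(f, 13, 40), sys)
  expect_equal(c1$low, cyclic_shift(c0$low, 13, 40), tolerance = 1e-12)
  for (i in c(1, 5, 12)) {
    expect_equal(c1$high[[i]], cyclic_shift(c0$high[[i]], 13, 40),
                 tolerance = 1e-12)
  }
})

test_that("decompose is linear and zero maps to zero", {
  set.seed(9)
  sys <- shearlet_system(32, 32, 1)
  f <- matrix(rnorm(1024), 32, 32)
  g <- matrix(rnorm(1024), 32, 32)
  cz <- shearlet_decompose(matrix(0, 32, 32), sys)
  expect_true(all(cz$low == 0) && all(vapply(cz$high, function(b) all(b == 0),
                                             logical(1))))
  cf <- shearlet_decompose(f, sys)
  cg <- shearlet_decompose(g, sys)
  cc <- shearlet_decompose(2 * f - 3 * g, sys)
  expect_equal(cc$low, 2 * cf$low - 3 * cg$low, tolerance = 1e-12)
  expect_equal(cc$high[[3]], 2 * cf$high[[3]] - 3 * cg$high[[3]],
               tolerance = 1e-12)
})

test_that("reconstruct is linear and energy bookkeeping holds", {
  set.seed(13)
  sys <- shearlet_system(32, 32, 2)
  f <- matrix(rnorm(1024), 32, 32)
  g <- matrix(rnorm(1024), 32, 32)
  cf <- shearlet_decompose(f, sys)
  cg <- shearlet_decompose(g, sys)
  mix <- list(low = 2 * cf$low + 0.5 * cg$low,
              high = lapply(seq_along(cf$high), function(i)
                2 * cf$high[[i]] + 0.5 * cg$high[[i]]))
  expect_equal(shearlet_reconstruct(mix, sys),
               2 * f + 0.5 * g, tolerance = 1e-12)
  # weighted coefficient energy equals signal energy (frame bookkeeping)
  Fc <- shearfuse:::fftshift2(stats::fft(f))
  wen <- sum(Mod(Fc * sys$phi)^2 / sys$weight)
  for (W in sys$windows) wen <- wen + sum(Mod(Fc * W)^2 / sys$weight)
  expect_equal(wen / (32 * 32), sum(f^2), tolerance = 1e-8)
})

test_that("reconstruct validates stack consistency", {
  sys <- shearlet_system(32, 32, 1)
  co <- shearlet_decompose(matrix(rnorm(1024), 32, 32), sys)
  expect_error(shearlet_reconstruct(list(low = co$low, high = co$high[1:2]),
                                    sys), "band count")
  bad <- co
  bad$high[[1]] <- matrix(0, 16, 16)
  expect_error(shearlet_reconstruct(bad, sys), "shapes")
})
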