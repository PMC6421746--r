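# Patch extraction, OMP, K-SVD, the three-case fusion rule, and the
# overlap-averaged low-band rebuild.

test_that("patch extraction yields the sliding-window count and layout", {
  b <- matrix(rnorm(64), 8, 8)
  V <- extract_patches(b, 3)
  expect_equal(dim(V), c(9L, 100L))  # (8+3-1)^2 columns of length 3^2
  cV <- extract_patches(matrix(2.5, 10, 12), 5)
  expect_true(all(cV == 2.5))
  expect_equal(ncol(cV), (10 + 5 - 1) * (12 + 5 - 1))
  expect_error(extract_patches(b, 2), "patch side")
  expect_error(extract_patches(b, 9), "patch side")
})

test_that("extract then overlap-average reassemble is exact", {
  set.seed(21)
  for (geom in list(c(8, 8, 3), c(12, 10, 4), c(16, 16, 8), c(9, 14, 5))) {
    b <- matrix(rnorm(geom[1] * geom[2]), geom[1], geom[2])
    V <- extract_patches(b, geom[3])
    expect_lt(max(abs(reconstruct_low_band(V, geom[1], geom[2], geom[3]) - b)),
              1e-12)
  }
})

test_that("OMP reproduces single atoms and rejects mismatches", {
  set.seed(31)
  D <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  codes <- sparse_code(D[, 4, drop = FALSE], D, t0 = 3)
  expect_equal(drop(codes), c(0, 0, 0, 1, 0, 0), tolerance = 1e-12)
  expect_true(all(sparse_code(matrix(0, 6, 1), D, t0 = 3) == 0))
  expect_error(sparse_code(matrix(0, 5, 1), D), "column length")
})

test_that("OMP matches the step-by-step greedy oracle", {
  set.seed(41)
  for (rep in 1:25) {
    D <- matrix(rnorm(24), 4, 6)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    x <- matrix(rnorm(4), 4, 1)
    codes <- sparse_code(x, D, t0 = 2, tol_rel = 0)
    ref <- oracle_omp(D, drop(x), t0 = 2)
    expect_equal(sort(which(codes[, 1] != 0)), sort(ref$support))
    resid <- drop(x) - D %*% codes[, 1]
    expect_lt(max(abs(resid - ref$residual)), 1e-10)
  }
})

test_that("K-SVD decreases the objective and keeps atoms unit norm", {
  set.seed(51)
  X <- matrix(rnorm(16 * 300), 16, 300)
  d <- ksvd_train(X, n_atoms = 24, t0 = 4, iterations = 10, seed = 3)
  expect_true(all(diff(d$objective) <= 1e-9))
  expect_lt(max(abs(sqrt(colSums(d$D^2)) - 1)), 1e-12)
})

test_that("K-SVD recovers atoms of a one-sparse model", {
  set.seed(61)
  truth <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  idx <- sample(8, 400, replace = TRUE)
  X <- truth[, idx] * rep(runif(400, 0.5, 2), each = 8) +
    matrix(rnorm(8 * 400, 0, 0.01), 8, 400)
  d <- ksvd_train(X, n_atoms = 8, t0 = 1, iterations = 15, seed = 5)
  corr <- abs(crossprod(truth, d$D))
  expect_true(all(apply(corr, 1, max) >= 0.99))
})

test_that("K-SVD rejects degenerate input", {
  expect_error(ksvd_train(matrix(0, 4, 50), n_atoms = 8), "degenerate")
  expect_error(ksvd_train(matrix(rnorm(40), 4, 10), n_atoms = 16),
               "at least")
})

test_that("three-case fusion follows the rule enumeration oracle", {
  # spec'd worked example: dominant A, opposite signs with |a| > |b|, and a
  # zero product both keep A's element
  expect_equal(drop(fuse_sparse_codes(matrix(c(2, -1)), matrix(c(-1, 0)))),
               c(2, -1))
  # equal columns pass through
  a <- matrix(c(1, -2, 0.5))
  expect_equal(fuse_sparse_codes(a, a), a)
  set.seed(71)
  for (rep in 1:200) {
    a <- matrix(round(rnorm(6), 2), 6, 1)
    b <- matrix(round(rnorm(6), 2), 6, 1)
    if (rep %% 5 == 0) b <- a + 0  # force exact ties sometimes
    if (rep %% 7 == 0) b[2] <- 0
    expect_equal(drop(fuse_sparse_codes(a, b)), oracle_fuse_column(a, b))
    # swap symmetry
    expect_equal(fuse_sparse_codes(a, b), fuse_sparse_codes(b, a))
    # support containment in the union of input supports
    fused <- fuse_sparse_codes(a, b)
    expect_true(all(fused[a == 0 & b == 0] == 0))
  }
})

test_that("low-band rebuild is linear and exact for coded constants", {
  set.seed(81)
  D <- matrix(rnorm(16 * 32), 16, 32)
  D[, 1] <- 1  # a flat atom so constant patches are coded exactly
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  band <- matrix(0.7, 12, 12)
  V <- extract_patches(band, 4)
  codes <- sparse_code(V, D, t0 = 6, tol_rel = 1e-12)
  out <- reconstruct_low_band(D %*% codes, 12, 12, 4)
  expect_lt(max(abs(out - band)), 1e-6)
  out2 <- reconstruct_low_band(D %*% (3 * codes), 12, 12, 4)
  expect_equal(out2, 3 * out, tolerance = 1e-12)
  expect_error(reconstruct_low_band(D %*% codes, 14, 12, 4), "geometry")
})

test_that("full low-band fusion of identical smooth bands is near-lossless", {
  set.seed(91)
  t <- seq(0, 1, length.out = 32)
  band <- outer(sin(2 * pi * t), cos(2 * pi * t)) * 0.3 + 0.5
  fused <- shearfuse:::fuse_low_bands(band, band, n = 6, n_atoms = 64,
                                      t0 = 6, iterations = 8,
                                      train_size = 600, seed = 1)
  expect_gt(psnr(fused, band, peak = 1), 40)
})
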