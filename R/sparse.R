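# Sparse-representation fusion of the low-frequency band: sliding-window
# patches -> joint K-SVD dictionary -> OMP coding -> three-case L1 fusion
# rule -> overlap-averaged reconstruction.

patch_geometry <- function(M, N, n) {
  list(P = M + 2L * (n - 1L), Q = N + 2L * (n - 1L),
       WM = M + n - 1L, WN = N + n - 1L)
}

# Linear indices into the mirror-padded image for every (patch element,
# window) combination. Patch elements are vectorized column-major; windows
# are ordered column-major by their top-left corner in the padded image.
patch_index <- function(M, N, n) {
  g <- patch_geometry(M, N, n)
  off <- as.vector(outer(0:(n - 1L), (0:(n - 1L)) * g$P, "+"))
  base <- as.vector(outer(1:g$WM, (0:(g$WN - 1L)) * g$P, "+"))
  outer(off, base, "+")
}

#' Extract sliding-window patches from a band
#'
#' Slides an `n` by `n` window with step 1 over the band, mirror-padded by
#' `n - 1` pixels per side so that exactly `(M + n - 1) * (N + n - 1)`
#' windows exist. Each window becomes one column (vectorized column-major).
#'
#' @param band real `M` by `N` matrix.
#' @param n patch side in pixels, `3 <= n <= min(M, N)`.
#' @return `n^2` by `(M + n - 1) * (N + n - 1)` matrix of class
#'   `patch_matrix` with attributes `img_dim` and `patch_side`.
#' @export
extract_patches <- function(band, n) {
  stopifnot(is.matrix(band), all(is.finite(band)))
  M <- nrow(band); N <- ncol(band); n <- as.integer(n)
  if (n < 3L || n > min(M, N))
    stop("patch side n must satisfy 3 <= n <= min(M, N)")
  padded <- pad_mirror(band, n - 1L)
  V <- matrix(padded[patch_index(M, N, n)],
              nrow = n * n)
  attr(V, "img_dim") <- c(M, N)
  attr(V, "patch_side") <- n
  class(V) <- c("patch_matrix", "matrix", "array")
  V
}

#' Rebuild a band from patch columns by overlap averaging
#'
#' Inverse of the patch path: columns of `D %*% codes` are reshaped to
#' patches, accumulated at their sliding-window positions on the padded
#' grid, divided by the per-pixel coverage count, and the padding margin is
#' cropped. `reconstruct_low_band(extract_patches(x, n))` (identity codes)
#' returns `x` exactly.
#'
#' @param V `n^2` by `(M + n - 1) * (N + n - 1)` matrix of patch columns
#'   (typically `D %*% codes`).
#' @param M,N output band dimensions.
#' @param n patch side used for extraction.
#' @return real `M` by `N` matrix.
#' @export
reconstruct_low_band <- function(V, M, N, n) {
  n <- as.integer(n)
  g <- patch_geometry(M, N, n)
  if (nrow(V) != n * n || ncol(V) != g$WM * g$WN)
    stop("patch matrix geometry inconsistent with (M, N, n)")
  acc <- matrix(0, g$P, g$Q)
  cnt <- matrix(0, g$P, g$Q)
  base <- as.vector(outer(1:g$WM, (0:(g$WN - 1L)) * g$P, "+"))
  for (a in 0:(n - 1L)) for (b in 0:(n - 1L)) {
    idx <- base + a + b * g$P
    acc[idx] <- acc[idx] + V[a + b * n + 1L, ]
    cnt[idx] <- cnt[idx] + 1
  }
  out <- acc / cnt
  out[(n - 1L) + 1:M, (n - 1L) + 1:N, drop = FALSE]
}

#' Sparse-code patch columns with orthogonal matching pursuit
#'
#' Greedy per-column OMP: repeatedly select the atom with the largest
#' absolute correlation with the residual, least-squares refit on the
#' selected support, and stop after `t0` atoms or once the residual norm
#' falls below `tol_rel * ||column||`.
#'
#' @param V signal columns (`n^2` rows), e.g. a [extract_patches()] result.
#' @param D dictionary with unit-norm atoms, same row count as `V`.
#' @param t0 maximum number of nonzeros per column.
#' @param tol_rel relative residual tolerance (0 disables early stopping).
#' @return dense coefficient matrix, `ncol(D)` rows by `ncol(V)` columns;
#'   each column has at most `t0` nonzeros.
#' @export
sparse_code <- function(V, D, t0 = 8L, tol_rel = 1e-6) {
  if (nrow(V) != nrow(D)) stop("column length of V must match atom length")
  eps <- tol_rel * sqrt(colSums(V^2))
  omp_encode_cpp(D, V, as.integer(t0), eps)
}

#' Train an overcomplete dictionary with K-SVD
#'
#' Alternates OMP sparse coding of the training columns with sequential
#' rank-1 SVD updates of each atom (jointly re-fitting the coefficients of
#' the columns that use it). Atoms that no column uses are replaced by the
#' currently worst-represented training column. The dictionary is
#' initialized from a seeded random sample of the training columns; the
#' whole procedure is deterministic given `seed`.
#'
#' @param samples training columns (patches pooled from both sources).
#' @param n_atoms number of atoms; must exceed the signal dimension for an
#'   overcomplete dictionary and not exceed `ncol(samples)`.
#' @param t0 sparsity used during training.
#' @param iterations number of K-SVD sweeps.
#' @param seed RNG seed for initialization.
#' @param tol_rel OMP residual tolerance during training.
#' @return object of class `ksvd_dictionary`: list with the unit-norm atom
#'   matrix `D`, the per-iteration `objective` trace (squared Frobenius
#'   residual after each sweep), and the training metadata.
#' @export
ksvd_train <- function(samples, n_atoms = 256L, t0 = 8L, iterations = 20L,
                       seed = 0L, tol_rel = 1e-6) {
  X <- as.matrix(samples)
  K <- nrow(X)
  if (ncol(X) < n_atoms)
    stop("need at least n_atoms training columns")
  norms <- sqrt(colSums(X^2))
  if (max(norms) == 0) stop("degenerate all-zero training samples")
  usable <- which(norms > 1e-12 * max(norms))
  if (length(usable) < n_atoms)
    stop("too few non-degenerate training columns")

  D <- with_seed(seed, {
    init <- sample(usable, n_atoms)
    X[, init, drop = FALSE]
  })
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")

  objective <- numeric(iterations)
  A_prev <- NULL
  for (it in seq_len(iterations)) {
    A <- sparse_code(X, D, t0 = t0, tol_rel = tol_rel)
    if (!is.null(A_prev)) {
      # greedy OMP can occasionally code a column worse than the previous
      # sweep's coefficients (still valid for the current dictionary after
      # the rank-1 updates); keeping the better of the two per column makes
      # the objective monotone non-increasing by construction
      worse <- colSums((X - D %*% A)^2) > colSums((X - D %*% A_prev)^2)
      if (any(worse)) A[, worse] <- A_prev[, worse]
    }
    R <- X - D %*% A
    resnorm <- colSums(R^2)
    for (k in seq_len(n_atoms)) {
      users <- which(A[k, ] != 0)
      if (length(users) == 0L) {
        worst <- which.max(resnorm)
        cand <- X[, worst]
        if (sqrt(sum(cand^2)) > 0) {
          D[, k] <- cand / sqrt(sum(cand^2))
          resnorm[worst] <- 0  # avoid reusing the same column this sweep
        }
        next
      }
      E <- R[, users, drop = FALSE] + outer(D[, k], A[k, users])
      sv <- svd(E, nu = 1, nv = 1)
      D[, k] <- sv$u[, 1]
      A[k, users] <- sv$d[1] * sv$v[, 1]
      R[, users] <- E - outer(D[, k], A[k, users])
    }
    objective[it] <- sum((X - D %*% A)^2)
    A_prev <- A
  }
  structure(
    list(D = D, objective = objective,
         n_atoms = n_atoms, t0 = t0, iterations = iterations, seed = seed),
    class = "ksvd_dictionary"
  )
}

#' @export
print.ksvd_dictionary <- function(x, ...) {
  cat("K-SVD dictionary: ", nrow(x$D), " x ", ncol(x$D),
      " (", x$iterations, " iterations, final objective ",
      signif(utils::tail(x$objective, 1), 4), ")\n", sep = "")
  invisible(x)
}

# Elementwise "absorb the weaker opposite-sign element" rule shared by the
# dominant-column cases: keep a, but where the elements have strictly
# opposite signs and |a| < |b|, use a + b/2.
absorb_rule <- function(a, b) {
  mix <- (a * b < 0) & (abs(a) < abs(b))
  ifelse(mix, a + b / 2, a)
}

#' Fuse two sparse coefficient matrices with the three-case L1 rule
#'
#' Columns are compared by L1 norm. If column A dominates, its elements are
#' kept except where an element is strictly opposite in sign to and smaller
#' in magnitude than its counterpart, in which case half the counterpart is
#' absorbed (`a + b/2`); the mirrored rule applies when B dominates. On an
#' exact L1 tie the opposite-sign elementwise winner absorbs half the loser,
#' and all remaining elements (including products of exactly zero) are
#' averaged. The rule is symmetric: swapping A and B leaves the result
#' unchanged.
#'
#' @param alphaA,alphaB coefficient matrices of identical shape with
#'   aligned columns (as returned by [sparse_code()]).
#' @return fused coefficient matrix of the same shape.
#' @export
fuse_sparse_codes <- function(alphaA, alphaB) {
  if (!all(dim(alphaA) == dim(alphaB)))
    stop("coefficient matrices must have identical shape")
  l1A <- colSums(abs(alphaA))
  l1B <- colSums(abs(alphaB))
  out <- matrix(0, nrow(alphaA), ncol(alphaA))
  caseA <- l1A > l1B
  caseB <- l1A < l1B
  tie <- !(caseA | caseB)
  if (any(caseA))
    out[, caseA] <- absorb_rule(alphaA[, caseA, drop = FALSE],
                                alphaB[, caseA, drop = FALSE])
  if (any(caseB))
    out[, caseB] <- absorb_rule(alphaB[, caseB, drop = FALSE],
                                alphaA[, caseB, drop = FALSE])
  if (any(tie)) {
    a <- alphaA[, tie, drop = FALSE]
    b <- alphaB[, tie, drop = FALSE]
    opp <- a * b < 0
    f <- (a + b) / 2
    f[opp & abs(a) > abs(b)] <- (a + b / 2)[opp & abs(a) > abs(b)]
    f[opp & abs(a) < abs(b)] <- (b + a / 2)[opp & abs(a) < abs(b)]
    out[, tie] <- f
  }
  out
}

# Full low-frequency fusion path used by the pipeline: patches from both
# bands, joint dictionary on a seeded subset of the pooled columns, OMP
# coding of every column, three-case fusion, overlap-averaged rebuild.
#
# The training subset takes the same seeded window positions from both
# sources and is then put into a canonical column order, so the learned
# dictionary (and hence the whole fusion) is invariant under swapping the
# two inputs.
fuse_low_bands <- function(lowA, lowB, n = 8L, n_atoms = 256L, t0 = 8L,
                           iterations = 20L, tol_rel = 1e-6,
                           train_size = 5000L, seed = 0L) {
  M <- nrow(lowA); N <- ncol(lowA)
  VA <- extract_patches(lowA, n)
  VB <- extract_patches(lowB, n)
  half <- ceiling(train_size / 2)
  idx <- if (ncol(VA) > half)
    with_seed(seed + 1L, sample(ncol(VA), half)) else seq_len(ncol(VA))
  X <- cbind(VA[, idx, drop = FALSE], VB[, idx, drop = FALSE])
  X <- X[, order(colSums(X), colSums(X^2)), drop = FALSE]
  dict <- ksvd_train(X, n_atoms = n_atoms, t0 = t0,
                     iterations = iterations, seed = seed, tol_rel = tol_rel)
  aA <- sparse_code(VA, dict$D, t0 = t0, tol_rel = tol_rel)
  aB <- sparse_code(VB, dict$D, t0 = t0, tol_rel = tol_rel)
  aF <- fuse_sparse_codes(aA, aB)
  reconstruct_low_band(dict$D %*% aF, M, N, n)
}
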