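# Discrete, fully frequency-domain shearlet transform.
#
# The system is built on the centered frequency grid w_i = -n/2 ... n/2-1
# (per axis). Windows are Meyer-type: a radial wavelet window psi1 applied to
# the cone axis, an angular bump psi2 applied to the sheared frequency ratio,
# and a scaling window phi covering the centre. Because no band is
# subsampled, every subband has the source image's size and the transform
# commutes exactly with cyclic shifts.

# Meyer auxiliary polynomial: 0 below 0, 1 above 1, C^3 ramp in between,
# satisfying v(x) + v(1 - x) = 1.
meyer_v <- function(x) {
  y <- numeric(length(x))
  y[x >= 1] <- 1
  i <- x > 0 & x < 1
  xi <- x[i]
  y[i] <- xi^4 * (35 - 84 * xi + 70 * xi^2 - 20 * xi^3)
  y
}

# Radial bump b: sin ramp on |w| in [1,2], cos ramp on [2,4], 0 elsewhere.
meyer_b <- function(w) {
  aw <- abs(w)
  y <- numeric(length(w))
  i <- aw >= 1 & aw <= 2
  y[i] <- sin(pi / 2 * meyer_v(aw[i] - 1))
  i <- aw > 2 & aw <= 4
  y[i] <- cos(pi / 2 * meyer_v(aw[i] / 2 - 1))
  y
}

# Radial wavelet window, support |w| in [1/2, 4], identically 1 on [1, 2].
psi1_hat <- function(w) sqrt(meyer_b(2 * w)^2 + meyer_b(w)^2)

# Angular bump, support [-1, 1], psi2(0) = 1, with unit partition over
# integer shifts.
psi2_hat <- function(w) {
  y <- numeric(length(w))
  i <- w <= 0 & w >= -1
  y[i] <- sqrt(meyer_v(1 + w[i]))
  i <- w > 0 & w <= 1
  y[i] <- sqrt(meyer_v(1 - w[i]))
  y
}

# 1-D scaling window: 1 on |w| <= 1/2, cos ramp to 0 at |w| = 1.
phi1_hat <- function(w) {
  aw <- abs(w)
  y <- numeric(length(w))
  y[aw <= 0.5] <- 1
  i <- aw > 0.5 & aw < 1
  y[i] <- cos(pi / 2 * meyer_v(2 * aw[i] - 1))
  y
}

# Quadrant swap between FFT-native and centered (DC at [M/2+1, N/2+1])
# frequency layouts. For even dimensions the shift is an involution, so the
# same function serves both directions.
fftshift2 <- function(x) {
  M <- nrow(x); N <- ncol(x)
  x[c((M / 2 + 1):M, 1:(M / 2)), c((N / 2 + 1):N, 1:(N / 2))]
}
ifftshift2 <- fftshift2

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Build a discrete shearlet system
#'
#' Precomputes the frequency-domain windows (scaling window, directional
#' windows per scale and shear, merged seam windows on the cone diagonals)
#' and the per-frequency frame weight for an `M` by `N` image.
#'
#' At scale `j` (0-based, 0 = coarsest) the shear index runs over
#' `k = -2^j ... 2^j` per cone; the four windows straddling the cone seams
#' (`|k| = 2^j`) are merged pairwise across cones, leaving `4 * 2^j` distinct
#' directions per scale. The frequency axes are normalized per axis and
#' rescaled by `2 * 4^(scales - 1)` so that the finest scale's unit plateau
#' reaches the grid edge; the frame weight is then positive (numerically
#' equal to 1) at every frequency, making the transform invertible for any
#' admissible number of scales.
#'
#' @param M,N image dimensions in pixels; both must be even and >= 16.
#' @param scales number of scales `j0` with
#'   `1 <= j0 <= log2(min(M, N)) - 2`.
#' @return An object of class `shearlet_system`: a list with the scaling
#'   window `phi`, a list `windows` of directional windows, a data frame
#'   `bands` describing each window (`scale`, `cone`, `k`), the frame
#'   weight matrix `weight`, and the geometry (`M`, `N`, `scales`).
#' @examples
#' sys <- shearlet_system(64, 64, 2)
#' length(sys$windows)  # 4 + 8 directional windows
#' @export
shearlet_system <- function(M, N, scales = 3L) {
  M <- as.integer(M); N <- as.integer(N); scales <- as.integer(scales)
  if (M %% 2L != 0L || N %% 2L != 0L || M < 16L || N < 16L)
    stop("M and N must be even and >= 16")
  jmax <- floor(log2(min(M, N))) - 2
  if (scales < 1L || scales > jmax)
    stop("scales must satisfy 1 <= scales <= log2(min(M, N)) - 2 = ", jmax)

  cscale <- 2 * 4^(scales - 1)
  w1 <- (-(M / 2)):(M / 2 - 1)
  w2 <- (-(N / 2)):(N / 2 - 1)
  X1 <- matrix(w1 / (M / 2) * cscale, M, N)
  X2 <- matrix(w2 / (N / 2) * cscale, M, N, byrow = TRUE)

  # sheared frequency ratios, guarded at the axis (radial factor is 0 there)
  r21 <- X2 / X1; r21[X1 == 0] <- 0
  r12 <- X1 / X2; r12[X2 == 0] <- 0
  hcone <- abs(X2) <= abs(X1)

  dirwin_h <- function(j, k) {
    W <- matrix(psi1_hat(X1 / 4^j), M, N) *
      matrix(psi2_hat(2^j * r21 + k), M, N)
    W[X1 == 0] <- 0
    W
  }
  dirwin_v <- function(j, k) {
    W <- matrix(psi1_hat(X2 / 4^j), M, N) *
      matrix(psi2_hat(2^j * r12 + k), M, N)
    W[X2 == 0] <- 0
    W
  }

  # Symmetrize under frequency negation modulo the grid. Interior
  # frequencies are already symmetric; the Nyquist row/column (w = -n/2,
  # which has no positive partner) is averaged with its modular mirror so
  # every band spectrum is Hermitian and the coefficients exactly real.
  # Window values are nonnegative, so the frame weight stays positive.
  ri <- c(1L, M:2L); ci <- c(1L, N:2L)
  symmetrize <- function(W) (W + W[ri, ci]) / 2

  windows <- list()
  bands <- list()
  for (j in 0:(scales - 1)) {
    kk <- 2^j
    for (k in setdiff((-kk):kk, c(-kk, kk))) {
      windows[[length(windows) + 1L]] <- symmetrize(dirwin_h(j, k))
      bands[[length(bands) + 1L]] <- c(scale = j, cone = "h", k = k)
    }
    for (k in setdiff((-kk):kk, c(-kk, kk))) {
      windows[[length(windows) + 1L]] <- symmetrize(dirwin_v(j, k))
      bands[[length(bands) + 1L]] <- c(scale = j, cone = "v", k = k)
    }
    for (k in c(-kk, kk)) {
      W <- dirwin_h(j, k) * hcone + dirwin_v(j, k) * !hcone
      windows[[length(windows) + 1L]] <- symmetrize(W)
      bands[[length(bands) + 1L]] <- c(scale = j, cone = "seam", k = k)
    }
  }

  phi <- matrix(phi1_hat(pmax(abs(X1), abs(X2))), M, N)
  weight <- phi^2
  for (W in windows) weight <- weight + W^2
  if (min(weight) <= 0)
    stop("internal error: frame weight not positive")

  bands <- data.frame(
    scale = vapply(bands, function(b) as.integer(b["scale"]), integer(1)),
    cone = vapply(bands, function(b) b["cone"], character(1)),
    k = vapply(bands, function(b) as.integer(b["k"]), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(M = M, N = N, scales = scales, phi = phi, windows = windows,
         bands = bands, weight = weight),
    class = "shearlet_system"
  )
}

#' @export
print.shearlet_system <- function(x, ...) {
  cat("Shearlet system: ", x$M, "x", x$N, ", ", x$scales,
      " scale(s), ", length(x$windows), " directional bands\n", sep = "")
  invisible(x)
}

#' Shearlet decomposition of an image
#'
#' Splits `image` into one low-frequency band (scaling window) and
#' `sum(4 * 2^j)` directional high-frequency bands, each the size of the
#' source image. Every band is the inverse FFT of the image spectrum
#' multiplied by the corresponding (real, symmetric) frequency window, so
#' the transform is linear and exactly covariant under cyclic shifts.
#'
#' Bands are ordered scale-ascending; within a scale: horizontal-cone shear
#' indices ascending, vertical-cone indices ascending, then the two merged
#' seam directions (`k = -2^j`, `k = +2^j`). The ordering is recorded in
#' `system$bands`.
#'
#' @param image real `M` by `N` matrix matching the system's grid.
#' @param system a [shearlet_system()].
#' @return An object of class `shear_coeffs`: list with elements `low`
#'   (matrix), `high` (list of matrices), and `system` geometry metadata.
#' @export
shearlet_decompose <- function(image, system) {
  stopifnot(inherits(system, "shearlet_system"))
  if (!is.matrix(image) || nrow(image) != system$M || ncol(image) != system$N)
    stop("image shape does not match the shearlet system grid")
  if (!all(is.finite(image))) stop("image must be finite")
  Fc <- fftshift2(stats::fft(image))
  to_band <- function(W) {
    z <- ifft2(ifftshift2(Fc * W))
    res <- max(abs(Im(z)))
    if (res > 1e-10 * max(1, max(abs(Re(z)))))
      stop("imaginary residue exceeds tolerance; non-symmetric window?")
    Re(z)
  }
  structure(
    list(low = to_band(system$phi),
         high = lapply(system$windows, to_band),
         M = system$M, N = system$N, scales = system$scales,
         bands = system$bands),
    class = "shear_coeffs"
  )
}

#' Inverse shearlet transform
#'
#' Frame reconstruction: each band's spectrum is multiplied by its window,
#' the results are summed and divided per-frequency by the frame weight,
#' and the inverse FFT returns the image. Round trips through
#' [shearlet_decompose()] are exact to floating-point precision.
#'
#' @param coeffs a `shear_coeffs` object (or anything with the same shape).
#' @param system the [shearlet_system()] used to produce `coeffs`.
#' @return real `M` by `N` matrix.
#' @export
shearlet_reconstruct <- function(coeffs, system) {
  stopifnot(inherits(system, "shearlet_system"))
  if (length(coeffs$high) != length(system$windows))
    stop("band count does not match the shearlet system")
  ok <- function(b) is.matrix(b) && nrow(b) == system$M && ncol(b) == system$N
  if (!ok(coeffs$low) || !all(vapply(coeffs$high, ok, logical(1))))
    stop("band shapes do not match the shearlet system")
  acc <- fftshift2(stats::fft(coeffs$low)) * system$phi
  for (i in seq_along(system$windows))
    acc <- acc + fftshift2(stats::fft(coeffs$high[[i]])) * system$windows[[i]]
  Re(ifft2(ifftshift2(acc / system$weight)))
}
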