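# Simplified pulse-coupled neural network for high-frequency band fusion.
# One neuron per pixel; the feedback input is the (normalized) coefficient
# magnitude, the link strength is the local spatial-frequency map, and the
# per-pixel ignition counts decide which source's coefficient is kept.

#' PCNN parameters
#'
#' Constants of the simplified PCNN recurrence
#' \deqn{L_n = e^{-\alpha_L} L_{n-1} + V_L (W * Y_{n-1}), \quad
#'       U_n = F (1 + \beta L_n), \quad
#'       \theta_n = e^{-\alpha_\theta} \theta_{n-1} + V_\theta Y_{n-1},}
#' with `Y_n = 1` where `U_n > theta_n`. Defaults are the values commonly
#' used in PCNN fusion work: inverse-distance 3x3 link kernel, slow link
#' decay, a large threshold jump after each firing, and 200 iterations.
#'
#' @param alpha_l link decay per iteration (>= 0).
#' @param v_l link amplification (>= 0).
#' @param alpha_theta threshold decay per iteration (>= 0).
#' @param v_theta threshold amplification after a firing (>= 0).
#' @param w 3x3 nonnegative, symmetric link kernel with zero center.
#' @param n_iter number of iterations (>= 1).
#' @return list of class `pcnn_params`.
#' @export
pcnn_params <- function(alpha_l = 0.06931, v_l = 1.0,
                        alpha_theta = 0.2, v_theta = 20,
                        w = matrix(c(0.707, 1, 0.707,
                                     1, 0, 1,
                                     0.707, 1, 0.707), 3, 3),
                        n_iter = 200L) {
  stopifnot(alpha_l >= 0, v_l >= 0, alpha_theta >= 0, v_theta >= 0,
            n_iter >= 1)
  if (!is.matrix(w) || any(dim(w) != 3L) || any(w < 0) ||
      w[2, 2] != 0 || !isTRUE(all.equal(w, t(w))))
    stop("w must be a symmetric nonnegative 3x3 kernel with zero center")
  structure(list(alpha_l = alpha_l, v_l = v_l, alpha_theta = alpha_theta,
                 v_theta = v_theta, w = w, n_iter = as.integer(n_iter)),
            class = "pcnn_params")
}

# 3x3 weighted neighbourhood sum with mirror boundary.
conv3_mirror <- function(x, w) {
  M <- nrow(x); N <- ncol(x)
  p <- pad_mirror(x, 1L)
  out <- matrix(0, M, N)
  for (a in -1:1) for (b in -1:1) {
    wt <- w[a + 2, b + 2]
    if (wt != 0) out <- out + wt * p[(2 + a):(M + 1 + a), (2 + b):(N + 1 + b)]
  }
  out
}

#' Local spatial-frequency map
#'
#' At every pixel, the row and column frequencies (root mean squared
#' horizontal/vertical first differences) are evaluated over the pixel's
#' 3x3 neighbourhood (mirror-padded at the borders, six differences each,
#' divided by the nine window pixels), and combined as
#' `SF = sqrt(RF^2 + CF^2)`.
#'
#' @param band real matrix, at least 3x3.
#' @return nonnegative matrix of the same shape.
#' @export
spatial_frequency_map <- function(band) {
  stopifnot(is.matrix(band), all(is.finite(band)))
  M <- nrow(band); N <- ncol(band)
  if (M < 3 || N < 3) stop("band must be at least 3x3")
  p <- pad_mirror(band, 1L)
  dh <- (p[, -1, drop = FALSE] - p[, -ncol(p), drop = FALSE])^2  # (M+2) x (N+1)
  dv <- (p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2  # (M+1) x (N+2)
  rf2 <- matrix(0, M, N)
  cf2 <- matrix(0, M, N)
  # window centered at (i, j) spans padded rows i..i+2, cols j..j+2;
  # dh column c holds the difference of padded columns c+1 and c, so the
  # six in-window horizontal differences sit at dh columns j and j+1
  for (a in 0:2) for (b in 0:1) {
    rf2 <- rf2 + dh[a + 1:M, b + 1:N, drop = FALSE]
    cf2 <- cf2 + dv[b + 1:M, a + 1:N, drop = FALSE]
  }
  sqrt(rf2 / 9 + cf2 / 9)
}

#' Run the simplified PCNN and return the ignition-count map
#'
#' Iterates the recurrence of [pcnn_params()] from the off state
#' (`L = U = theta = Y = O = 0`). Each iteration: the link field decays and
#' picks up the 3x3 neighbourhood (mirror boundary) of last iteration's
#' firings; internal activity is `stimulus * (1 + beta * L)`; neurons fire
#' where activity exceeds the threshold; the threshold decays and jumps by
#' `v_theta` where a neuron fired. The returned map counts each pixel's
#' firings over all iterations. Fully deterministic.
#'
#' @param stimulus nonnegative matrix, typically normalized to \[0, 1\].
#' @param beta nonnegative link-strength matrix of the same shape (the
#'   spatial-frequency map of the band in the fusion pipeline).
#' @param params a [pcnn_params()] object.
#' @return integer-valued matrix of ignition counts in
#'   `0 ... params$n_iter`.
#' @export
run_pcnn <- function(stimulus, beta, params = pcnn_params()) {
  stopifnot(inherits(params, "pcnn_params"))
  if (!is.matrix(stimulus) || !is.matrix(beta) ||
      !all(dim(stimulus) == dim(beta)))
    stop("stimulus and beta must be matrices of identical shape")
  if (!all(is.finite(stimulus)) || !all(is.finite(beta)))
    stop("non-finite stimulus or beta")
  if (any(beta < 0)) stop("beta must be nonnegative")
  M <- nrow(stimulus); N <- ncol(stimulus)
  L <- matrix(0, M, N)
  theta <- matrix(0, M, N)
  Y <- matrix(0, M, N)
  O <- matrix(0L, M, N)
  dL <- exp(-params$alpha_l)
  dT <- exp(-params$alpha_theta)
  any_fired <- FALSE
  for (iter in seq_len(params$n_iter)) {
    WY <- if (any_fired) conv3_mirror(Y, params$w) else matrix(0, M, N)
    L <- dL * L + params$v_l * WY
    U <- stimulus * (1 + beta * L)
    theta <- dT * theta + params$v_theta * Y
    Y <- (U > theta) * 1
    O <- O + as.integer(Y)
    if (any(Y > 0)) any_fired <- TRUE
  }
  O
}

#' Select high-frequency coefficients by ignition counts
#'
#' Per pixel: the coefficient of the source whose neuron fired more often
#' wins; exact ties average the two coefficients.
#'
#' @param ha,hb corresponding high-frequency bands of sources A and B.
#' @param oa,ob their ignition-count maps from [run_pcnn()].
#' @return fused band of the same shape.
#' @export
fuse_high_bands <- function(ha, hb, oa, ob) {
  if (!all(dim(ha) == dim(hb)) || !all(dim(ha) == dim(oa)) ||
      !all(dim(ha) == dim(ob)))
    stop("all four arrays must share one shape")
  out <- (ha + hb) / 2
  out[oa > ob] <- ha[oa > ob]
  out[oa < ob] <- hb[oa < ob]
  out
}

# Normalize a matrix to [0, 1] by its own max (zero map stays zero).
normalize01 <- function(x) {
  m <- max(abs(x))
  if (m == 0) x else abs(x) / m
}

# Full high-frequency fusion of one pair of corresponding subbands.
# Stimuli (coefficient magnitudes) and link strengths (spatial-frequency
# maps) are normalized jointly over the band PAIR, so the ignition counts
# of the two networks are directly comparable and the genuinely stronger
# coefficient wins.
fuse_high_pair <- function(ha, hb, params = pcnn_params()) {
  m <- max(abs(ha), abs(hb))
  if (m == 0) m <- 1
  sa <- spatial_frequency_map(ha)
  sb <- spatial_frequency_map(hb)
  ms <- max(sa, sb)
  if (ms == 0) ms <- 1
  oa <- run_pcnn(abs(ha) / m, sa / ms, params)
  ob <- run_pcnn(abs(hb) / m, sb / ms, params)
  fuse_high_bands(ha, hb, oa, ob)
}
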