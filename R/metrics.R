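# Fusion quality indicators: spatial frequency (SF), average gradient (AG),
# mutual information (MI), and the Xydeas-Petrovic edge-preservation index
# QAB/F. The source work names these indicators without printing formulas;
# the definitions below are the standard literature conventions and are
# documented as such.

#' Global spatial frequency of an image
#'
#' `SF = sqrt(RF^2 + CF^2)` where RF (CF) is the root mean square of the
#' horizontal (vertical) first differences over the whole image, each sum
#' divided by the full pixel count `M * N`.
#'
#' @param image real matrix, at least 2x2.
#' @return nonnegative scalar.
#' @export
spatial_frequency <- function(image) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  M <- nrow(image); N <- ncol(image)
  if (M < 2 || N < 2) stop("image must be at least 2x2")
  rf2 <- sum((image[, -1, drop = FALSE] - image[, -N, drop = FALSE])^2) / (M * N)
  cf2 <- sum((image[-1, , drop = FALSE] - image[-M, , drop = FALSE])^2) / (M * N)
  sqrt(rf2 + cf2)
}

#' Average gradient of an image
#'
#' Mean over the `(M-1) x (N-1)` interior of
#' `sqrt((dx^2 + dy^2) / 2)` with forward differences; a sharpness
#' indicator, invariant to constant offsets.
#'
#' @param image real matrix, at least 2x2.
#' @return nonnegative scalar.
#' @export
average_gradient <- function(image) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  M <- nrow(image); N <- ncol(image)
  if (M < 2 || N < 2) stop("image must be at least 2x2")
  dx <- image[-M, -N, drop = FALSE] - image[-M, -1, drop = FALSE]
  dy <- image[-M, -N, drop = FALSE] - image[-1, -N, drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

# Quantize an image to the 8-bit bins used for histogram entropies: linear
# min-max rescale to 0..255 (constant images map to bin 0), then round.
quantize256 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) x <- (x - r[1]) / (r[2] - r[1]) * 255
  else x <- x * 0
  as.integer(round(x))
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# I(X;Y) in bits from 256-bin joint histogram of pre-quantized images.
mi_pair <- function(qx, qy) {
  joint <- tabulate(qx * 256L + qy + 1L, nbins = 256L * 256L) / length(qx)
  px <- tabulate(qx + 1L, nbins = 256L) / length(qx)
  py <- tabulate(qy + 1L, nbins = 256L) / length(qy)
  entropy_bits(px) + entropy_bits(py) - entropy_bits(joint)
}

#' Mutual information between a fused image and its two sources
#'
#' Fusion convention `MI = I(F;A) + I(F;B)` in bits, from 256-bin joint
#' histograms after each image is min-max rescaled to \[0, 255\] and
#' rounded. For `F = A = B` this equals twice the marginal entropy of A.
#'
#' @param fused,src_a,src_b real matrices of identical shape.
#' @return nonnegative scalar (bits).
#' @export
mutual_information <- function(fused, src_a, src_b) {
  if (!all(dim(fused) == dim(src_a)) || !all(dim(fused) == dim(src_b)))
    stop("images must share one shape")
  qf <- quantize256(fused)
  mi_pair(qf, quantize256(src_a)) + mi_pair(qf, quantize256(src_b))
}

# Sobel gradients with mirror boundary; returns strength g and orientation
# alpha = atan(gy / gx) in (-pi/2, pi/2] (0 where both gradients vanish).
sobel_edges <- function(x) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # column gradient
  gx <- conv3_mirror(x, kx)
  gy <- conv3_mirror(x, t(kx))
  g <- sqrt(gx^2 + gy^2)
  alpha <- atan(gy / gx)
  alpha[!is.finite(alpha)] <- 0
  list(g = g, alpha = alpha)
}

sigmoid_q <- function(x, gamma, kappa, sigma) gamma / (1 + exp(kappa * (x - sigma)))

# Per-pixel edge preservation of source s in fused f (both sobel_edges
# lists), normalized so perfect preservation scores 1.
edge_preservation <- function(es, ef, const) {
  G <- matrix(1, nrow(es$g), ncol(es$g))
  hi <- es$g > ef$g
  lo <- es$g < ef$g
  G[hi] <- (ef$g / es$g)[hi]
  G[lo] <- (es$g / ef$g)[lo]
  G[es$g == 0 & ef$g == 0] <- 0
  A <- 1 - abs(es$alpha - ef$alpha) / (pi / 2)
  qg <- sigmoid_q(G, const$gamma_g, const$kappa_g, const$sigma_g)
  qa <- sigmoid_q(A, const$gamma_a, const$kappa_a, const$sigma_a)
  ceiling_q <- sigmoid_q(1, const$gamma_g, const$kappa_g, const$sigma_g) *
    sigmoid_q(1, const$gamma_a, const$kappa_a, const$sigma_a)
  qg * qa / ceiling_q
}

#' Edge information transfer factor QAB/F
#'
#' Xydeas-Petrovic construction: Sobel edge strength and orientation are
#' computed for the fused image and each source; strength and orientation
#' preservation factors are passed through sigmoids and multiplied, and the
#' per-pixel products are averaged with the source edge strengths as
#' weights. The sigmoid constants (defaults: `gamma_g = 0.9994`,
#' `kappa_g = -15`, `sigma_g = 0.5`, `gamma_a = 0.9879`, `kappa_a = -22`,
#' `sigma_a = 0.8`) are the standard published values; the per-pixel
#' product is normalized by its analytic ceiling so that a fused image
#' identical to both sources scores 1.
#'
#' @param fused,src_a,src_b real matrices of identical shape, >= 3x3.
#' @param constants named list overriding any of the six sigmoid constants.
#' @return scalar in \[0, 1\] (0 when both sources are constant).
#' @export
qabf <- function(fused, src_a, src_b, constants = list()) {
  if (!all(dim(fused) == dim(src_a)) || !all(dim(fused) == dim(src_b)))
    stop("images must share one shape")
  if (nrow(fused) < 3 || ncol(fused) < 3) stop("images must be at least 3x3")
  const <- utils::modifyList(
    list(gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
         gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8),
    constants
  )
  ef <- sobel_edges(fused)
  ea <- sobel_edges(src_a)
  eb <- sobel_edges(src_b)
  wa <- ea$g
  wb <- eb$g
  wsum <- sum(wa) + sum(wb)
  if (wsum == 0) return(0)
  qa <- edge_preservation(ea, ef, const)
  qb <- edge_preservation(eb, ef, const)
  min(1, max(0, (sum(qa * wa) + sum(qb * wb)) / wsum))
}

#' Score a fused image against its two sources
#'
#' Convenience wrapper computing all four indicators.
#'
#' @inheritParams qabf
#' @param names optional character vector of image names for the report.
#' @return list of class `quality_report` with elements `sf`, `ag`, `mi`,
#'   `qabf`, and `meta`.
#' @export
quality_report <- function(fused, src_a, src_b, names = NULL) {
  structure(
    list(sf = spatial_frequency(fused),
         ag = average_gradient(fused),
         mi = mutual_information(fused, src_a, src_b),
         qabf = qabf(fused, src_a, src_b),
         meta = list(names = names, dim = dim(fused))),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("%-6s %10.4f\n", "SF", x$sf))
  cat(sprintf("%-6s %10.4f\n", "AG", x$ag))
  cat(sprintf("%-6s %10.4f\n", "MI", x$mi))
  cat(sprintf("%-6s %10.4f\n", "QAB/F", x$qabf))
  invisible(x)
}
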