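# Seeded synthetic co-registered multimodal image pairs. Both images of a
# pair share an elliptical "skull + tissue" phantom geometry; the two
# modalities differ in which structures carry contrast and texture, so the
# pair is complementary in the way CT/MR, MR/MR and MR/PET pairs are.

ellipse_mask <- function(M, N, cy, cx, ry, rx, angle = 0) {
  yy <- matrix(seq_len(M), M, N) / M - cy
  xx <- matrix(seq_len(N), M, N, byrow = TRUE) / N - cx
  ca <- cos(angle); sa <- sin(angle)
  u <- ca * yy + sa * xx
  v <- -sa * yy + ca * xx
  (u / ry)^2 + (v / rx)^2 <= 1
}

# Band-limited texture: white noise filtered to an annulus of normalized
# frequencies [f_lo, f_hi] (cycles per image, relative to Nyquist).
bandpass_texture <- function(M, N, f_lo, f_hi) {
  z <- matrix(rnorm(M * N), M, N)
  Fc <- fftshift2(stats::fft(z))
  w1 <- (-(M / 2)):(M / 2 - 1)
  w2 <- (-(N / 2)):(N / 2 - 1)
  r <- sqrt(outer((w1 / (M / 2))^2, (w2 / (N / 2))^2, "+"))
  Fc[r < f_lo | r > f_hi] <- 0
  t <- Re(ifft2(ifftshift2(Fc)))
  s <- stats::sd(t)
  if (s > 0) t / s else t
}

#' Specification of a synthetic multimodal phantom pair
#'
#' @param size integer vector `c(M, N)`; both even and >= 64.
#' @param mode `"ct_mr"` (bright-rim/coarse vs fine-texture), `"mr_mr"`
#'   (coarse vs fine interior texture), or `"mr_pet"` (grayscale anatomy
#'   vs RGB pseudo-color low-frequency activity).
#' @param seed integer RNG seed; the pair is bitwise reproducible.
#' @param noise standard deviation of added Gaussian noise in intensity
#'   units (images live in \[0, 1\]); 0 gives the exact noise-free phantom.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(64L, 64L), mode = "ct_mr", seed = 0L,
                         noise = 0.01) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 64L) || any(size %% 2L != 0L))
    stop("size must be two even integers >= 64")
  if (!mode %in% c("ct_mr", "mr_mr", "mr_pet"))
    stop("mode must be one of ct_mr, mr_mr, mr_pet")
  if (noise < 0) stop("noise must be >= 0")
  structure(list(size = size, mode = mode, seed = as.integer(seed),
                 noise = noise),
            class = "phantom_spec")
}

# Hot-metal pseudo-color map (black -> red -> yellow -> white), the usual
# PET display palette; its luminance is strictly increasing in activity.
activity_colormap <- function(v) {
  r <- clip_range(3 * v)
  g <- clip_range(3 * v - 1)
  b <- clip_range(3 * v - 2)
  array(c(r, g, b), dim = c(dim(v), 3L))
}

#' Generate one co-registered synthetic image pair
#'
#' Both images share the same skull/brain ellipse layout. Depending on the
#' mode, image A carries a bright skull rim and coarse interior structure
#' (CT-like) or coarse texture (MR-like), while image B carries fine
#' interior texture (MR-like) or a low-spatial-frequency pseudo-color
#' activity field (PET-like, returned as an `M x N x 3` RGB array). The
#' attribute `regions` holds two disjoint logical masks `r1` and `r2` on
#' which A respectively B is the locally more active (higher-variance)
#' modality.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `a` (matrix), `b` (matrix, or RGB array in
#'   `mr_pet` mode), and attribute-like element `regions`.
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- spec$size[1]; N <- spec$size[2]
  with_seed(spec$seed, {
    skull_out <- ellipse_mask(M, N, 0.5, 0.5, 0.44, 0.40)
    skull_in <- ellipse_mask(M, N, 0.5, 0.5, 0.38, 0.34)
    rim <- skull_out & !skull_in
    brain <- skull_in
    # shared interior anatomy: a few seeded sub-ellipses
    vent <- ellipse_mask(M, N, 0.45 + runif(1, -0.02, 0.02), 0.5,
                         0.10, 0.05, runif(1, -0.3, 0.3))
    blob1 <- ellipse_mask(M, N, 0.62, 0.38 + runif(1, -0.02, 0.02),
                          0.08, 0.09, runif(1, -0.5, 0.5))
    blob2 <- ellipse_mask(M, N, 0.60, 0.66, 0.07, 0.08, runif(1, -0.5, 0.5))
    left <- matrix(seq_len(N), M, N, byrow = TRUE) / N < 0.5

    fine <- bandpass_texture(M, N, 0.25, 0.6)
    coarse <- bandpass_texture(M, N, 0.05, 0.18)
    activity_lo <- bandpass_texture(M, N, 0, 0.06)

    base <- 0.45 * brain + 0.1 * blob1 + 0.12 * blob2 - 0.25 * vent

    # complementarity regions straddle the structures only one modality
    # renders with contrast: a shell across the skull rim (CT-like A),
    # interior texture zones, or the activity blobs (PET-like B)
    rim_shell <- ellipse_mask(M, N, 0.5, 0.5, 0.47, 0.43) &
      !ellipse_mask(M, N, 0.5, 0.5, 0.35, 0.31)

    if (spec$mode == "ct_mr") {
      a <- 0.92 * rim + 0.35 * brain + 0.18 * blob1 + 0.2 * blob2 -
        0.2 * vent + 0.03 * coarse * brain
      b <- 0.12 * rim + base + 0.12 * fine * brain
      r1 <- rim_shell
      r2 <- brain & !vent & !rim_shell
    } else if (spec$mode == "mr_mr") {
      a <- 0.2 * rim + base + 0.14 * coarse * brain * left +
        0.02 * fine * brain
      b <- 0.25 * rim + base + 0.14 * fine * brain * (!left)
      r1 <- brain & left & !vent
      r2 <- brain & (!left) & !vent
    } else { # mr_pet
      a <- 0.2 * rim + base + 0.12 * fine * brain
      # focal uptake with no anatomical correlate, a hallmark of
      # functional imaging
      hot_cy <- 0.40 + runif(1, -0.03, 0.03)
      hot_cx <- 0.62 + runif(1, -0.03, 0.03)
      hot <- ellipse_mask(M, N, hot_cy, hot_cx, 0.06, 0.07)
      # moderate tanh-bounded background variation under focal uptake with
      # 2-4x focal-to-background contrast; nothing saturates, so the hot
      # edge always falls on a steep part of the palette
      act <- clip_range(0.35 + 0.15 * tanh(activity_lo) + 0.25 * blob1 +
                          0.2 * blob2 + 0.45 * hot) * brain
      b <- activity_colormap(act)
      # outside the brain the activity (hence B) is exactly constant while
      # A still carries the skull rim; the hot spot's edge is present only
      # in B
      r1 <- rim_shell & !brain
      # ring across the hot spot's edge: B's luminance steps there while A
      # carries only texture
      r2 <- ellipse_mask(M, N, hot_cy, hot_cx, 0.085, 0.095) &
        !ellipse_mask(M, N, hot_cy, hot_cx, 0.035, 0.04) & brain & !vent
    }

    addnoise <- function(x) {
      if (spec$noise > 0) x <- x + array(rnorm(length(x), 0, spec$noise), dim(x))
      clip_range(x)
    }
    list(a = addnoise(clip_range(a)), b = addnoise(clip_range(b)),
         regions = list(r1 = r1, r2 = r2), spec = spec)
  })
}

#' Seeded suite of five synthetic pairs spanning all three modes
#'
#' The suite used by the package's regression benchmarks: two CT/MR-style
#' pairs, two MR/MR-style pairs and one MR/PET-style pair, all at the
#' given size, deterministic per seed.
#'
#' @param seed integer seed.
#' @param size image size passed to every [phantom_spec()].
#' @param noise noise level passed to every [phantom_spec()].
#' @return list of five [make_pair()] results.
#' @export
make_suite <- function(seed = 0L, size = c(64L, 64L), noise = 0.01) {
  modes <- c("ct_mr", "mr_mr", "mr_pet", "ct_mr", "mr_mr")
  lapply(seq_along(modes), function(i)
    make_pair(phantom_spec(size = size, mode = modes[i],
                           seed = seed * 31L + i, noise = noise)))
}
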