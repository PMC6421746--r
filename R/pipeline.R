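# End-to-end fusion pipeline: decompose both sources with the shearlet
# system, fuse the low bands by sparse coding and the high bands by the
# PCNN, reconstruct, clip. Color (anatomical gray + functional RGB) pairs
# are fused on the luminance channel with chrominance carried over.

#' Fusion configuration
#'
#' Collects every free parameter of the pipeline. Numeric defaults:
#' 3 shearlet scales, 8-pixel patches, 256 atoms, sparsity 8, relative OMP
#' tolerance 1e-6, 20 K-SVD sweeps over a 5000-column seeded training
#' subset, standard PCNN constants, luminance-chrominance color handling,
#' intensities in \[0, 1\].
#'
#' @param scales shearlet scale count `j0`.
#' @param patch_size sliding-window side `n` in pixels.
#' @param dict_size number of dictionary atoms.
#' @param t0 OMP sparsity.
#' @param tol_rel OMP relative residual tolerance.
#' @param ksvd_iter K-SVD sweeps.
#' @param train_size training columns sampled from the pooled patches.
#' @param pcnn a [pcnn_params()] object.
#' @param color_mode `"luminance"` (fuse Y, keep CbCr) or `"none"`.
#' @param seed RNG seed controlling dictionary initialization/sampling.
#' @param range intensity range of inputs and clipped output.
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(scales = 3L, patch_size = 8L, dict_size = 256L,
                          t0 = 8L, tol_rel = 1e-6, ksvd_iter = 20L,
                          train_size = 5000L, pcnn = pcnn_params(),
                          color_mode = c("luminance", "none"),
                          seed = 0L, range = c(0, 1)) {
  color_mode <- match.arg(color_mode)
  stopifnot(scales >= 1, patch_size >= 3, dict_size > patch_size^2,
            t0 >= 1, tol_rel >= 0, ksvd_iter >= 1, train_size >= dict_size,
            inherits(pcnn, "pcnn_params"), length(range) == 2,
            range[2] > range[1])
  structure(list(scales = as.integer(scales),
                 patch_size = as.integer(patch_size),
                 dict_size = as.integer(dict_size), t0 = as.integer(t0),
                 tol_rel = tol_rel, ksvd_iter = as.integer(ksvd_iter),
                 train_size = as.integer(train_size), pcnn = pcnn,
                 color_mode = color_mode, seed = as.integer(seed),
                 range = range),
            class = "fusion_config")
}

#' Fuse two co-registered grayscale images
#'
#' Both images are decomposed with a shared shearlet system; the two
#' low-frequency bands are fused by joint K-SVD dictionary learning, OMP
#' sparse coding and the three-case L1 rule; each pair of corresponding
#' directional bands is fused by the spatial-frequency-driven PCNN; the
#' fused stack is inverted and the result clipped to the configured range.
#' Registration is assumed; only shape equality is checked.
#'
#' @param image_a,image_b real matrices of identical (even) shape.
#' @param config a [fusion_config()].
#' @return fused matrix with attribute `clipped_fraction` (fraction of
#'   pixels clipped to the intensity range).
#' @export
fuse_gray <- function(image_a, image_b, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  if (!is.matrix(image_a) || !is.matrix(image_b))
    stop("inputs must be single-channel matrices")
  if (!all(dim(image_a) == dim(image_b)))
    stop("source images must share the registered size M x N")
  if (!all(is.finite(image_a)) || !all(is.finite(image_b)))
    stop("inputs must be finite")
  sys <- shearlet_system(nrow(image_a), ncol(image_a), config$scales)
  ca <- shearlet_decompose(image_a, sys)
  cb <- shearlet_decompose(image_b, sys)
  low <- fuse_low_bands(ca$low, cb$low, n = config$patch_size,
                        n_atoms = config$dict_size, t0 = config$t0,
                        iterations = config$ksvd_iter,
                        tol_rel = config$tol_rel,
                        train_size = config$train_size, seed = config$seed)
  high <- lapply(seq_along(ca$high), function(i)
    fuse_high_pair(ca$high[[i]], cb$high[[i]], config$pcnn))
  fused <- shearlet_reconstruct(list(low = low, high = high), sys)
  lo <- config$range[1]; hi <- config$range[2]
  clipped <- mean(fused < lo | fused > hi)
  out <- clip_range(fused, lo, hi)
  attr(out, "clipped_fraction") <- clipped
  out
}

# BT.601 full-range RGB <-> YCbCr on [0, 1] arrays; the two maps are exact
# inverses (coefficients derived from Kr = 0.299, Kb = 0.114).
rgb_to_ycbcr <- function(img) {
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  Y <- 0.299 * R + 0.587 * G + 0.114 * B
  array(c(Y, (B - Y) / (2 * (1 - 0.114)) + 0.5,
          (R - Y) / (2 * (1 - 0.299)) + 0.5),
        dim = dim(img))
}
ycbcr_to_rgb <- function(img) {
  Y <- img[, , 1]; Cb <- img[, , 2] - 0.5; Cr <- img[, , 3] - 0.5
  R <- Y + 2 * (1 - 0.299) * Cr
  B <- Y + 2 * (1 - 0.114) * Cb
  G <- (Y - 0.299 * R - 0.114 * B) / 0.587
  array(c(R, G, B), dim = dim(img))
}

#' Fuse a grayscale image with a pseudo-color image
#'
#' The color image (functional modality, e.g. PET/SPECT pseudo-color) is
#' converted to YCbCr; its luminance channel is fused with the grayscale
#' image via [fuse_gray()]; the original chrominance channels are
#' reattached unchanged and the result converted back to RGB and clipped.
#'
#' @param image_gray real matrix.
#' @param image_color `M x N x 3` RGB array on the same spatial grid.
#' @param config a [fusion_config()].
#' @return fused `M x N x 3` RGB array.
#' @export
fuse_color <- function(image_gray, image_color, config = fusion_config()) {
  if (length(dim(image_color)) != 3L || dim(image_color)[3] != 3L)
    stop("image_color must have 3 channels")
  if (!all(dim(image_color)[1:2] == dim(image_gray)))
    stop("spatial shapes must match")
  ycc <- rgb_to_ycbcr(image_color)
  yf <- fuse_gray(image_gray, ycc[, , 1], config)
  out <- ycbcr_to_rgb(array(c(yf, ycc[, , 2], ycc[, , 3]), dim = dim(ycc)))
  clip_range(out, config$range[1], config$range[2])
}

#' Read an 8-bit grayscale or RGB image
#'
#' PNG and TIFF are supported; intensities are returned in \[0, 1\] as a
#' matrix (grayscale) or `M x N x 3` array (RGB; alpha is dropped).
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return matrix or 3-channel array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG and TIFF are supported)")
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
    else img <- img[, , 1]
    if (length(dim(img)) == 3L) {
      # collapse gray-as-RGB to a matrix
      if (max(abs(img[, , 1] - img[, , 2])) == 0 &&
          max(abs(img[, , 1] - img[, , 3])) == 0)
        img <- img[, , 1]
    }
  }
  img
}

#' Write an image in \[0, 1\] to PNG or TIFF
#'
#' @param img matrix or `M x N x 3` array with values in \[0, 1\].
#' @param path output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- clip_range(img, 0, 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format '.", ext, "' (PNG and TIFF are supported)")
  )
  invisible(path)
}

# Luminance view of a gray matrix or RGB array.
luminance <- function(img) {
  if (length(dim(img)) == 3L) rgb_to_ycbcr(img)[, , 1] else img
}

cli_parse <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("missing value for --", key)
    flags[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

cli_config <- function(flags) {
  num <- function(key, default) {
    if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
  }
  fusion_config(
    scales = num("scales", 3L),
    patch_size = num("patch_size", 8L),
    dict_size = num("dict_size", 256L),
    t0 = num("t0", 8L),
    ksvd_iter = num("ksvd_iter", 20L),
    train_size = num("train_size", 5000L),
    seed = num("seed", 0L)
  )
}

cli_report <- function(fused, a, b, config, inputs, path = NULL) {
  rep <- quality_report(luminance(fused), luminance(a), luminance(b))
  print(rep)
  if (!is.null(path)) {
    payload <- list(sf = rep$sf, ag = rep$ag, mi = rep$mi, qabf = rep$qabf,
                    config = config[setdiff(names(config), "pcnn")],
                    inputs = inputs)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    message("report written to ", path)
  }
  invisible(rep)
}

#' Command line interface
#'
#' Subcommands:
#' \describe{
#'   \item{fuse}{`--input-a a.png --input-b b.png --output f.png`
#'     (optional `--report r.json` plus any config flag): fuse two images;
#'     if input B is RGB the luminance-fusion color path is used.}
#'   \item{metrics}{`--fused f.png --input-a a.png --input-b b.png`
#'     (optional `--report r.json`): score an existing fused image.}
#'   \item{demo}{`--seed 7 --outdir dir` (optional `--mode`, `--size`):
#'     generate a synthetic pair, fuse it, write the three images and print
#'     the quality report. Deterministic per seed.}
#' }
#' Config flags: `--scales`, `--patch-size`, `--dict-size`, `--t0`,
#' `--ksvd-iter`, `--train-size`, `--seed`.
#'
#' @param args character vector of command line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(args) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop("usage: shearfuse <fuse|metrics|demo> --flag value ...")
    cmd <- args[1]
    flags <- cli_parse(args[-1])
    if (cmd == "fuse") {
      for (k in c("input_a", "input_b", "output"))
        if (is.null(flags[[k]])) stop("fuse requires --", gsub("_", "-", k))
      a <- read_image(flags$input_a)
      b <- read_image(flags$input_b)
      config <- cli_config(flags)
      t0 <- Sys.time()
      fused <- if (length(dim(b)) == 3L) fuse_color(a, b, config)
               else fuse_gray(a, b, config)
      message(sprintf("fused %s + %s in %.1f s (scales=%d, atoms=%d, t0=%d)",
                      flags$input_a, flags$input_b,
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      config$scales, config$dict_size, config$t0))
      write_image(fused, flags$output)
      cli_report(fused, a, b, config,
                 list(a = flags$input_a, b = flags$input_b), flags$report)
    } else if (cmd == "metrics") {
      for (k in c("fused", "input_a", "input_b"))
        if (is.null(flags[[k]])) stop("metrics requires --", gsub("_", "-", k))
      cli_report(read_image(flags$fused), read_image(flags$input_a),
                 read_image(flags$input_b), cli_config(flags),
                 list(a = flags$input_a, b = flags$input_b), flags$report)
    } else if (cmd == "demo") {
      seed <- if (is.null(flags$seed)) 0L else as.integer(flags$seed)
      mode <- if (is.null(flags$mode)) "ct_mr" else flags$mode
      size <- if (is.null(flags$size)) 64L else as.integer(flags$size)
      outdir <- if (is.null(flags$outdir)) "." else flags$outdir
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      pair <- make_pair(phantom_spec(size = c(size, size), mode = mode,
                                     seed = seed))
      config <- cli_config(flags)
      fused <- if (length(dim(pair$b)) == 3L) fuse_color(pair$a, pair$b, config)
               else fuse_gray(pair$a, pair$b, config)
      write_image(pair$a, file.path(outdir, "source_a.png"))
      write_image(pair$b, file.path(outdir, "source_b.png"))
      write_image(fused, file.path(outdir, "fused.png"))
      message("demo images written to ", outdir)
      cli_report(fused, pair$a, pair$b, config, list(mode = mode, seed = seed),
                 flags$report)
    } else {
      stop("unknown subcommand: ", cmd)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
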