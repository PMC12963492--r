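# Preprocessing: plain bilinear resize, CLAHE on the LAB L-channel,
# Gaussian denoising, unsharp sharpening, and channel-wise standardization
# whose statistics come from the training split only. The enhancement chain
# maps valid 8-bit RGB to valid 8-bit RGB; standardization is the only step
# producing unbounded reals. Nothing in this module uses the RNG.

#' Preprocessing configuration
#'
#' CLAHE clip limit 4.0 on a 12x12 tile grid, 9x9 Gaussian blur with sigma
#' 2, unsharp masking with amount 1.8 against a 7x7 Gaussian blur, target
#' size 248. The sigma of the unsharp blur follows the kernel-size
#' convention `0.3 * ((k - 1)/2 - 1) + 0.8`.
#'
#' @param clahe_clip,clahe_tiles,blur_kernel,blur_sigma,unsharp_kernel,unsharp_alpha,unsharp_sigma,target_size
#'   stage parameters (pixel units; kernels must be odd).
#' @return object of class `preproc_config`.
#' @export
preproc_config <- function(clahe_clip = 4.0, clahe_tiles = c(12, 12),
                           blur_kernel = 9, blur_sigma = 2.0,
                           unsharp_kernel = 7, unsharp_alpha = 1.8,
                           unsharp_sigma = NULL, target_size = 248) {
  stopifnot(blur_kernel %% 2 == 1, unsharp_kernel %% 2 == 1,
            unsharp_alpha > 0, clahe_clip > 0)
  if (is.null(unsharp_sigma))
    unsharp_sigma <- 0.3 * ((unsharp_kernel - 1) / 2 - 1) + 0.8
  structure(list(clahe_clip = clahe_clip, clahe_tiles = clahe_tiles,
                 blur_kernel = as.integer(blur_kernel), blur_sigma = blur_sigma,
                 unsharp_kernel = as.integer(unsharp_kernel),
                 unsharp_alpha = unsharp_alpha, unsharp_sigma = unsharp_sigma,
                 target_size = as.integer(target_size)),
            class = "preproc_config")
}

#' Bilinear image resize
#'
#' Plain (aspect-ignoring) bilinear resize with half-pixel-center sampling;
#' source coordinates are clamped at the border.
#'
#' @param img `(H, W, 3)` array.
#' @param size output side in pixels (square output), or `c(height, width)`.
#' @return `(size, size, 3)` array.
#' @export
resize_image <- function(img, size) {
  assert_rgb(img)
  d <- dim(img)
  if (any(d[1:2] < 1) || any(size < 1)) stop("zero-size image in resize")
  oh <- size[1]; ow <- if (length(size) > 1) size[2] else size[1]
  if (oh == d[1] && ow == d[2]) return(img)
  src_r <- pmin(pmax((seq_len(oh) - 0.5) * d[1] / oh - 0.5, 0), d[1] - 1)
  src_c <- pmin(pmax((seq_len(ow) - 0.5) * d[2] / ow - 0.5, 0), d[2] - 1)
  r0 <- floor(src_r); wr <- src_r - r0
  c0 <- floor(src_c); wc <- src_c - c0
  r1 <- pmin(r0 + 1, d[1] - 1) + 1; r0 <- r0 + 1
  c1 <- pmin(c0 + 1, d[2] - 1) + 1; c0 <- c0 + 1
  out <- array(0, c(oh, ow, 3))
  for (ch in 1:3) {
    top <- img[r0, , ch, drop = FALSE] * (1 - wr) + img[r1, , ch, drop = FALSE] * wr
    dim(top) <- c(oh, d[2])
    out[, , ch] <- top[, c0, drop = FALSE] * rep(1 - wc, each = oh) +
      top[, c1, drop = FALSE] * rep(wc, each = oh)
  }
  out
}

#' Contrast-limited adaptive histogram equalization on the L channel
#'
#' Converts to LAB, applies CLAHE to the lightness channel with the
#' configured clip limit and tile grid, leaves A/B untouched, converts back
#' to RGB and clips to the 8-bit range. Images smaller than twice the tile
#' grid shrink the grid with a warning.
#'
#' @param img `(H, W, 3)` array in `[0, 255]`.
#' @param config a [preproc_config()].
#' @return enhanced `(H, W, 3)` array in `[0, 255]`.
#' @export
clahe_l_channel <- function(img, config = preproc_config()) {
  assert_rgb(img)
  d <- dim(img)
  m <- matrix(img, d[1] * d[2], 3) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  nx <- config$clahe_tiles[1]; ny <- config$clahe_tiles[2]
  if (d[1] < 2 * ny || d[2] < 2 * nx) {
    nx <- max(1L, min(nx, d[2] %/% 2))
    ny <- max(1L, min(ny, d[1] %/% 2))
    warning("image smaller than CLAHE tile grid; shrinking grid to ",
            nx, "x", ny)
  }
  L <- matrix(lab[, 1] / 100, d[1], d[2])
  # the tile grid requires tile-divisible dimensions: reflect-pad, then crop
  ph <- (ny - d[1] %% ny) %% ny
  pw <- (nx - d[2] %% nx) %% nx
  Lp <- L[c(seq_len(d[1]), d[1] - seq_len(ph)),
          c(seq_len(d[2]), d[2] - seq_len(pw)), drop = FALSE]
  Leq <- EBImage::clahe(EBImage::Image(t(Lp)), nx = nx, ny = ny,
                        bins = 256, limit = config$clahe_clip)
  Lout <- t(EBImage::imageData(Leq))[seq_len(d[1]), seq_len(d[2])]
  lab[, 1] <- pmin(pmax(as.numeric(Lout), 0), 1) * 100
  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  clip255(array(rgb * 255, d))
}

#' Discrete Gaussian kernel
#'
#' One-dimensional sampled Gaussian, `g_i` proportional to
#' `exp(-i^2 / (2 sigma^2))` for `i` in `-(k-1)/2 .. (k-1)/2`, normalized to
#' sum 1.
#'
#' @param k odd kernel size.
#' @param sigma standard deviation in pixels.
#' @return length-`k` numeric vector.
#' @export
gaussian_kernel <- function(k, sigma) {
  stopifnot(k %% 2 == 1, sigma > 0)
  i <- seq(-(k - 1) / 2, (k - 1) / 2)
  g <- exp(-i^2 / (2 * sigma^2))
  g / sum(g)
}

reflect_pad_idx <- function(n, p) {
  # reflect-101 indices for a vector of length n padded by p on both sides
  idx <- seq(1 - p, n + p)
  m <- 2 * (n - 1)
  idx <- abs(idx - 1) %% m
  ifelse(idx > n - 1, m - idx, idx) + 1
}

#' Gaussian blur with reflection border handling
#'
#' Separable convolution with the sampled Gaussian of [gaussian_kernel()];
#' borders are mirrored (reflect-101).
#'
#' @param img `(H, W, 3)` array.
#' @param kernel odd kernel size (default 9).
#' @param sigma Gaussian sigma (default 2).
#' @return blurred array of the same shape.
#' @export
gaussian_blur <- function(img, kernel = 9, sigma = 2.0) {
  assert_rgb(img)
  g <- gaussian_kernel(kernel, sigma)
  p <- (kernel - 1) / 2
  d <- dim(img)
  ridx <- reflect_pad_idx(d[1], p)
  cidx <- reflect_pad_idx(d[2], p)
  out <- array(0, d)
  for (ch in 1:3) {
    x <- img[, , ch]
    xp <- x[ridx, , drop = FALSE]
    acc <- matrix(0, d[1], d[2])
    for (t in seq_len(kernel)) acc <- acc + g[t] * xp[t:(t + d[1] - 1), , drop = FALSE]
    accp <- acc[, cidx, drop = FALSE]
    acc2 <- matrix(0, d[1], d[2])
    for (t in seq_len(kernel)) acc2 <- acc2 + g[t] * accp[, t:(t + d[2] - 1), drop = FALSE]
    out[, , ch] <- acc2
  }
  out
}

#' Unsharp masking
#'
#' `out = clip((1 + alpha) * img - alpha * blur(img))` with a Gaussian blur
#' of the configured kernel; equivalently `img + alpha * (img - blur)`.
#'
#' @param img `(H, W, 3)` array in `[0, 255]`.
#' @param alpha sharpening amount (default 1.8).
#' @param kernel odd blur kernel size (default 7).
#' @param sigma blur sigma; defaults to the kernel-size convention of
#'   [preproc_config()].
#' @return sharpened array clipped to `[0, 255]`.
#' @export
unsharp_mask <- function(img, alpha = 1.8, kernel = 7, sigma = NULL) {
  if (is.null(sigma)) sigma <- 0.3 * ((kernel - 1) / 2 - 1) + 0.8
  blur <- gaussian_blur(img, kernel, sigma)
  clip255((1 + alpha) * img - alpha * blur)
}

## ---- channel statistics ----------------------------------------------------

SIGMA_FLOOR <- 1e-6

#' Fit per-channel standardization statistics on the training split
#'
#' Accumulates the per-channel mean and standard deviation over all pixels
#' of the training records after the enhancement chain (resize, CLAHE,
#' blur, unsharp). Any record whose split is not `train` aborts: this is
#' the leakage guard.
#'
#' @param records a `leaf_manifest` (or data frame) of training records.
#' @param config a [preproc_config()].
#' @param enhance apply the enhancement chain before accumulating (set
#'   `FALSE` to fit on raw resized pixels).
#' @return object of class `channel_stats`: list with `mu`, `sigma` (both
#'   length 3, sigma floored at 1e-6), `n_pixels`, `n_images`.
#' @export
fit_channel_stats <- function(records, config = preproc_config(),
                              enhance = TRUE) {
  if (nrow(records) == 0) stop("no records to fit channel statistics on")
  if (any(records$split != "train"))
    stop("leakage guard: fit_channel_stats received non-training records (",
         paste(unique(records$split[records$split != "train"]), collapse = ", "),
         ")")
  s <- numeric(3); ss <- numeric(3); n <- 0
  for (i in seq_len(nrow(records))) {
    img <- read_image(records$path[i])
    img <- if (enhance) enhance_image(img, config)
           else resize_image(img, config$target_size)
    px <- matrix(img, ncol = 3)
    s <- s + colSums(px)
    ss <- ss + colSums(px^2)
    n <- n + nrow(px)
  }
  mu <- s / n
  sigma <- pmax(sqrt(pmax(ss / n - mu^2, 0)), SIGMA_FLOOR)
  structure(list(mu = mu, sigma = sigma, n_pixels = n,
                 n_images = nrow(records)),
            class = "channel_stats")
}

#' Channel statistics from an in-memory image stack
#'
#' @param x array `(H, W, 3, N)` of already-enhanced training images.
#' @return a `channel_stats` object.
#' @export
channel_stats_from_array <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  px <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = 3)
  mu <- colMeans(px)
  sigma <- pmax(sqrt(colMeans(px^2) - mu^2), SIGMA_FLOOR)
  structure(list(mu = mu, sigma = sigma, n_pixels = nrow(px),
                 n_images = dim(x)[4]),
            class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat(sprintf("Channel stats from %d training images (%d pixels)\n",
              x$n_images, x$n_pixels))
  cat("  mu:   ", paste(sprintf("%.3f", x$mu), collapse = " "), "\n")
  cat("  sigma:", paste(sprintf("%.3f", x$sigma), collapse = " "), "\n")
  invisible(x)
}

#' @rdname fit_channel_stats
#' @param stats a `channel_stats`.
#' @param path small text (YAML) file.
#' @export
write_channel_stats <- function(stats, path) {
  yaml::write_yaml(lapply(unclass(stats), as.numeric), path)
  invisible(path)
}

#' @rdname fit_channel_stats
#' @export
read_channel_stats <- function(path) {
  v <- yaml::read_yaml(path)
  structure(list(mu = as.numeric(v$mu), sigma = as.numeric(v$sigma),
                 n_pixels = v$n_pixels, n_images = v$n_images),
            class = "channel_stats")
}

#' Channel-wise standardization
#'
#' `x' = (x - mu) / sigma` per channel; the output is real-valued and not
#' clipped.
#'
#' @param img `(H, W, 3)` array (or `(H, W, 3, N)` batch).
#' @param stats a `channel_stats`.
#' @return standardized array of the same shape.
#' @export
standardize <- function(img, stats) {
  d <- dim(img)
  HW <- d[1] * d[2]
  # a length HW*3 vector recycles across any batch dimension
  out <- (img - rep(stats$mu, each = HW)) / rep(stats$sigma, each = HW)
  dim(out) <- d
  out
}

## ---- pipeline --------------------------------------------------------------

enhance_image <- function(img, config = preproc_config()) {
  img <- resize_image(img, config$target_size)
  img <- clahe_l_channel(img, config)
  img <- gaussian_blur(img, config$blur_kernel, config$blur_sigma)
  unsharp_mask(img, config$unsharp_alpha, config$unsharp_kernel,
               config$unsharp_sigma)
}

#' Full preprocessing pipeline
#'
#' Resize, CLAHE (LAB L-channel), Gaussian blur, unsharp masking, and —
#' when statistics are supplied — channel-wise standardization, in that
#' order. Applying the pipeline twice is not idempotent (each pass
#' re-enhances contrast); it is meant to run once per image.
#'
#' @param img an `(H, W, 3)` array, or a list of such arrays (order is
#'   preserved).
#' @param config a [preproc_config()].
#' @param stats optional `channel_stats`; when present the output is
#'   standardized (real-valued), otherwise 8-bit range.
#' @return array (or list of arrays) of shape `(target, target, 3)`.
#' @export
preprocess_pipeline <- function(img, config = preproc_config(), stats = NULL) {
  if (is.list(img))
    return(lapply(img, preprocess_pipeline, config = config, stats = stats))
  out <- enhance_image(img, config)
  if (!is.null(stats)) out <- standardize(out, stats)
  out
}
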