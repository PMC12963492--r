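# Shared helpers: image representation, color conversions, seeded RNG.
#
# Images are numeric arrays (H, W, 3) with values in [0, 255] (doubles);
# only standardization produces unbounded reals.

clip255 <- function(x) pmin(pmax(x, 0), 255)

assert_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("expected an (H, W, 3) RGB array")
  invisible(img)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a well-spread child seed below 2^31 from a base seed and indices.
derive_seed <- function(seed, ...) {
  v <- c(seed, ...)
  h <- 0
  for (x in v) h <- (h * 1103515245 + as.numeric(x) + 12345) %% 2147483647
  as.integer(h)
}

## ---- HSV <-> RGB (vectorized, numeric) -------------------------------------

rgb_to_hsv_mat <- function(img) {
  # img (H, W, 3) in 0..255 -> list(h, s, v) each H*W vectors, h,s,v in [0,1]
  d <- dim(img)
  m <- pmin(pmax(matrix(img, d[1] * d[2], 3) / 255, 0), 1)
  grDevices::rgb2hsv(t(m), maxColorValue = 1)
}

hsv_to_rgb_mat <- function(hsv, d) {
  h <- hsv[1, ] * 6
  s <- hsv[2, ]
  v <- hsv[3, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b) * 255, dim = d)
}

shift_hue <- function(img, degrees) {
  d <- dim(img)
  hsv <- rgb_to_hsv_mat(img)
  hsv[1, ] <- (hsv[1, ] + degrees / 360) %% 1
  clip255(hsv_to_rgb_mat(hsv, d))
}

## ---- logging ---------------------------------------------------------------

log_msg <- function(fmt, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(fmt, ...))
}
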