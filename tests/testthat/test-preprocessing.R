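test_that("bilinear resize honors its shape contract and identity case", {
  img <- random_image(496, 496)
  expect_equal(dim(resize_image(img, 248)), c(248, 248, 3))
  img2 <- random_image(248, 248)
  expect_identical(resize_image(img2, 248), img2)
  expect_error(resize_image(img2, 0), "zero-size")
})

test_that("bilinear resize matches a naive half-pixel-center oracle", {
  img <- random_image(5, 7, seed = 3)
  out <- resize_image(img, c(9, 4))
  naive <- array(0, c(9, 4, 3))
  for (i in 1:9) for (j in 1:4) for (ch in 1:3) {
    sr <- min(max((i - 0.5) * 5 / 9 - 0.5, 0), 4)
    sc <- min(max((j - 0.5) * 7 / 4 - 0.5, 0), 6)
    r0 <- floor(sr); c0 <- floor(sc)
    r1 <- min(r0 + 1, 4); c1 <- min(c0 + 1, 6)
    wr <- sr - r0; wc <- sc - c0
    naive[i, j, ch] <-
      img[r0 + 1, c0 + 1, ch] * (1 - wr) * (1 - wc) +
      img[r0 + 1, c1 + 1, ch] * (1 - wr) * wc +
      img[r1 + 1, c0 + 1, ch] * wr * (1 - wc) +
      img[r1 + 1, c1 + 1, ch] * wr * wc
  }
  expect_equal(out, naive, tolerance = 1e-12)
  # 2x2 checkerboard to 4x4: corners keep the source values
  cb <- array(c(0, 255, 255, 0), c(2, 2, 3))
  up <- resize_image(cb, 4)
  expect_equal(up[1, 1, 1], 0)
  expect_equal(up[1, 4, 1], 255)
  expect_equal(up[2, 2, 1], 0 * 0.75 * 0.75 + 255 * 0.75 * 0.25 +
                 255 * 0.25 * 0.75 + 0 * 0.25 * 0.25)
})

test_that("CLAHE keeps constants constant, stays 8-bit, and raises ramp contrast", {
  const <- array(128, c(48, 48, 3))
  out <- clahe_l_channel(const)
  expect_lt(max(abs(sweep(out, 3, out[1, 1, ]))), 1e-9)  # spatially constant
  img <- random_image(48, 48, seed = 5)
  out2 <- clahe_l_channel(img)
  expect_true(all(out2 >= 0 & out2 <= 255))
  # low-contrast linear ramp: L standard deviation strictly increases
  ramp <- array(rep(seq(110, 140, length.out = 48), each = 48), c(48, 48, 3))
  lab_sd <- function(im) {
    lab <- grDevices::convertColor(matrix(im, ncol = 3) / 255, "sRGB", "Lab")
    sd(lab[, 1])
  }
  expect_gt(lab_sd(clahe_l_channel(ramp)), lab_sd(ramp))
  expect_warning(clahe_l_channel(random_image(10, 10)), "tile grid")
})

test_that("gaussian blur reproduces its kernel on an impulse and shifts equivariantly", {
  const <- array(77, c(20, 20, 3))
  expect_equal(gaussian_blur(const), const, tolerance = 1e-9)
  # central unit impulse: response equals the separable 9x9 kernel
  img <- array(0, c(31, 31, 3))
  img[16, 16, ] <- 1
  out <- gaussian_blur(img, 9, 2)
  g <- gaussian_kernel(9, 2)
  K <- outer(g, g)
  expect_equal(out[12:20, 12:20, 1], K, tolerance = 1e-12)
  expect_equal(sum(out[, , 1]), 1, tolerance = 1e-12)
  # shift equivariance away from borders
  img2 <- random_image(40, 40, seed = 9)
  shifted <- img2[, c(4:40, 1:3), , drop = FALSE]
  b1 <- gaussian_blur(img2)
  b2 <- gaussian_blur(shifted)
  expect_equal(b2[10:30, 10:30, ], b1[10:30, c(13:33), ], tolerance = 1e-9)
})

test_that("unsharp masking fixes constants and matches the 1-D step-edge form", {
  const <- array(200, c(16, 16, 3))
  expect_equal(unsharp_mask(const), const, tolerance = 1e-9)
  # step edge along columns: compare against an explicit 1-D stencil
  H <- 16; W <- 32
  step <- array(rep(c(rep(50, 16), rep(180, 16)), each = H), c(H, W, 3))
  alpha <- 1.8
  sigma <- 0.3 * ((7 - 1) / 2 - 1) + 0.8
  g <- gaussian_kernel(7, sigma)
  row1d <- c(rep(50, 16), rep(180, 16))
  padded <- row1d[c(4:2, 1:32, 31:29)]  # reflect-101
  blur1d <- vapply(1:32, function(j) sum(g * padded[j:(j + 6)]), numeric(1))
  expected <- pmin(pmax((1 + alpha) * row1d - alpha * blur1d, 0), 255)
  out <- unsharp_mask(step, alpha, 7)
  expect_equal(out[8, , 1], expected, tolerance = 1e-9)
  # overshoot exists on both sides of the edge
  expect_lt(out[8, 15, 1], 50)
  expect_gt(out[8, 18, 1], 180)
})

test_that("channel statistics guard against leakage and match hand moments", {
  d <- file.path(tempdir(), "stats_imgs")
  unlink(d, recursive = TRUE)
  a <- array(rep(c(10, 100, 200), each = 4), c(2, 2, 3))
  b <- array(rep(c(30, 120, 240), each = 4), c(2, 2, 3))
  write_image(a, file.path(d, "cls", "a.png"))
  write_image(b, file.path(d, "cls", "b.png"))
  m <- scan_image_folder(d)
  m$split <- "train"
  cfg <- preproc_config(target_size = 2)
  st <- fit_channel_stats(m, cfg, enhance = FALSE)
  expect_equal(st$mu, c(20, 110, 220))
  expect_equal(st$sigma, c(10, 10, 20))  # population sd of two values
  expect_equal(st$n_pixels, 8)
  # leakage guard
  m$split[2] <- "val"
  expect_error(fit_channel_stats(m, cfg), "leakage")
  # round-trip
  p <- file.path(tempdir(), "stats.yaml")
  write_channel_stats(st, p)
  st2 <- read_channel_stats(p)
  expect_equal(st2$mu, st$mu)
  expect_equal(st2$sigma, st$sigma)
})

test_that("standardization is exact at the mean and self-consistent on a split", {
  st <- structure(list(mu = c(50, 100, 150), sigma = c(5, 10, 15)),
                  class = "channel_stats")
  img <- array(rep(c(50, 100, 150), each = 16), c(4, 4, 3))
  expect_equal(standardize(img, st), array(0, c(4, 4, 3)))
  ident <- structure(list(mu = c(0, 0, 0), sigma = c(1, 1, 1)),
                     class = "channel_stats")
  r <- random_image(6, 6)
  expect_equal(standardize(r, ident), r)
  # the training stack standardized against its own stats has mean 0, sd 1
  set.seed(11)
  x <- array(runif(8 * 8 * 3 * 5, 0, 255), c(8, 8, 3, 5))
  stx <- channel_stats_from_array(x)
  z <- standardize(x, stx)
  for (ch in 1:3) {
    v <- as.numeric(z[, , ch, ])
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sqrt(mean(v^2)) - 1), 1e-6)
  }
})

test_that("the pipeline preserves constants, order, and batch structure", {
  cfg <- preproc_config(target_size = 32)
  const <- array(90, c(32, 32, 3))
  out <- preprocess_pipeline(const, cfg)
  expect_lt(max(abs(sweep(out, 3, out[1, 1, ]))), 1e-9)
  stc <- channel_stats_from_array(out)
  expect_equal(preprocess_pipeline(const, cfg, stc),
               array(0, c(32, 32, 3)), tolerance = 1e-9)
  # batches preserve order
  imgs <- list(random_image(20, 20, 1), random_image(20, 20, 2))
  outs <- preprocess_pipeline(imgs, cfg)
  expect_length(outs, 2)
  expect_equal(outs[[1]], preprocess_pipeline(imgs[[1]], cfg))
  expect_equal(outs[[2]], preprocess_pipeline(imgs[[2]], cfg))
})
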