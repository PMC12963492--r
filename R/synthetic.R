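# Deterministic procedural generator of twelve-class leaf-disease imagery.
# Three species bases (broad scalloped Kalanchoe, serrated lanceolate Neem,
# small ovate Tulsi) crossed with disorder overlays: none, brown ringed
# spots, gray web filaments (with or without necrotic patches), uniform
# chlorosis (veins green or not), chlorosis plus marginal necrosis, angular
# mildew patches with a gray-purple coating, and yellow halo rings.
# Signatures are deliberately exaggerated relative to real pathology: the
# goal is pipeline testability, not realism. Color bands are reserved so
# that leaf, background and overlay pixels are separable by rule (leaf
# value >= 0.40 pre-jitter, background <= 0.26; overlays are gray, brown or
# purple while healthy tissue stays green).

#' The twelve leaf-disease class names
#' @return character vector of class names (sorted).
#' @export
leaf_class_names <- function() {
  sort(c("Kalanchoe_Healthy", "Kalanchoe_Web_Blight", "Kalanchoe_Yellow",
         "Kalanchoe_Yellow_Blight", "Neem_Healthy", "Neem_Spot",
         "Neem_Web_Blight", "Neem_Yellow", "Tulsi_Downy_Mildew",
         "Tulsi_Healthy", "Tulsi_Web_Blight", "Tulsi_Yellow_Spot"))
}

leaf_class_spec <- function(name) {
  species <- sub("_.*$", "", name)
  base <- switch(species,
    Kalanchoe = list(hue = 0.34, a = 0.62, b = 0.48, serration = 8,
                     ser_amp = 0.035, n_lat = 4),
    Neem = list(hue = 0.30, a = 0.78, b = 0.30, serration = 26,
                ser_amp = 0.05, n_lat = 6),
    Tulsi = list(hue = 0.265, a = 0.52, b = 0.36, serration = 14,
                 ser_amp = 0.03, n_lat = 5),
    stop("unknown species in class name: ", name))
  disorder <- switch(name,
    Kalanchoe_Healthy = , Neem_Healthy = , Tulsi_Healthy = "none",
    Neem_Spot = "spots",
    Kalanchoe_Web_Blight = , Neem_Web_Blight = "web_necrotic",
    Tulsi_Web_Blight = "web",
    Kalanchoe_Yellow = "chlorosis_veins_green",
    Neem_Yellow = "chlorosis_uniform",
    Kalanchoe_Yellow_Blight = "chlorosis_marginal_necrosis",
    Tulsi_Downy_Mildew = "mildew",
    Tulsi_Yellow_Spot = "halo_spots",
    stop("unknown class: ", name))
  c(base, list(name = name, species = species, disorder = disorder))
}

smooth_field <- function(u, v, freq, k = 4) {
  f <- 0
  for (i in seq_len(k)) {
    a <- stats::runif(1, 0.5, 1) * freq
    b <- stats::runif(1, 0.5, 1) * freq
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + sin(a * (u * cos(th) + v * sin(th)) + b * (v * cos(th) - u * sin(th)) / 2 + ph)
  }
  f / sqrt(k)
}

seg_dist <- function(u, v, p1, p2) {
  du <- p2[1] - p1[1]; dv <- p2[2] - p1[2]
  len2 <- du^2 + dv^2 + 1e-12
  t <- pmin(pmax(((u - p1[1]) * du + (v - p1[2]) * dv) / len2, 0), 1)
  sqrt((u - p1[1] - t * du)^2 + (v - p1[2] - t * dv)^2)
}

#' Generate one synthetic leaf image
#'
#' @param class_name one of [leaf_class_names()].
#' @param size image side in pixels.
#' @param seed integer seed; identical calls are bit-identical.
#' @param clutter background clutter level in `[0, 1]`.
#' @param lighting lighting jitter amplitude in `[0, 0.3]`.
#' @return `(size, size, 3)` array in `[0, 255]`.
#' @export
generate_leaf_image <- function(class_name, size = 64, seed = 1,
                                clutter = 0.5, lighting = 0.15) {
  spec <- leaf_class_spec(class_name)
  with_seed(seed, {
    S <- as.integer(size)
    g <- expand.grid(i = seq_len(S) - 1, j = seq_len(S) - 1)
    cy <- (S - 1) / 2 + stats::runif(1, -0.08, 0.08) * S
    cx <- (S - 1) / 2 + stats::runif(1, -0.08, 0.08) * S
    y <- (g$i - cy) / (S / 2)
    x <- (g$j - cx) / (S / 2)
    th <- stats::runif(1, -25, 25) * pi / 180
    u <- cos(th) * x + sin(th) * y
    v <- -sin(th) * x + cos(th) * y
    a <- spec$a * stats::runif(1, 0.9, 1.1)
    b <- spec$b * stats::runif(1, 0.9, 1.1)
    phi <- atan2(v / b, u / a)
    rho <- sqrt((u / a)^2 + (v / b)^2)
    edge <- 1 + spec$ser_amp * sin(spec$serration * phi + stats::runif(1, 0, 2 * pi))
    mask <- rho <= edge
    d <- pmax(edge - rho, 0) / edge          # 0 at edge, ~1 at center

    # veins: midrib along u plus lateral pairs
    vein <- abs(v) < 0.022 & abs(u) < a & mask
    for (m in seq_len(spec$n_lat)) {
      um <- -a + 2 * a * m / (spec$n_lat + 1)
      lat <- abs(abs(v) * 0.8 - (u - um) * 0.6) < 0.015 & (u - um) > -0.02 & mask
      vein <- vein | lat
    }

    hue <- rep(spec$hue, S * S) + 0.015 * smooth_field(u, v, 3)
    sat <- 0.60 + 0.10 * smooth_field(u, v, 4)
    val <- 0.46 + 0.16 * d
    val[vein] <- val[vein] * 0.82
    sat[vein] <- sat[vein] * 0.9

    in_leaf_pt <- function() {
      r1 <- sqrt(stats::runif(1)) * 0.6
      ph <- stats::runif(1, 0, 2 * pi)
      c(a * r1 * cos(ph), b * r1 * sin(ph))
    }
    paint_spots <- function(n, rmin, rmax, ring, halo = FALSE) {
      for (s in seq_len(n)) {
        ctr <- in_leaf_pt()
        rs <- stats::runif(1, rmin, rmax)
        dist <- sqrt((u - ctr[1])^2 + (v - ctr[2])^2)
        core <- dist < rs * 0.72 & mask
        hue[core] <<- 0.07; sat[core] <<- 0.78; val[core] <<- 0.42
        if (ring) {
          rg <- dist >= rs * 0.72 & dist < rs & mask
          hue[rg] <<- 0.05; sat[rg] <<- 0.85; val[rg] <<- 0.40
        }
        if (halo) {
          hl <- dist >= rs * 0.72 & dist < rs * 1.9 & mask
          hue[hl] <<- 0.14; sat[hl] <<- 0.85; val[hl] <<- 0.78
        }
      }
    }
    paint_web <- function(nseg, width) {
      for (s in seq_len(nseg)) {
        p1 <- in_leaf_pt()
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 0.25, 0.7)
        p2 <- p1 + len * c(cos(ang), sin(ang))
        wb <- seg_dist(u, v, p1, p2) < width & mask
        hue[wb] <<- 0.30; sat[wb] <<- 0.06; val[wb] <<- 0.78
      }
    }

    switch(spec$disorder,
      none = NULL,
      spots = paint_spots(sample(5:8, 1), 0.07, 0.12, ring = TRUE),
      halo_spots = paint_spots(sample(4:7, 1), 0.05, 0.08,
                               ring = FALSE, halo = TRUE),
      web = paint_web(sample(14:20, 1), 0.010),
      web_necrotic = {
        paint_web(sample(10:16, 1), 0.012)
        paint_spots(sample(2:4, 1), 0.09, 0.15, ring = FALSE)
      },
      chlorosis_veins_green = {
        chl <- mask & !vein
        hue[chl] <- 0.145; sat[chl] <- 0.75; val[chl] <- 0.72
      },
      chlorosis_uniform = {
        hue[mask] <- 0.150; sat[mask] <- 0.70
        val[mask] <- 0.70 - 0.06 * vein[mask]
      },
      chlorosis_marginal_necrosis = {
        chl <- mask & !vein
        hue[chl] <- 0.145; sat[chl] <- 0.75; val[chl] <- 0.72
        nec <- mask & d < 0.14
        hue[nec] <- 0.065; sat[nec] <- 0.78; val[nec] <- 0.42
      },
      mildew = {
        f1 <- smooth_field(u, v, 9)
        patch <- mask & f1 > 0.55
        hue[patch] <- 0.13; sat[patch] <- 0.80; val[patch] <- 0.74
        f2 <- smooth_field(u, v, 11)
        coat <- mask & f2 > 0.95
        hue[coat] <- 0.80; sat[coat] <- 0.28; val[coat] <- 0.55
      })

    # background: dark soil with clutter-scaled texture
    bg_hue <- 0.08 + 0.02 * smooth_field(x, y, 2)
    bg_sat <- 0.35 + 0.08 * smooth_field(x, y, 3)
    bg_val <- 0.16 + clutter * (0.05 * smooth_field(x, y, 6) +
                                  stats::runif(S * S, -0.03, 0.03))
    hue[!mask] <- bg_hue[!mask]
    sat[!mask] <- bg_sat[!mask]
    val[!mask] <- bg_val[!mask]

    hsv <- rbind(pmin(pmax(hue, 0), 0.999),
                 pmin(pmax(sat, 0.01), 1),
                 pmin(pmax(val, 0.02), 1))
    img <- hsv_to_rgb_mat(hsv, c(S, S, 3))

    jf <- 1 + stats::runif(1, -lighting, lighting)
    cast <- stats::runif(3, 0.98, 1.02)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * jf * cast[ch]
    clip255(img)
  })
}

#' Generate a synthetic leaf-disease dataset
#'
#' Writes `n_per_class` PNG images per class into
#' `out_dir/<class_name>/img_NNNN.png` and returns the scanned manifest.
#' The output is a pure function of the configuration: identical calls give
#' byte-identical images.
#'
#' @param out_dir output directory.
#' @param n_per_class images per class.
#' @param size image side in pixels.
#' @param seed base seed.
#' @param clutter,lighting see [generate_leaf_image()].
#' @param classes class names to generate (default all twelve).
#' @return a `leaf_manifest` of the generated images.
#' @export
generate_leaf_dataset <- function(out_dir, n_per_class = 20, size = 64,
                                  seed = 42, clutter = 0.5, lighting = 0.15,
                                  classes = leaf_class_names()) {
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    dir.create(file.path(out_dir, cl), recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n_per_class)) {
      img <- generate_leaf_image(cl, size = size,
                                 seed = derive_seed(seed, ci, k),
                                 clutter = clutter, lighting = lighting)
      write_image(img, file.path(out_dir, cl, sprintf("img_%04d.png", k)))
    }
  }
  m <- scan_image_folder(out_dir)
  md <- attr(m, "metadata")
  md$generator_seed <- seed
  md$n_per_class <- n_per_class
  md$size <- size
  new_manifest(m, metadata = md)
}

#' Per-class color-signature report
#'
#' For each class: mean hue and mean brightness of leaf pixels and the mean
#' overlay-pixel fraction, where leaf pixels are bright enough to be tissue
#' (value above the background band) and overlay pixels are leaf pixels
#' colored outside the healthy green-yellow band (gray webs/coatings, brown
#' lesions, purple mildew). The report is invariant to file order.
#'
#' @param x a dataset directory or a `leaf_manifest`.
#' @return data frame with one row per class: `class`, `n`, `mean_hue`,
#'   `mean_brightness`, `overlay_fraction`.
#' @export
class_signature_report <- function(x) {
  m <- if (inherits(x, "leaf_manifest")) x else scan_image_folder(x)
  classes <- manifest_classes(m)
  out <- lapply(classes, function(cl) {
    paths <- sort(m$path[m$label == cl])
    hs <- vs <- of <- numeric(length(paths))
    for (i in seq_along(paths)) {
      img <- read_image(paths[i])
      hsv <- rgb_to_hsv_mat(img)
      leaf <- hsv[3, ] > 0.32
      if (!any(leaf)) { hs[i] <- NA; vs[i] <- NA; of[i] <- NA; next }
      h <- hsv[1, leaf]; s <- hsv[2, leaf]
      hs[i] <- mean(h)
      vs[i] <- mean(hsv[3, leaf])
      of[i] <- mean(s < 0.18 | h < 0.11 | h > 0.55)
    }
    data.frame(class = cl, n = length(paths), mean_hue = mean(hs, na.rm = TRUE),
               mean_brightness = mean(vs, na.rm = TRUE),
               overlay_fraction = mean(of, na.rm = TRUE))
  })
  do.call(rbind, out)
}
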