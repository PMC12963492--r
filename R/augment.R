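# Leakage-free dataset engineering: stratified splitting of ORIGINAL images
# before any augmentation, then per-(class, split) quota augmentation whose
# products stay in their parent's split by construction. Geometric
# transforms use reflection padding and bilinear sampling.

#' Augmentation policy
#'
#' Transform families and ranges: rotation +-40 degrees, scaling
#' `[0.7, 1.3]`, horizontal and vertical flips, +-60 px translation,
#' brightness factor `[0.6, 1.5]`, contrast factor `[1.5, 2.3]`, hue shift
#' +-40 degrees (on the 0-360 hue circle), center zoom `[1.4, 1.8]`. Every
#' geometric operation uses reflection padding. Each augmented sample
#' composes `ops_per_image` transforms drawn without replacement.
#'
#' @param rotation,scale,translate_px,brightness,contrast,hue_deg,zoom
#'   ranges as length-2 vectors (or a single magnitude for symmetric
#'   ranges).
#' @param hflip,vflip allow the corresponding flip.
#' @param ops_per_image number of transforms composed per augmented sample.
#' @return object of class `augment_policy`.
#' @export
augment_policy <- function(rotation = c(-40, 40), scale = c(0.7, 1.3),
                           hflip = TRUE, vflip = TRUE,
                           translate_px = c(-60, 60),
                           brightness = c(0.6, 1.5), contrast = c(1.5, 2.3),
                           hue_deg = c(-40, 40), zoom = c(1.4, 1.8),
                           ops_per_image = 3) {
  structure(list(rotation = rotation, scale = scale, hflip = hflip,
                 vflip = vflip, translate_px = translate_px,
                 brightness = brightness, contrast = contrast,
                 hue_deg = hue_deg, zoom = zoom,
                 ops_per_image = as.integer(ops_per_image)),
            class = "augment_policy")
}

#' Split plan
#'
#' @param ratios train/val/test ratios (default 0.70/0.15/0.15).
#' @param quotas per-class post-augmentation quotas per split (default
#'   700/150/150, i.e. 1,000 images per class).
#' @param seed RNG seed for the split shuffle and augmentation parameters.
#' @return object of class `split_plan`.
#' @export
split_plan <- function(ratios = c(0.70, 0.15, 0.15),
                       quotas = c(train = 700, val = 150, test = 150),
                       seed = 42) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (any(quotas <= 0) || any(quotas != round(quotas)))
    stop("quotas must be positive integers")
  structure(list(ratios = ratios,
                 quotas = stats::setNames(as.integer(quotas),
                                          c("train", "val", "test")),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Stratified split of original images
#'
#' Within each class, records are shuffled by a seeded RNG and assigned
#' 70/15/15 (or the plan's ratios); on non-divisible class sizes val and
#' test get the floor and the remainder goes to train. Splitting happens
#' before augmentation, on original images only.
#'
#' @param manifest a `leaf_manifest` with all records `origin = original`,
#'   `split = unassigned`.
#' @param plan a [split_plan()].
#' @return the manifest with splits assigned.
#' @export
stratified_split <- function(manifest, plan = split_plan()) {
  if (any(manifest$origin != "original") || any(manifest$split != "unassigned"))
    stop("stratified_split expects unassigned original records")
  classes <- manifest_classes(manifest)
  split <- manifest$split
  with_seed(plan$seed, {
    for (cl in classes) {
      idx <- which(manifest$label == cl)
      n <- length(idx)
      if (n < 3)
        stop("class '", cl, "' has fewer than 3 images (", n, ")")
      n_val <- floor(plan$ratios[2] * n)
      n_test <- floor(plan$ratios[3] * n)
      n_train <- n - n_val - n_test
      perm <- sample(idx)
      split[perm[seq_len(n_train)]] <- "train"
      split[perm[n_train + seq_len(n_val)]] <- "val"
      split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
    }
  })
  manifest$split <- split
  md <- attr(manifest, "metadata")
  md$split_seed <- plan$seed
  new_manifest(manifest, metadata = md)
}

## ---- geometric warps -------------------------------------------------------

reflect_coord <- function(v, n) {
  # continuous reflect-101 fold into [0, n-1]
  if (n == 1) return(rep(0, length(v)))
  m <- 2 * (n - 1)
  v <- abs(v) %% m
  ifelse(v > n - 1, m - v, v)
}

# Sample img at continuous (row, col) source coordinates (0-based) with
# bilinear interpolation and reflection padding.
bilinear_sample <- function(img, src_r, src_c) {
  d <- dim(img)
  src_r <- reflect_coord(src_r, d[1])
  src_c <- reflect_coord(src_c, d[2])
  r0 <- floor(src_r); wr <- src_r - r0
  c0 <- floor(src_c); wc <- src_c - c0
  r1 <- pmin(r0 + 1, d[1] - 1)
  c1 <- pmin(c0 + 1, d[2] - 1)
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c1 + 1)
  i10 <- cbind(r1 + 1, c0 + 1); i11 <- cbind(r1 + 1, c1 + 1)
  out <- array(0, d)
  for (ch in 1:3) {
    x <- img[, , ch]
    v <- x[i00] * (1 - wr) * (1 - wc) + x[i01] * (1 - wr) * wc +
      x[i10] * wr * (1 - wc) + x[i11] * wr * wc
    out[, , ch] <- v
  }
  out
}

# Inverse-mapped affine warp about the image center: dst (r, c) samples
# src = M %*% (dst - center) + center + shift.
warp_affine <- function(img, M, shift = c(0, 0)) {
  d <- dim(img)
  ctr <- (d[1:2] - 1) / 2
  g <- expand.grid(r = seq_len(d[1]) - 1, c = seq_len(d[2]) - 1)
  rr <- g$r - ctr[1]; cc <- g$c - ctr[2]
  src_r <- M[1, 1] * rr + M[1, 2] * cc + ctr[1] + shift[1]
  src_c <- M[2, 1] * rr + M[2, 2] * cc + ctr[2] + shift[2]
  bilinear_sample(img, src_r, src_c)
}

aug_rotate <- function(img, degrees) {
  if (degrees == 0) return(img)
  th <- degrees * pi / 180
  # inverse rotation of the output grid
  warp_affine(img, matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2))
}

aug_scale <- function(img, factor) {
  if (factor == 1) return(img)
  warp_affine(img, diag(2) / factor)
}

aug_translate <- function(img, dr, dc) {
  if (dr == 0 && dc == 0) return(img)
  warp_affine(img, diag(2), shift = c(-dr, -dc))
}

aug_flip_h <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
aug_flip_v <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]

aug_brightness <- function(img, factor) clip255(img * factor)

aug_contrast <- function(img, factor) {
  m <- mean(img)
  clip255((img - m) * factor + m)
}

aug_zoom <- function(img, z) {
  # crop the central 1/z fraction and resize back: a center scale by z
  if (z == 1) return(img)
  warp_affine(img, diag(2) / z)
}

#' Apply a randomly parameterized augmentation
#'
#' Draws `ops_per_image` transform families without replacement from the
#' policy, samples each family's parameter uniformly within its range, and
#' composes them in the drawn order. Geometric operations use reflection
#' padding; the output has the input's size.
#'
#' @param img `(H, W, 3)` array in `[0, 255]`.
#' @param policy an [augment_policy()].
#' @param seed integer seed controlling both the transform draw and its
#'   parameters.
#' @return augmented `(H, W, 3)` array.
#' @export
apply_random_augment <- function(img, policy = augment_policy(), seed = 1) {
  assert_rgb(img)
  with_seed(seed, {
    ops <- c("rotation", "scale", "hflip", "vflip", "translate",
             "brightness", "contrast", "hue", "zoom")
    chosen <- sample(ops, min(policy$ops_per_image, length(ops)))
    for (op in chosen) {
      img <- switch(op,
        rotation = aug_rotate(img, stats::runif(1, policy$rotation[1],
                                                policy$rotation[2])),
        scale = aug_scale(img, stats::runif(1, policy$scale[1], policy$scale[2])),
        hflip = if (policy$hflip && stats::runif(1) < 0.5) aug_flip_h(img) else img,
        vflip = if (policy$vflip && stats::runif(1) < 0.5) aug_flip_v(img) else img,
        translate = aug_translate(img,
                                  round(stats::runif(1, policy$translate_px[1],
                                                     policy$translate_px[2])),
                                  round(stats::runif(1, policy$translate_px[1],
                                                     policy$translate_px[2]))),
        brightness = aug_brightness(img, stats::runif(1, policy$brightness[1],
                                                      policy$brightness[2])),
        contrast = aug_contrast(img, stats::runif(1, policy$contrast[1],
                                                  policy$contrast[2])),
        hue = shift_hue(img, stats::runif(1, policy$hue_deg[1],
                                          policy$hue_deg[2])),
        zoom = aug_zoom(img, stats::runif(1, policy$zoom[1], policy$zoom[2])))
    }
    img
  })
}

## ---- quota augmentation ----------------------------------------------------

#' Expand every (class, split) cell to its quota by augmentation
#'
#' Originals are always retained; augmented copies (origin `augmented`,
#' parent in the same split) are generated round-robin over the cell's
#' originals until the quota is met exactly. A cell already above quota is
#' an error — originals are never discarded silently. With materialization
#' (`out_dir` given) augmented PNGs are written to
#' `out_dir/<class>/<parent>__augNNN.png`; without it the augmented records
#' reference their parent's pixels plus a stored augmentation seed, and
#' [load_split()] synthesizes them on the fly.
#'
#' @param manifest a split `leaf_manifest`.
#' @param plan a [split_plan()] (quotas and seed).
#' @param policy an [augment_policy()].
#' @param out_dir directory for materialized augmented images, or `NULL`
#'   for the on-the-fly mode.
#' @return manifest including augmented records.
#' @export
augment_to_quota <- function(manifest, plan = split_plan(),
                             policy = augment_policy(), out_dir = NULL) {
  if (all(manifest$split == "unassigned"))
    stop("manifest must be split before augmentation")
  classes <- manifest_classes(manifest)
  splits <- c("train", "val", "test")
  new_recs <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    for (si in seq_along(splits)) {
      sp <- splits[si]
      cell <- manifest[manifest$label == cl & manifest$split == sp &
                         manifest$origin == "original", , drop = FALSE]
      quota <- plan$quotas[[sp]]
      if (nrow(cell) == 0)
        stop("empty (class, split) cell: ", cl, " / ", sp)
      if (nrow(cell) > quota)
        stop("cell ", cl, "/", sp, " holds ", nrow(cell),
             " originals, above the quota of ", quota,
             "; refusing to discard images")
      need <- quota - nrow(cell)
      if (need == 0) next
      parents <- rep(seq_len(nrow(cell)), length.out = need)
      for (j in seq_len(need)) {
        prec <- cell[parents[j], ]
        aug_seed <- derive_seed(plan$seed, ci, si, j)
        id <- sprintf("%s__aug%04d", prec$image_id, j)
        path <- prec$path
        if (!is.null(out_dir)) {
          img <- read_image(prec$path)
          img <- apply_random_augment(img, policy, aug_seed)
          path <- file.path(out_dir, cl,
                            sprintf("%s__aug%04d.png",
                                    basename(tools::file_path_sans_ext(prec$path)),
                                    j))
          write_image(img, path)
        }
        new_recs[[length(new_recs) + 1L]] <- data.frame(
          image_id = id, path = path, label = cl, split = sp,
          origin = "augmented", parent_id = prec$image_id,
          aug_seed = aug_seed, stringsAsFactors = FALSE)
      }
    }
  }
  recs <- rbind(as.data.frame(manifest),
                if (length(new_recs)) do.call(rbind, new_recs))
  md <- attr(manifest, "metadata")
  md$quotas <- paste(plan$quotas, collapse = "/")
  md$materialized <- !is.null(out_dir)
  new_manifest(recs, metadata = md)
}

#' Audit a manifest for split leakage
#'
#' Verifies that (a) every original is assigned to exactly one split, (b)
#' every augmented record's parent exists and lives in the same split, and
#' (c) optionally that each (class, split) cell meets its quota exactly.
#' The verdict is invariant to record order.
#'
#' @param manifest a split `leaf_manifest`.
#' @param quotas optional named quota vector (train/val/test) to check.
#' @return object of class `leakage_audit`: list with `pass` and a
#'   `violations` data frame (`rule`, `detail`).
#' @export
audit_leakage <- function(manifest, quotas = NULL) {
  v <- list()
  bad <- function(rule, detail)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, detail = detail)
  if (anyDuplicated(manifest$image_id))
    bad("unique_ids", paste("duplicated:",
        paste(unique(manifest$image_id[duplicated(manifest$image_id)]),
              collapse = ", ")))
  orig <- manifest[manifest$origin == "original", ]
  if (any(orig$split == "unassigned"))
    bad("originals_assigned",
        paste(sum(orig$split == "unassigned"), "originals unassigned"))
  aug <- manifest[manifest$origin == "augmented", ]
  if (nrow(aug) > 0) {
    pidx <- match(aug$parent_id, orig$image_id)
    missing <- is.na(pidx)
    if (any(missing))
      bad("parent_exists", paste("missing parents:",
          paste(aug$parent_id[missing], collapse = ", ")))
    same <- !missing & orig$split[pidx] == aug$split
    crossed <- !missing & !same
    if (any(crossed))
      bad("parent_split", paste("augmented records in a different split",
          "than their parent:", paste(aug$image_id[crossed], collapse = ", ")))
  }
  if (!is.null(quotas)) {
    tab <- table(manifest$label, manifest$split)
    for (sp in names(quotas)) {
      if (!sp %in% colnames(tab)) {
        bad("quota", paste("split missing entirely:", sp))
        next
      }
      off <- tab[, sp] != quotas[[sp]]
      if (any(off))
        bad("quota", paste0(sp, " cells off quota: ",
            paste(rownames(tab)[off], "=", tab[off, sp], collapse = ", ")))
    }
  }
  violations <- if (length(v)) do.call(rbind, v)
    else data.frame(rule = character(0), detail = character(0))
  structure(list(pass = nrow(violations) == 0, violations = violations),
            class = "leakage_audit")
}

#' @export
print.leakage_audit <- function(x, ...) {
  cat("Leakage audit:", if (x$pass) "PASS" else "FAIL", "\n")
  if (!x$pass) print.data.frame(x$violations, row.names = FALSE)
  invisible(x)
}
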