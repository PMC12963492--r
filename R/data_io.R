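# Dataset manifests, image and configuration I/O. Every downstream module
# consumes manifests, never raw folders, which keeps split/augmentation
# provenance auditable: each record carries its split, origin (original or
# augmented) and the id of the original it derives from.

MANIFEST_COLUMNS <- c("image_id", "path", "label", "split", "origin",
                      "parent_id", "aug_seed")
VALID_SPLITS <- c("train", "val", "test", "unassigned")

#' Read an image file as an 8-bit RGB array
#'
#' PNG (and JPEG, when the jpeg package is installed) images are decoded to
#' a numeric `(H, W, 3)` array in `[0, 255]`. Grayscale images are
#' replicated to three channels; an alpha channel is discarded.
#'
#' @param path image file path.
#' @return numeric array `(H, W, 3)`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg") &&
             requireNamespace("jpeg", quietly = TRUE)) {
    jpeg::readJPEG(path)
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an 8-bit RGB array as PNG
#'
#' @param img numeric `(H, W, 3)` array in `[0, 255]`.
#' @param path output path (created recursively).
#' @export
write_image <- function(img, path) {
  assert_rgb(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(clip255(img) / 255, path)
  invisible(path)
}

## ---- manifest --------------------------------------------------------------

new_manifest <- function(records, metadata = list()) {
  stopifnot(all(MANIFEST_COLUMNS %in% names(records)))
  records <- as.data.frame(records)[, MANIFEST_COLUMNS]
  rownames(records) <- NULL
  if (anyDuplicated(records$image_id))
    stop("duplicate image_id values in manifest")
  if (!all(records$split %in% VALID_SPLITS))
    stop("invalid split value in manifest")
  structure(records,
            classes = sort(unique(records$label)),
            metadata = metadata,
            class = c("leaf_manifest", "data.frame"))
}

manifest_classes <- function(m) attr(m, "classes")

#' @export
print.leaf_manifest <- function(x, ...) {
  cat(sprintf("Dataset manifest: %d records, %d classes\n",
              nrow(x), length(attr(x, "classes"))))
  tab <- table(x$label, x$split)
  print(tab)
  invisible(x)
}

#' Scan a class-per-subdirectory image folder into a manifest
#'
#' One record per decodable image; `label` is the subdirectory name, split
#' is `unassigned`, origin `original`, `parent_id` the record's own id.
#' Ordering is lexicographic by path, so two scans of the same folder are
#' identical. Undecodable images are skipped with a warning and counted in
#' the manifest metadata; empty subdirectories contribute no class.
#'
#' @param root directory containing one subdirectory per class.
#' @return a `leaf_manifest`.
#' @export
scan_image_folder <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(dirs) == 0) stop("dataset root has no class subdirectories: ", root)
  recs <- list()
  skipped <- 0L
  for (d in dirs) {
    files <- sort(list.files(d, pattern = "(?i)\\.(png|jpe?g)$",
                             full.names = TRUE))
    lab <- basename(d)
    if (length(files) == 0) {
      warning("empty class directory skipped: ", lab)
      next
    }
    for (f in files) {
      ok <- tryCatch({ read_image(f); TRUE },
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) {
        warning("undecodable image skipped: ", f)
        skipped <- skipped + 1L
        next
      }
      id <- paste0(lab, "/", tools::file_path_sans_ext(basename(f)))
      recs[[length(recs) + 1L]] <- data.frame(
        image_id = id, path = f, label = lab, split = "unassigned",
        origin = "original", parent_id = id, aug_seed = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) stop("no decodable images under ", root)
  new_manifest(do.call(rbind, recs),
               metadata = list(root = root, skipped = skipped))
}

#' Write / read a manifest as UTF-8 CSV
#'
#' The file is a plain CSV with a header row, preceded by `#!`-prefixed
#' metadata lines, so that leakage audits can be performed by eye or with
#' standard text tools. Round-trips are lossless (including non-ASCII class
#' names).
#'
#' @param manifest a `leaf_manifest`.
#' @param path file path.
#' @return `read_manifest` returns a `leaf_manifest`; `write_manifest`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  md <- attr(manifest, "metadata")
  for (k in names(md))
    writeLines(sprintf("#! %s: %s", k, paste(md[[k]], collapse = " ")), con)
  utils::write.csv(as.data.frame(manifest), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_md <- startsWith(lines, "#!")
  md_lines <- lines[is_md]
  body <- lines[!is_md]
  metadata <- list()
  for (l in md_lines) {
    kv <- sub("^#! *", "", l)
    k <- sub(":.*$", "", kv)
    metadata[[k]] <- utils::type.convert(trimws(sub("^[^:]*: *", "", kv)),
                                         as.is = TRUE)
  }
  df <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE,
                    colClasses = c(aug_seed = "integer")),
    error = function(e) stop("malformed manifest: ", conditionMessage(e)))
  if (!identical(sort(names(df)), sort(MANIFEST_COLUMNS)))
    stop("manifest has wrong columns: ", paste(names(df), collapse = ", "))
  nf <- which(!stats::complete.cases(df[c("image_id", "path", "label", "split")]) |
                !nzchar(df$image_id) | !nzchar(df$path) | !nzchar(df$label))
  if (length(nf) > 0)
    stop("malformed manifest row(s): ", paste(nf, collapse = ", "))
  new_manifest(df, metadata = metadata)
}

## ---- run configuration -----------------------------------------------------

#' Run configuration
#'
#' Bundles the experiment hyperparameters: 248 px inputs, batch size 32, up
#' to 50 epochs of Adam (betas 0.9/0.999) with step-decayed learning rate
#' from 1e-3 to 1e-4, early-stopping patience 10, seed 42, 5-fold
#' cross-validation, 70/15/15 split ratios and per-class quotas
#' 700/150/150.
#'
#' @param image_size,batch_size,max_epochs,initial_lr,final_lr,betas,patience,seed,k_folds,split_ratios,quotas
#'   see Details; defaults reproduce the reference training protocol.
#' @param monitor early-stopping monitor: maximize validation `"macro_f1"`
#'   (default) or minimize validation `"loss"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(image_size = 248, batch_size = 32, max_epochs = 50,
                       initial_lr = 1e-3, final_lr = 1e-4,
                       betas = c(0.9, 0.999), patience = 10, seed = 42,
                       k_folds = 5, split_ratios = c(0.70, 0.15, 0.15),
                       quotas = c(train = 700, val = 150, test = 150),
                       monitor = c("macro_f1", "loss")) {
  if (abs(sum(split_ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (any(quotas <= 0) || any(quotas != round(quotas)))
    stop("quotas must be positive integers")
  structure(list(image_size = as.integer(image_size),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 initial_lr = initial_lr, final_lr = final_lr,
                 betas = betas, patience = as.integer(patience),
                 seed = as.integer(seed), k_folds = as.integer(k_folds),
                 split_ratios = split_ratios,
                 quotas = stats::setNames(as.integer(quotas),
                                          c("train", "val", "test")),
                 monitor = match.arg(monitor)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  for (k in c("quotas", "split_ratios", "betas"))
    if (!is.null(v[[k]])) v[[k]] <- unlist(v[[k]])
  do.call(run_config, v)
}
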