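# Explainability: Grad-CAM spatial attributions from the class logit's
# gradient at a convolutional stage, LIME superpixel surrogates, GAP-layer
# embeddings, t-SNE projection with per-class cluster statistics and
# silhouette, and the misclassification failure panel.

#' Grad-CAM class-activation map
#'
#' Channel weights are the spatially averaged gradients of the target
#' class's pre-softmax logit with respect to the target stage's
#' activations, `alpha_k = 1/Z sum_ij d y_c / d A_k(i,j)`; the map is
#' `ReLU(sum_k alpha_k A_k)`, max-normalized to `[0, 1]` (an all-zero map
#' stays zero). The map is invariant to positive rescaling of the logit
#' gradient.
#'
#' @param model an `lsetnet_model`.
#' @param image standardized input `(H, W, 3)` (or `(H, W, 3, 1)`).
#' @param target_class integer class index; defaults to the predicted
#'   class.
#' @param target_layer stage name with spatial extent (default
#'   `"extra_conv"`, the last convolutional map before the transformer;
#'   `"transformer"` uses the reshaped transformer output).
#' @return object of class `explanation_map`: the map at target-layer
#'   resolution, an upsampled `overlay` at image resolution, the target
#'   class, predicted probabilities, and `mean_intensity` / `top5_mean`
#'   statistics of the normalized map.
#' @export
grad_cam <- function(model, image, target_class = NULL,
                     target_layer = "extra_conv") {
  if (length(dim(image)) == 3) dim(image) <- c(dim(image), 1L)
  if (!target_layer %in% names(model$stages))
    stop("unknown target layer: ", target_layer)
  if (model$stages[[target_layer]]$spec$kind %in% c("gap", "dense_head"))
    stop("target layer has no spatial extent: ", target_layer)
  fw <- model_forward(model, image, training = FALSE, record = TRUE)
  probs <- drop(fw$probs)
  if (is.null(target_class)) target_class <- which.max(probs)
  dlog <- matrix(0, model$config$num_classes, 1)
  dlog[target_class, 1] <- 1
  bw <- model_backward(model, fw$caches, dlog, collect_stage_grads = TRUE)
  A <- fw$acts[[target_layer]]
  dA <- bw$stage_grads[[target_layer]]
  d <- dim(A)
  alpha <- gap(dA)                       # 1/Z sum_ij dY/dA, per channel
  map <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) map <- map + alpha[k] * A[, , k, 1]
  map <- pmax(map, 0)
  if (max(map) > 0) map <- map / max(map)
  overlay <- resize_map(map, dim(image)[1:2])
  st <- heatmap_stats(map)
  structure(list(map = map, overlay = overlay,
                 target_class = target_class, probs = probs,
                 target_layer = target_layer,
                 mean_intensity = st[["mean_intensity"]],
                 top5_mean = st[["top5_mean"]]),
            class = "explanation_map")
}

resize_map <- function(map, size) {
  img <- array(rep(map, 3), c(dim(map), 3))
  resize_image(img, size)[, , 1]
}

#' Heatmap intensity statistics
#'
#' Arithmetic mean of a normalized attribution map and the mean of its top
#' 5% most active pixels (`ceiling(0.05 * H * W)` values).
#'
#' @param map numeric matrix (or vector) of normalized intensities.
#' @return named vector `mean_intensity`, `top5_mean`.
#' @export
heatmap_stats <- function(map) {
  v <- as.numeric(map)
  ntop <- ceiling(0.05 * length(v))
  top <- sort(v, decreasing = TRUE)[seq_len(ntop)]
  c(mean_intensity = mean(v), top5_mean = mean(top))
}

## ---- LIME -------------------------------------------------------------------

#' SLIC-style superpixel segmentation
#'
#' K-means over (row, col, L, a, b) features with a locality weight, giving
#' compact approximately-equal superpixels.
#'
#' @param img `(H, W, 3)` array in `[0, 255]`.
#' @param n_segments requested number of superpixels.
#' @param compactness spatial-weight multiplier; larger gives squarer
#'   segments.
#' @param seed k-means seed.
#' @return integer matrix `(H, W)` of segment ids `1..M`.
#' @export
slic_segments <- function(img, n_segments = 100, compactness = 1, seed = 42) {
  d <- dim(img)
  g <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]))
  lab <- grDevices::convertColor(matrix(img, ncol = 3) / 255,
                                 from = "sRGB", to = "Lab")
  sp_scale <- compactness * 100 / max(d[1:2])
  feat <- cbind(g$r * sp_scale, g$c * sp_scale, lab)
  km <- with_seed(seed,
    stats::kmeans(feat, centers = n_segments, iter.max = 30, nstart = 1))
  matrix(km$cluster, d[1], d[2])
}

#' LIME surrogate explanation
#'
#' Segments the image into superpixels, samples binary presence masks,
#' builds perturbed images in which absent segments are replaced by their
#' mean color, weights each mask by `pi(z) = exp(-D(z, 1)^2 / width^2)`
#' with cosine distance `D`, and fits a ridge-penalized weighted linear
#' surrogate `g(z) = w0 + sum_i w_i z_i` to the black-box probabilities of
#' the explained class. Reports the five largest-weight segments and the
#' weighted R-squared fidelity of the surrogate.
#'
#' @param predict_fn `function(image) -> probability vector`.
#' @param image `(H, W, 3)` array in `[0, 255]`.
#' @param n_segments number of superpixels (>= 2).
#' @param n_samples number of sampled masks (ignored when `enumerate`).
#' @param kernel_width proximity kernel width on cosine distance.
#' @param ridge ridge penalty on segment weights (the intercept is
#'   unpenalized); 0 gives plain weighted least squares.
#' @param seed RNG seed for mask sampling.
#' @param target_class class index to explain; defaults to the class
#'   predicted for the unperturbed image.
#' @param enumerate enumerate all `2^M` masks instead of sampling (exact;
#'   only for small `M`).
#' @return object of class `surrogate_explanation`: `segments` map,
#'   `weights` (intercept first), `top5` data frame, `fidelity` (weighted
#'   R-squared), `target_class`.
#' @export
lime_explain <- function(predict_fn, image, n_segments = 100,
                         n_samples = 1000, kernel_width = 0.25, ridge = 1,
                         seed = 42, target_class = NULL, enumerate = FALSE) {
  if (n_segments < 2) stop("need at least 2 segments")
  seg <- slic_segments(image, n_segments, seed = seed)
  M <- max(seg)
  f0 <- predict_fn(image)
  if (is.null(target_class)) target_class <- which.max(f0)
  # per-segment mean color fill
  d <- dim(image)
  px <- matrix(image, ncol = 3)
  segv <- as.vector(seg)
  fill <- apply(px, 2, function(ch) stats::ave(ch, segv))
  Z <- if (enumerate) {
    as.matrix(do.call(expand.grid, rep(list(c(1, 0)), M)))
  } else {
    with_seed(seed, matrix(stats::rbinom(n_samples * M, 1, 0.5),
                           n_samples, M))
  }
  Z[1, ] <- 1   # always include the unperturbed instance
  y <- numeric(nrow(Z))
  for (s in seq_len(nrow(Z))) {
    if (all(Z[s, ] == 1)) { y[s] <- f0[target_class]; next }
    off <- which(Z[s, ] == 0)
    pert <- px
    sel <- segv %in% off
    pert[sel, ] <- fill[sel, ]
    y[s] <- predict_fn(array(pert, d))[target_class]
  }
  # cosine distance to the all-ones mask
  on <- rowSums(Z)
  D <- 1 - on / (sqrt(on) * sqrt(M) + 1e-12)
  w_pi <- exp(-D^2 / kernel_width^2)
  X <- cbind(1, Z)
  A <- t(X * w_pi) %*% X + ridge * diag(c(0, rep(1, M)))
  coef <- solve(A, t(X * w_pi) %*% y)
  yhat <- X %*% coef
  ybar <- sum(w_pi * y) / sum(w_pi)
  ss_res <- sum(w_pi * (y - yhat)^2)
  ss_tot <- sum(w_pi * (y - ybar)^2)
  fidelity <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  wseg <- coef[-1]
  top <- order(wseg, decreasing = TRUE)[seq_len(min(5, M))]
  structure(list(segments = seg,
                 weights = as.numeric(coef),
                 top5 = data.frame(segment = top, weight = wseg[top]),
                 fidelity = fidelity,
                 target_class = target_class,
                 n_samples = nrow(Z)),
            class = "surrogate_explanation")
}

#' @export
print.surrogate_explanation <- function(x, ...) {
  cat(sprintf("LIME surrogate for class %d (fidelity R^2 = %.3f, %d masks)\n",
              x$target_class, x$fidelity, x$n_samples))
  cat("Top 5 segments:\n")
  print.data.frame(x$top5, row.names = FALSE)
  invisible(x)
}

## ---- embeddings and t-SNE ---------------------------------------------------

#' Extract GAP-layer embeddings
#'
#' The global-average-pooled feature vector feeding the dense head, one row
#' per image.
#'
#' @param model an `lsetnet_model`.
#' @param images array `(H, W, 3, N)`.
#' @param batch_size forward batch size.
#' @return `N x C` matrix.
#' @export
extract_embeddings <- function(model, images, batch_size = 64) {
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  N <- dim(images)[4]
  C <- model$config$channels[4]
  out <- matrix(NA_real_, N, C)
  for (s in seq(1, N, by = batch_size)) {
    e <- min(s + batch_size - 1, N)
    fw <- model_forward(model, images[, , , s:e, drop = FALSE],
                        training = FALSE, record = TRUE)
    out[s:e, ] <- t(fw$acts$gap)
  }
  out
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `sum_i p_i log(p_i / q_i)` over entries with `p_i > 0`; zero when the
#' distributions are equal.
#'
#' @param p,q non-negative arrays of equal shape summing to 1.
#' @return scalar divergence (nats).
#' @export
kl_divergence <- function(p, q) {
  sel <- p > 0
  sum(p[sel] * log(p[sel] / pmax(q[sel], 1e-300)))
}

tsne_p_matrix <- function(X, perplexity) {
  N <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, N, N)
  logU <- log(perplexity)
  for (i in seq_len(N)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- p + 1e-12
      p <- p / max(sp, 1e-300)
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * N)
  pmax(P, 1e-12)
}

#' t-SNE projection with cluster statistics
#'
#' Exact (quadratic-cost) t-SNE: Gaussian input similarities calibrated per
#' point to the target perplexity, Student-t output similarities, and
#' gradient descent with momentum and early exaggeration minimizing
#' `KL(P || Q)`. On top of the 2-D embedding, per-class centroids and
#' per-axis spreads and the Euclidean silhouette score are reported.
#'
#' @param features `N x D` numeric matrix (e.g. [extract_embeddings()]).
#' @param labels class labels per row.
#' @param perplexity Gaussian-neighborhood size; requires
#'   `N >= 3 * perplexity + 2`.
#' @param seed RNG seed for the initialization.
#' @param max_iter gradient-descent iterations.
#' @return object of class `projection_result`: `coords` (`N x 2`),
#'   `clusters` (per-class centroid and X/Y spread), `silhouette`,
#'   `kl_divergence`.
#' @export
project_tsne <- function(features, labels, perplexity = 30, seed = 42,
                         max_iter = 1000) {
  X <- as.matrix(features)
  N <- nrow(X)
  if (N < 3 * perplexity + 2)
    stop("too few samples (", N, ") for perplexity ", perplexity)
  P <- tsne_p_matrix(X, perplexity)
  Y <- with_seed(seed, matrix(stats::rnorm(N * 2, sd = 1e-4), N, 2))
  G <- matrix(0, N, 2)
  gains <- matrix(1, N, 2)
  eta <- 200
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 100) P * 12 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= 250) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8), 0.01)
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  sumY <- rowSums(Y^2)
  num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
  diag(num) <- 0
  Q <- pmax(num / sum(num), 1e-12)
  kl <- kl_divergence(P, Q)
  labs <- as.character(labels)
  cl <- lapply(sort(unique(labs)), function(g) {
    yy <- Y[labs == g, , drop = FALSE]
    data.frame(class = g, n = nrow(yy),
               centroid_x = mean(yy[, 1]), centroid_y = mean(yy[, 2]),
               spread_x = stats::sd(yy[, 1]), spread_y = stats::sd(yy[, 2]))
  })
  sil <- if (length(unique(labs)) > 1) {
    s <- cluster::silhouette(as.integer(factor(labs)), stats::dist(Y))
    mean(s[, "sil_width"])
  } else NA_real_
  structure(list(coords = Y, clusters = do.call(rbind, cl),
                 silhouette = sil, kl_divergence = kl,
                 perplexity = perplexity),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("t-SNE projection: %d points, KL = %.4f, silhouette = %.3f\n",
              nrow(x$coords), x$kl_divergence, x$silhouette))
  print.data.frame(x$clusters, row.names = FALSE)
  invisible(x)
}

## ---- failure panel ----------------------------------------------------------

#' Misclassification failure panel
#'
#' For every misclassified sample: true and predicted labels, the predicted
#' class's probability, the full probability vector, and a Grad-CAM overlay
#' for the predicted class. A perfect model yields an empty panel.
#'
#' @param model an `lsetnet_model`.
#' @param data list with `x` (standardized stack) and `y` (integer labels),
#'   as from [load_split()].
#' @param classes class names.
#' @param explain compute Grad-CAM overlays (set `FALSE` to skip).
#' @param target_layer Grad-CAM target stage.
#' @return object of class `failure_panel`: a list of per-failure entries.
#' @export
failure_panel <- function(model, data, classes, explain = TRUE,
                          target_layer = "extra_conv") {
  probs <- predict(model, data$x)
  pred <- max.col(probs, ties.method = "first")
  bad <- which(pred != data$y)
  entries <- lapply(bad, function(i) {
    e <- list(index = i,
              true_label = classes[data$y[i]],
              predicted_label = classes[pred[i]],
              probability = probs[i, pred[i]],
              class_probs = stats::setNames(probs[i, ], classes))
    if (explain)
      e$grad_cam <- grad_cam(model, data$x[, , , i, drop = FALSE],
                             target_class = pred[i],
                             target_layer = target_layer)
    e
  })
  structure(list(entries = entries, n_evaluated = length(data$y)),
            class = "failure_panel")
}

#' @export
print.failure_panel <- function(x, ...) {
  cat(sprintf("Failure panel: %d misclassified of %d samples\n",
              length(x$entries), x$n_evaluated))
  for (e in x$entries)
    cat(sprintf("  [%d] true %s -> predicted %s (p = %.3f)\n",
                e$index, e$true_label, e$predicted_label, e$probability))
  invisible(x)
}
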