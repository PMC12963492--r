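# Shared fixtures and independent oracles. Datasets are generated
# programmatically (and memoized per session) under tempdir().

.fixture_env <- new.env(parent = emptyenv())

# Memoized synthetic dataset: generated once per (n, size, seed) per session.
fixture_dataset <- function(n_per_class = 10, size = 32, seed = 42) {
  key <- sprintf("ds_%d_%d_%d", n_per_class, size, seed)
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), key)
    m <- generate_leaf_dataset(dir, n_per_class = n_per_class, size = size,
                               seed = seed)
    .fixture_env[[key]] <- m
  }
  .fixture_env[[key]]
}

# A fabricated manifest (no files on disk) for split/fold arithmetic tests.
fake_manifest <- function(n_per_class, classes = leaf_class_names(),
                          split = "unassigned") {
  recs <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(image_id = sprintf("%s/img_%04d", cl, seq_len(n_per_class)),
               path = sprintf("%s/img_%04d.png", cl, seq_len(n_per_class)),
               label = cl, split = split, origin = "original",
               parent_id = sprintf("%s/img_%04d", cl, seq_len(n_per_class)),
               aug_seed = NA_integer_, stringsAsFactors = FALSE)
  }))
  lsetnet:::new_manifest(recs)
}

random_image <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3, 0, 255), c(h, w, 3))
}

# Independent brute-force multi-head attention oracle: explicit loops over
# heads and positions, no matrix shortcuts shared with the implementation.
naive_mhsa <- function(tokens, weights, heads) {
  N <- nrow(tokens); d <- ncol(tokens); dk <- d / heads
  proj <- function(wb) {
    out <- matrix(0, N, d)
    for (i in 1:N) for (j in 1:d) {
      s <- wb$b[j]
      for (l in 1:d) s <- s + tokens[i, l] * wb$W[j, l]
      out[i, j] <- s
    }
    out
  }
  Q <- proj(weights$Wq); K <- proj(weights$Wk); V <- proj(weights$Wv)
  Z <- matrix(0, N, d)
  for (h in 1:heads) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    for (i in 1:N) {
      logits <- numeric(N)
      for (j in 1:N) logits[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dk)
      a <- exp(logits - max(logits)); a <- a / sum(a)
      for (cc in cols) Z[i, cc] <- sum(a * V[, cc])
    }
  }
  out <- matrix(0, N, d)
  for (i in 1:N) for (j in 1:d)
    out[i, j] <- weights$Wo$b[j] + sum(Z[i, ] * weights$Wo$W[j, ])
  out
}

# Tiny network configuration used wherever a real forward/backward pass is
# needed but size does not matter.
tiny_config <- function(num_classes = 3) {
  lsetnet_config(input_size = 32, channels = c(4, 8, 12, 16),
                 num_classes = num_classes, heads = 2, se_reduction = 4,
                 head_hidden = 10, dropout = 0)
}

# Run the post-target tail of a model (stages after `after`) on a modified
# activation; returns the logit of `class_idx`. Used as the numerical
# oracle for Grad-CAM gradients.
tail_logit <- function(model, A, after = "extra_conv", class_idx = 1) {
  nms <- names(model$stages)
  start <- which(nms == after) + 1
  x <- A
  logits <- NULL
  for (i in start:length(nms)) {
    r <- lsetnet:::stage_forward(model$stages[[i]], x, training = FALSE)
    x <- r$out
    if (!is.null(r$logits)) logits <- r$logits
  }
  logits[class_idx, 1]
}
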