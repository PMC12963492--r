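# LSeTNet: declarative stage list -> built network -> parameter report.
#
# The network is a lightweight CNN stem, three residual blocks with
# squeeze-and-excitation channel recalibration, an extra convolutional
# block, a single post-norm transformer encoder block on the final spatial
# grid, global average pooling and a dense softmax head. Downsampling is by
# 2x2 max pooling with floor division, giving 248 -> 124 -> 62 -> 31 -> 15
# -> 7 at full size.

#' Declarative LSeTNet model configuration
#'
#' Builds the ordered stage list realizing the architecture:
#' `conv_bn(c1) -> se_pool(c1) -> residual_se(c1 -> c2) -> residual_se(c2 ->
#' c3) -> residual_se(c3 -> c4) -> extra_conv(c4) -> transformer(c4) -> gap
#' -> dense_head`. The transformer's model width equals the final channel
#' count; its feed-forward hidden width equals the model width and both
#' layer norms carry affine parameters.
#'
#' @param input_size input image side in pixels (images are square).
#' @param channels four increasing channel counts, stem first. The defaults
#'   give the full-size network; `c(16, 32, 64, 128)` gives the
#'   width-reduced variant used for desk-scale training.
#' @param num_classes number of output classes.
#' @param heads attention heads; must divide the final channel count. Head
#'   count does not change the parameter count.
#' @param se_reduction squeeze-and-excitation bottleneck ratio (hidden width
#'   `max(1, C / se_reduction)`).
#' @param head_hidden hidden width of the dense head.
#' @param dropout dropout rate in the dense head (training only).
#' @param positional_encoding if `TRUE`, add learned additive positional
#'   embeddings to the tokens before attention (off by default; the
#'   architecture does not use them).
#' @return an object of class `lsetnet_config`.
#' @export
lsetnet_config <- function(input_size = 248,
                           channels = c(64, 128, 256, 512),
                           num_classes = 12,
                           heads = 8,
                           se_reduction = 16,
                           head_hidden = 1024,
                           dropout = 0.5,
                           positional_encoding = FALSE) {
  stopifnot(length(channels) == 4, all(diff(channels) > 0),
            channels[4] %% heads == 0, num_classes >= 2, input_size >= 32)
  sizes <- as.integer(input_size)
  for (i in 1:5) sizes <- c(sizes, sizes[length(sizes)] %/% 2L)
  if (sizes[length(sizes)] < 1)
    stop("input_size too small for the five-pool downsampling schedule")
  cfg <- list(input_size = as.integer(input_size),
              channels = as.integer(channels),
              num_classes = as.integer(num_classes),
              heads = as.integer(heads),
              se_reduction = as.integer(se_reduction),
              head_hidden = as.integer(head_hidden),
              dropout = dropout,
              positional_encoding = positional_encoding,
              schedule = sizes,
              d_model = as.integer(channels[4]))
  cfg$stages <- lsetnet_stage_specs(cfg)
  class(cfg) <- "lsetnet_config"
  cfg
}

lsetnet_stage_specs <- function(cfg) {
  ch <- cfg$channels
  list(
    stem = list(kind = "conv_bn", in_channels = 3L, out_channels = ch[1], kernel = 3L),
    se_pool = list(kind = "se_pool", in_channels = ch[1], out_channels = ch[1],
                   se_reduction = cfg$se_reduction),
    res1 = list(kind = "residual_se", in_channels = ch[1], out_channels = ch[2],
                kernel = 3L, se_reduction = cfg$se_reduction),
    res2 = list(kind = "residual_se", in_channels = ch[2], out_channels = ch[3],
                kernel = 3L, se_reduction = cfg$se_reduction),
    res3 = list(kind = "residual_se", in_channels = ch[3], out_channels = ch[4],
                kernel = 3L, se_reduction = cfg$se_reduction),
    extra_conv = list(kind = "extra_conv", in_channels = ch[4], out_channels = ch[4],
                      kernel = 3L, se_reduction = cfg$se_reduction),
    transformer = list(kind = "transformer", in_channels = ch[4],
                       out_channels = ch[4], heads = cfg$heads,
                       ffn_width = cfg$d_model),
    gap = list(kind = "gap", in_channels = ch[4], out_channels = ch[4]),
    head = list(kind = "dense_head", in_channels = ch[4],
                out_channels = cfg$num_classes, hidden = cfg$head_hidden,
                dropout = cfg$dropout)
  )
}

#' Build an LSeTNet model
#'
#' Initializes all weights (He initialization for convolutions and ReLU
#' dense layers, Glorot for projections, unit-gamma/zero-beta batch norm)
#' under the given seed. Two builds with the same seed are identical.
#'
#' @param config a [lsetnet_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `lsetnet_model`.
#' @export
build_lsetnet <- function(config = lsetnet_config(), seed = 42) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stages <- lapply(config$stages, init_stage, cfg = config)
  structure(list(config = config, stages = stages, seed = seed),
            class = "lsetnet_model")
}

init_stage <- function(spec, cfg) {
  p <- switch(spec$kind,
    conv_bn = list(conv = init_conv(spec$kernel, spec$in_channels, spec$out_channels),
                   bn = init_bn(spec$out_channels)),
    se_pool = list(se = init_se(spec$in_channels, spec$se_reduction)),
    residual_se = {
      pr <- list(conv1 = init_conv(spec$kernel, spec$in_channels, spec$out_channels),
                 bn1 = init_bn(spec$out_channels),
                 conv2 = init_conv(spec$kernel, spec$out_channels, spec$out_channels),
                 bn2 = init_bn(spec$out_channels),
                 se = init_se(spec$out_channels, spec$se_reduction))
      if (spec$in_channels != spec$out_channels) {
        pr$conv_sc <- init_conv(1L, spec$in_channels, spec$out_channels)
        pr$bn_sc <- init_bn(spec$out_channels)
      }
      pr
    },
    extra_conv = list(conv = init_conv(spec$kernel, spec$in_channels, spec$out_channels),
                      bn = init_bn(spec$out_channels),
                      se = init_se(spec$out_channels, spec$se_reduction)),
    transformer = {
      pt <- list(mhsa = init_mhsa(spec$in_channels),
                 ln1 = init_ln(spec$in_channels),
                 ffn1 = init_dense(spec$in_channels, spec$ffn_width, "he"),
                 ffn2 = init_dense(spec$ffn_width, spec$in_channels, "glorot"),
                 ln2 = init_ln(spec$in_channels))
      if (isTRUE(cfg$positional_encoding)) {
        Tn <- (cfg$schedule[6])^2
        pt$pos <- matrix(stats::rnorm(Tn * spec$in_channels, sd = 0.02),
                         Tn, spec$in_channels)
      }
      pt
    },
    gap = list(),
    dense_head = list(fc1 = init_dense(spec$in_channels, spec$hidden, "he"),
                      fc2 = init_dense(spec$hidden, spec$out_channels, "glorot")),
    stop("unknown stage kind: ", spec$kind))
  buffers <- switch(spec$kind,
    conv_bn = list(bn = init_bn_buffers(spec$out_channels)),
    residual_se = {
      b <- list(bn1 = init_bn_buffers(spec$out_channels),
                bn2 = init_bn_buffers(spec$out_channels))
      if (spec$in_channels != spec$out_channels)
        b$bn_sc <- init_bn_buffers(spec$out_channels)
      b
    },
    extra_conv = list(bn = init_bn_buffers(spec$out_channels)),
    list())
  list(spec = spec, params = p, buffers = buffers)
}

## ---- stage forward / backward ---------------------------------------------

stage_forward <- function(st, x, training) {
  p <- st$params; buf <- st$buffers
  switch(st$spec$kind,
    conv_bn = {
      a <- conv_forward(x, p$conv)
      bn <- bn_forward(a, p$bn, buf$bn, training)
      r <- relu_forward(bn$out)
      list(out = r$out, buffers = list(bn = bn$buffers),
           cache = list(x = x, bn = bn$cache, relu = r$cache))
    },
    se_pool = {
      se <- se_forward(x, p$se)
      mp <- maxpool_forward(se$out)
      list(out = mp$out, buffers = buf,
           cache = list(se = se$cache, mp = mp$cache))
    },
    residual_se = {
      a1 <- conv_forward(x, p$conv1)
      b1 <- bn_forward(a1, p$bn1, buf$bn1, training)
      r1 <- relu_forward(b1$out)
      a2 <- conv_forward(r1$out, p$conv2)
      b2 <- bn_forward(a2, p$bn2, buf$bn2, training)
      r2 <- relu_forward(b2$out)
      se <- se_forward(r2$out, p$se)
      if (!is.null(p$conv_sc)) {
        asc <- conv_forward(x, p$conv_sc)
        bsc <- bn_forward(asc, p$bn_sc, buf$bn_sc, training)
        shortcut <- bsc$out
        sc_cache <- list(bn = bsc$cache)
        nbuf <- list(bn1 = b1$buffers, bn2 = b2$buffers, bn_sc = bsc$buffers)
      } else {
        shortcut <- x
        sc_cache <- NULL
        nbuf <- list(bn1 = b1$buffers, bn2 = b2$buffers)
      }
      mp <- maxpool_forward(shortcut + se$out)
      list(out = mp$out, buffers = nbuf,
           cache = list(x = x, bn1 = b1$cache, relu1 = r1$cache, r1 = r1$out,
                        bn2 = b2$cache, relu2 = r2$cache, se = se$cache,
                        sc = sc_cache, mp = mp$cache))
    },
    extra_conv = {
      a <- conv_forward(x, p$conv)
      bn <- bn_forward(a, p$bn, buf$bn, training)
      r <- relu_forward(bn$out)
      se <- se_forward(r$out, p$se)
      mp <- maxpool_forward(se$out)
      list(out = mp$out, buffers = list(bn = bn$buffers),
           cache = list(x = x, bn = bn$cache, relu = r$cache, se = se$cache,
                        mp = mp$cache))
    },
    transformer = {
      d <- dim(x); N <- d[4]
      tok <- tokenize(x)
      spatial <- attr(tok, "spatial")
      if (!is.null(p$pos)) tok <- tok + p$pos[rep(seq_len(nrow(p$pos)), N), ]
      att <- mhsa_forward(tok, p$mhsa, st$spec$heads, n_images = N)
      l1 <- ln_forward(tok + att$out, p$ln1)
      f1 <- dense_forward(t(l1$out), p$ffn1)      # ffn operates on d x M
      rr <- relu_forward(f1$out)
      f2 <- dense_forward(rr$out, p$ffn2)
      l2 <- ln_forward(l1$out + t(f2$out), p$ln2)
      out <- detokenize(l2$out, spatial)
      list(out = out, buffers = buf,
           cache = list(spatial = spatial, att = att$cache, ln1 = l1$cache,
                        l1out = l1$out, ffn1_x = f1$cache, relu = rr$cache,
                        ffn2_x = f2$cache, ln2 = l2$cache, n_images = N))
    },
    gap = {
      g <- gap(x)
      if (is.null(dim(g))) g <- matrix(g, ncol = 1)
      list(out = g, buffers = buf, cache = list(xdim = dim(x)))
    },
    dense_head = {
      f1 <- dense_forward(x, p$fc1)
      r <- relu_forward(f1$out)
      h <- r$out
      drop_mask <- NULL
      if (training && st$spec$dropout > 0) {
        keep <- 1 - st$spec$dropout
        drop_mask <- matrix(stats::rbinom(length(h), 1, keep) / keep,
                            nrow(h), ncol(h))
        h <- h * drop_mask
      }
      f2 <- dense_forward(h, p$fc2)
      probs <- softmax_cols(f2$out)
      list(out = probs, logits = f2$out, buffers = buf,
           cache = list(x = x, relu = r$cache, h = h, drop = drop_mask,
                        fc1_x = f1$cache))
    },
    stop("unknown stage kind"))
}

stage_backward <- function(st, cache, dout) {
  p <- st$params
  switch(st$spec$kind,
    conv_bn = {
      da <- relu_backward(cache$relu, dout)
      bnb <- bn_backward(p$bn, cache$bn, da)
      cb <- conv_backward(cache$x, p$conv, bnb$dx)
      list(dx = cb$dx,
           grads = list(conv = list(W = cb$dW, b = cb$db),
                        bn = list(gamma = bnb$dgamma, beta = bnb$dbeta)))
    },
    se_pool = {
      dse <- maxpool_backward(cache$mp, dout)
      sb <- se_backward(p$se, cache$se, dse)
      list(dx = sb$dx, grads = list(se = sb$grads))
    },
    residual_se = {
      dsum <- maxpool_backward(cache$mp, dout)
      sb <- se_backward(p$se, cache$se, dsum)
      dr2 <- relu_backward(cache$relu2, sb$dx)
      b2 <- bn_backward(p$bn2, cache$bn2, dr2)
      c2 <- conv_backward(cache$r1, p$conv2, b2$dx)
      dr1 <- relu_backward(cache$relu1, c2$dx)
      b1 <- bn_backward(p$bn1, cache$bn1, dr1)
      c1 <- conv_backward(cache$x, p$conv1, b1$dx)
      grads <- list(conv1 = list(W = c1$dW, b = c1$db),
                    bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                    conv2 = list(W = c2$dW, b = c2$db),
                    bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
                    se = sb$grads)
      if (!is.null(p$conv_sc)) {
        bsc <- bn_backward(p$bn_sc, cache$sc$bn, dsum)
        csc <- conv_backward(cache$x, p$conv_sc, bsc$dx)
        grads$conv_sc <- list(W = csc$dW, b = csc$db)
        grads$bn_sc <- list(gamma = bsc$dgamma, beta = bsc$dbeta)
        dx <- c1$dx + csc$dx
      } else {
        dx <- c1$dx + dsum
      }
      list(dx = dx, grads = grads)
    },
    extra_conv = {
      dse <- maxpool_backward(cache$mp, dout)
      sb <- se_backward(p$se, cache$se, dse)
      da <- relu_backward(cache$relu, sb$dx)
      bnb <- bn_backward(p$bn, cache$bn, da)
      cb <- conv_backward(cache$x, p$conv, bnb$dx)
      list(dx = cb$dx,
           grads = list(conv = list(W = cb$dW, b = cb$db),
                        bn = list(gamma = bnb$dgamma, beta = bnb$dbeta),
                        se = sb$grads))
    },
    transformer = {
      dtok_out <- tokenize(dout)
      l2 <- ln_backward(p$ln2, cache$ln2, dtok_out)
      df2 <- dense_backward(p$ffn2, cache$ffn2_x, t(l2$dx))
      drr <- relu_backward(cache$relu, df2$dx)
      df1 <- dense_backward(p$ffn1, cache$ffn1_x, drr)
      dl1out <- l2$dx + t(df1$dx)
      l1 <- ln_backward(p$ln1, cache$ln1, dl1out)
      ab <- mhsa_backward(p$mhsa, cache$att, l1$dx)
      dtok <- l1$dx + ab$dx
      grads <- list(mhsa = ab$grads,
                    ln1 = list(gamma = l1$dgamma, beta = l1$dbeta),
                    ffn1 = df1$grads, ffn2 = df2$grads,
                    ln2 = list(gamma = l2$dgamma, beta = l2$dbeta))
      if (!is.null(p$pos)) {
        Tn <- nrow(p$pos)
        dpos <- matrix(0, Tn, ncol(p$pos))
        for (n in seq_len(cache$n_images))
          dpos <- dpos + dtok[((n - 1) * Tn + 1):(n * Tn), , drop = FALSE]
        grads$pos <- dpos
      }
      list(dx = detokenize(dtok, cache$spatial), grads = grads)
    },
    gap = list(dx = gap_backward(dout, cache$xdim), grads = list()),
    dense_head = {
      # dout here is the gradient at the LOGITS (pre-softmax)
      df2 <- dense_backward(p$fc2, cache$h, dout)
      dh <- df2$dx
      if (!is.null(cache$drop)) dh <- dh * cache$drop
      dr <- relu_backward(cache$relu, dh)
      df1 <- dense_backward(p$fc1, cache$fc1_x, dr)
      list(dx = df1$dx, grads = list(fc1 = df1$grads, fc2 = df2$grads))
    },
    stop("unknown stage kind"))
}

## ---- model-level forward / backward ---------------------------------------

#' Forward pass through an LSeTNet model
#'
#' @param model a built [build_lsetnet()] model.
#' @param x input array `(H, W, 3, N)` (a single `(H, W, 3)` image is
#'   promoted to a batch of one).
#' @param training if `TRUE`, batch statistics and dropout are active and
#'   running batch-norm buffers are updated (returned in `$model`).
#' @param record if `TRUE`, keep every stage's output activation in `$acts`.
#' @return list with `probs` (`num_classes x N`), `logits`, `caches`,
#'   optionally `acts`, and (when training) the updated `model`.
#' @export
model_forward <- function(model, x, training = FALSE, record = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  caches <- vector("list", length(model$stages))
  acts <- if (record) vector("list", length(model$stages)) else NULL
  names(caches) <- names(model$stages)
  if (record) names(acts) <- names(model$stages)
  logits <- NULL
  for (i in seq_along(model$stages)) {
    r <- stage_forward(model$stages[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    if (record) acts[[i]] <- x
    if (!is.null(r$logits)) logits <- r$logits
    if (training) model$stages[[i]]$buffers <- r$buffers
  }
  list(probs = x, logits = logits, caches = caches, acts = acts, model = model)
}

# Backward from a gradient at the logits. Returns parameter gradients
# (nested, parallel to params) and optionally the gradient at each stage's
# output (needed by Grad-CAM).
model_backward <- function(model, caches, dlogits, collect_stage_grads = FALSE) {
  n <- length(model$stages)
  grads <- vector("list", n)
  names(grads) <- names(model$stages)
  stage_grads <- if (collect_stage_grads) vector("list", n) else NULL
  if (collect_stage_grads) names(stage_grads) <- names(model$stages)
  dout <- dlogits
  for (i in rev(seq_len(n))) {
    if (collect_stage_grads && i < n) stage_grads[[i]] <- dout
    r <- stage_backward(model$stages[[i]], caches[[i]], dout)
    grads[[i]] <- r$grads
    dout <- r$dx
  }
  list(grads = grads, input_grad = dout, stage_grads = stage_grads)
}

#' Predict class probabilities
#'
#' @param object an `lsetnet_model`.
#' @param x input array `(H, W, 3, N)`.
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return `N x num_classes` probability matrix.
#' @export
predict.lsetnet_model <- function(object, x, batch_size = 64, ...) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[4]
  K <- object$config$num_classes
  out <- matrix(NA_real_, N, K)
  for (s in seq(1, N, by = batch_size)) {
    e <- min(s + batch_size - 1, N)
    fw <- model_forward(object, x[, , , s:e, drop = FALSE], training = FALSE)
    out[s:e, ] <- t(fw$probs)
  }
  colnames(out) <- paste0("class_", seq_len(K))
  out
}

## ---- parameter accounting --------------------------------------------------

count_array_list <- function(p) {
  if (is.list(p)) sum(vapply(p, count_array_list, numeric(1))) else length(p)
}

#' Parameter report for an LSeTNet model
#'
#' Per-stage and total parameter counts. Non-trainable parameters are the
#' batch-normalization running statistics (two per normalized channel);
#' everything else is trainable. The float32 size is `4 * total / 2^20` MB.
#'
#' @param model an `lsetnet_model`.
#' @return object of class `param_report`: a data frame of per-stage counts
#'   with attributes `total`, `trainable`, `non_trainable`, `size_mb`.
#' @export
count_parameters <- function(model) {
  stages <- model$stages
  tr <- vapply(stages, function(s) count_array_list(s$params), numeric(1))
  nt <- vapply(stages, function(s) count_array_list(s$buffers), numeric(1))
  rep <- data.frame(stage = names(stages),
                    kind = vapply(stages, function(s) s$spec$kind, character(1)),
                    trainable = tr, non_trainable = nt, total = tr + nt,
                    row.names = NULL)
  structure(rep,
            total = sum(rep$total), trainable = sum(tr), non_trainable = sum(nt),
            size_mb = 4 * sum(rep$total) / 2^20,
            class = c("param_report", "data.frame"))
}

#' @export
print.param_report <- function(x, ...) {
  cat("LSeTNet parameter summary\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("Total: %s (%.2f MB float32)\n",
              format(attr(x, "total"), big.mark = ","), attr(x, "size_mb")))
  cat(sprintf("Trainable / Non-trainable: %s / %s\n",
              format(attr(x, "trainable"), big.mark = ","),
              format(attr(x, "non_trainable"), big.mark = ",")))
  invisible(x)
}

#' Pinned architecture budget check
#'
#' Compares the built model against the published per-stage parameter
#' budgets. The stem convolution, first SE stage, transformer block, dense
#' head and the non-trainable total are hard constraints (the published
#' numbers are internally consistent); the residual-block and extra-block
#' budgets are soft (the published per-stage approximations do not sum to
#' the published total) and only the deviation is reported.
#'
#' @param model a full-size `lsetnet_model` (default channel widths).
#' @return data frame with columns `quantity`, `expected`, `actual`,
#'   `constraint`, `ok`.
#' @export
lsetnet_budget_check <- function(model) {
  p <- model$stages
  stem_conv <- length(p$stem$params$conv$W) + length(p$stem$params$conv$b)
  se_stage <- count_array_list(p$se_pool$params)
  transformer <- count_array_list(p$transformer$params)
  head <- count_array_list(p$head$params)
  rept <- count_parameters(model)
  soft <- function(nm) sum(rept$total[rept$stage == nm])
  out <- data.frame(
    quantity = c("stem_conv", "se_stage", "transformer", "dense_head",
                 "non_trainable", "res1", "res2", "res3", "extra_conv", "total"),
    expected = c(1792, 580, 1577984, 537612, 6528,
                 258624, 926736, 3631648, 2525280, 9387688),
    actual = c(stem_conv, se_stage, transformer, head, attr(rept, "non_trainable"),
               soft("res1"), soft("res2"), soft("res3"), soft("extra_conv"),
               attr(rept, "total")),
    constraint = c(rep("hard", 5), rep("soft", 5)))
  out$ok <- out$expected == out$actual | out$constraint == "soft"
  out
}
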