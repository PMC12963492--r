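# Supervised training: categorical cross-entropy, Adam with step-decayed
# learning rate, validation-monitored early stopping with best-weight
# restoration, and stratified k-fold cross-validation whose folds respect
# augmentation parentage (an original and its augmented children never
# straddle a fold boundary).

#' Categorical cross-entropy (nats)
#'
#' `-sum_i y_i log(yhat_i)` for one sample; the mean over samples for a
#' batch. Predictions are clamped at `eps` for log safety.
#'
#' @param y_true one-hot vector, matrix of one-hot rows (`N x C`), or a
#'   vector of integer class indices.
#' @param y_pred probability vector or `N x C` matrix on the simplex.
#' @param eps clamping floor.
#' @param strict abort if a prediction row is off the simplex by more than
#'   1e-4.
#' @return scalar mean loss, non-negative.
#' @export
cross_entropy <- function(y_true, y_pred, eps = 1e-12, strict = TRUE) {
  if (is.null(dim(y_pred))) y_pred <- matrix(y_pred, nrow = 1)
  N <- nrow(y_pred); C <- ncol(y_pred)
  if (strict && any(abs(rowSums(y_pred) - 1) > 1e-4))
    stop("predictions are not normalized probabilities")
  if (is.null(dim(y_true)) && length(y_true) == C && N == 1 &&
      all(y_true %in% c(0, 1)) && sum(y_true) == 1) {
    y_true <- matrix(y_true, nrow = 1)
  } else if (is.null(dim(y_true))) {
    yt <- matrix(0, N, C)
    yt[cbind(seq_len(N), as.integer(y_true))] <- 1
    y_true <- yt
  }
  stopifnot(dim(y_true) == dim(y_pred))
  -mean(rowSums(y_true * log(pmax(y_pred, eps))))
}

#' Step-decay learning-rate schedule
#'
#' Starts at `initial_lr` and multiplies by `(final_lr/initial_lr)^(1/n_steps)`
#' every `step_every` epochs, reaching exactly `final_lr` at the last
#' scheduled step; non-increasing in the epoch.
#'
#' @param epoch zero-based epoch index.
#' @param initial_lr,final_lr schedule endpoints (defaults 1e-3 and 1e-4).
#' @param step_every epochs per decay step (default 15, i.e. three steps
#'   across a 50-epoch run).
#' @param n_steps number of decay steps to reach `final_lr`.
#' @return learning rate at `epoch`.
#' @export
lr_schedule <- function(epoch, initial_lr = 1e-3, final_lr = 1e-4,
                        step_every = 15, n_steps = 3) {
  stopifnot(epoch >= 0)
  k <- pmin(floor(epoch / step_every), n_steps)
  initial_lr * (final_lr / initial_lr)^(k / n_steps)
}

## ---- Adam -------------------------------------------------------------------

flatten_params <- function(x, prefix = "") {
  if (!is.list(x)) return(stats::setNames(list(x), prefix))
  out <- list()
  for (nm in names(x))
    out <- c(out, flatten_params(x[[nm]], paste0(prefix, ".", nm)))
  out
}

model_flat_params <- function(model) {
  out <- list()
  for (nm in names(model$stages))
    out <- c(out, flatten_params(model$stages[[nm]]$params, nm))
  out
}

model_set_flat_params <- function(model, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    expr <- paste0("model$stages[['", path[1], "']]$params",
                   paste0("[['", path[-1], "']]", collapse = ""))
    eval(parse(text = paste0(expr, " <- flat[[key]]")))
  }
  model
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0)
}

adam_step <- function(flat, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g * g
    flat[[k]] <- flat[[k]] - lr * (state$m[[k]] / c1) /
      (sqrt(state$v[[k]] / c2) + eps)
  }
  list(flat = flat, state = state)
}

## ---- dataset loading --------------------------------------------------------

#' Load one split of a manifest into an image stack
#'
#' Reads (or synthesizes, for non-materialized augmented records) every
#' image of a split, optionally applies the enhancement chain and
#' standardization, and returns the stack with integer labels.
#'
#' @param manifest a `leaf_manifest`.
#' @param split one of `train`, `val`, `test` (or `NULL` for all records).
#' @param size target side in pixels (plain bilinear resize).
#' @param stats optional `channel_stats` for standardization.
#' @param config optional [preproc_config()]; when given, the full
#'   enhancement chain runs instead of a bare resize.
#' @param policy [augment_policy()] used to synthesize non-materialized
#'   augmented records from their stored seeds.
#' @return list with `x` array `(size, size, 3, N)`, `y` integer labels,
#'   `classes`, and the records used.
#' @export
load_split <- function(manifest, split = "train", size = 64, stats = NULL,
                       config = NULL, policy = augment_policy()) {
  recs <- if (is.null(split)) manifest
          else manifest[manifest$split == split, , drop = FALSE]
  if (nrow(recs) == 0) stop("no records in split: ", split)
  classes <- manifest_classes(manifest)
  x <- array(0, c(size, size, 3, nrow(recs)))
  for (i in seq_len(nrow(recs))) {
    img <- read_image(recs$path[i])
    if (recs$origin[i] == "augmented" && !is.na(recs$aug_seed[i]) &&
        identical(recs$path[i], manifest$path[match(recs$parent_id[i],
                                                    manifest$image_id)]))
      img <- apply_random_augment(img, policy, recs$aug_seed[i])
    img <- if (!is.null(config)) {
      cfg <- config; cfg$target_size <- as.integer(size)
      enhance_image(img, cfg)
    } else resize_image(img, size)
    x[, , , i] <- img
  }
  if (!is.null(stats)) x <- standardize(x, stats)
  list(x = x, y = match(recs$label, classes), classes = classes,
       records = recs)
}

## ---- training loop ----------------------------------------------------------

macro_f1_from_preds <- function(y_true, y_pred, K) {
  cm <- matrix(0, K, K)
  for (i in seq_along(y_true)) cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1
  prec <- diag(cm) / pmax(colSums(cm), 1e-12)
  rec <- diag(cm) / pmax(rowSums(cm), 1e-12)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  mean(f1)
}

eval_on <- function(model, x, y, batch_size) {
  probs <- predict(model, x, batch_size = batch_size)
  pred <- max.col(probs, ties.method = "first")
  list(loss = cross_entropy(y, probs, strict = FALSE),
       accuracy = mean(pred == y),
       macro_f1 = macro_f1_from_preds(y, pred, ncol(probs)))
}

#' Train an LSeTNet model
#'
#' Adam (betas 0.9/0.999) under the step-decay schedule of
#' [lr_schedule()], shuffled mini-batches, and early stopping that
#' monitors the validation metric (macro-F1 maximized by default) with the
#' configured patience, restoring the best epoch's weights. All randomness
#' (shuffling, dropout) derives from `config$seed`. When manifests are
#' supplied alongside the data, a leakage audit must pass before training
#' starts.
#'
#' @param model a built `lsetnet_model`.
#' @param train,val lists with `x` (`(H, W, 3, N)` standardized stack) and
#'   `y` (integer labels), as from [load_split()].
#' @param config a [run_config()].
#' @param manifest optional split manifest; when given it is audited for
#'   leakage and training refuses to start on a failing audit.
#' @param verbose print per-epoch progress.
#' @return list with the trained `model` and `history` (class
#'   `train_history`): per-epoch train/val loss and accuracy, validation
#'   macro-F1, learning rate, best epoch and stop reason.
#' @export
train_model <- function(model, train, val, config = run_config(),
                        manifest = NULL, verbose = FALSE) {
  if (!is.null(manifest)) {
    audit <- audit_leakage(manifest)
    if (!audit$pass)
      stop("refusing to train: leakage audit failed (",
           nrow(audit$violations), " violation(s))")
  }
  N <- dim(train$x)[4]
  K <- model$config$num_classes
  flat <- model_flat_params(model)
  state <- adam_init(flat)
  maximize <- config$monitor == "macro_f1"
  best_metric <- if (maximize) -Inf else Inf
  best_flat <- flat
  best_buffers <- lapply(model$stages, `[[`, "buffers")
  best_epoch <- 0L
  wait <- 0L
  hist <- list()
  stop_reason <- "max_epochs"
  n_epochs <- 0L
  for (epoch in seq_len(config$max_epochs) - 1L) {
    lr <- lr_schedule(epoch, config$initial_lr, config$final_lr)
    set.seed(derive_seed(config$seed, 1000 + epoch))
    perm <- sample(N)
    tr_loss <- 0; tr_correct <- 0
    for (s in seq(1, N, by = config$batch_size)) {
      e <- min(s + config$batch_size - 1, N)
      idx <- perm[s:e]
      xb <- train$x[, , , idx, drop = FALSE]
      yb <- train$y[idx]
      fw <- model_forward(model, xb, training = TRUE)
      model <- fw$model
      nb <- length(idx)
      loss <- cross_entropy(yb, t(fw$probs), strict = FALSE)
      tr_loss <- tr_loss + loss * nb
      tr_correct <- tr_correct + sum(max.col(t(fw$probs)) == yb)
      dlog <- fw$probs
      dlog[cbind(yb, seq_len(nb))] <- dlog[cbind(yb, seq_len(nb))] - 1
      dlog <- dlog / nb
      bw <- model_backward(model, fw$caches, dlog)
      gflat <- list()
      for (nm in names(model$stages))
        gflat <- c(gflat, flatten_params(bw$grads[[nm]], nm))
      upd <- adam_step(flat, gflat, state, lr, config$betas)
      flat <- upd$flat
      state <- upd$state
      model <- model_set_flat_params(model, flat)
    }
    vm <- eval_on(model, val$x, val$y, config$batch_size)
    n_epochs <- epoch + 1L
    hist[[n_epochs]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = tr_loss / N,
      train_accuracy = tr_correct / N, val_loss = vm$loss,
      val_accuracy = vm$accuracy, val_macro_f1 = vm$macro_f1)
    if (verbose)
      log_msg("epoch %d: lr %.2e train loss %.4f acc %.4f | val loss %.4f acc %.4f F1 %.4f",
              epoch, lr, tr_loss / N, tr_correct / N, vm$loss, vm$accuracy,
              vm$macro_f1)
    metric <- if (maximize) vm$macro_f1 else vm$loss
    improved <- if (maximize) metric > best_metric else metric < best_metric
    if (improved) {
      best_metric <- metric
      best_flat <- flat
      best_buffers <- lapply(model$stages, `[[`, "buffers")
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stop_reason <- "early_stop"
        break
      }
    }
  }
  model <- model_set_flat_params(model, best_flat)
  for (nm in names(model$stages)) model$stages[[nm]]$buffers <- best_buffers[[nm]]
  history <- do.call(rbind, hist)
  structure(list(model = model,
                 history = structure(history,
                                     best_epoch = best_epoch,
                                     stop_reason = stop_reason,
                                     monitor = config$monitor,
                                     seed = config$seed,
                                     class = c("train_history", "data.frame"))),
            class = "lsetnet_fit")
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("Training history: %d epochs, best epoch %d (%s), stop: %s\n",
              nrow(x), attr(x, "best_epoch"), attr(x, "monitor"),
              attr(x, "stop_reason")))
  print.data.frame(utils::tail(x, 5), row.names = FALSE)
  invisible(x)
}

## ---- k-fold cross-validation ------------------------------------------------

#' Parentage-respecting stratified k-fold plan
#'
#' Partitions a (typically augmented training) manifest into `k` folds,
#' stratified by class, assigning whole augmentation families (an original
#' plus its augmented children) as a unit so near-duplicates never straddle
#' a fold boundary. Within each class, families are dealt to the currently
#' smallest fold; fold sizes are exactly equal whenever family sizes permit
#' (e.g. 700 images per class in 20 families of 35 give five folds of 140
#' per class).
#'
#' @param manifest a `leaf_manifest` (one split, e.g. the training split).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold assignment (1..k) per manifest row.
#' @export
kfold_plan <- function(manifest, k = 5, seed = 42) {
  classes <- manifest_classes(manifest)
  fold <- integer(nrow(manifest))
  with_seed(seed, {
    for (cl in classes) {
      rows <- which(manifest$label == cl)
      if (length(rows) < k)
        stop("class '", cl, "' has fewer than k = ", k, " records")
      fam <- split(rows, manifest$parent_id[rows])
      fam <- fam[sample(length(fam))]
      sizes <- vapply(fam, length, integer(1))
      fam <- fam[order(-sizes)]
      load <- numeric(k)
      for (f in fam) {
        tgt <- which.min(load)
        fold[f] <- tgt
        load[tgt] <- load[tgt] + length(f)
      }
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Trains on k-1 folds and evaluates on the held-out fold, for each fold of
#' a [kfold_plan()]. The training routine is injectable: `train_fn`
#' receives the fold's training and held-out manifests and must return
#' predicted labels (integer indices into the class list) for the held-out
#' records.
#'
#' @param manifest the manifest to fold (typically the augmented training
#'   split).
#' @param k number of folds.
#' @param config a [run_config()] (supplies the seed).
#' @param train_fn `function(train_manifest, heldout_manifest) ->
#'   integer predictions`; defaults to training a width-reduced LSeTNet on
#'   64 px images.
#' @return data frame of class `fold_results`: per-fold held-out size,
#'   accuracy and macro precision/recall/F1.
#' @export
kfold_cv <- function(manifest, k = 5, config = run_config(),
                     train_fn = NULL) {
  fold <- kfold_plan(manifest, k, config$seed)
  classes <- manifest_classes(manifest)
  if (is.null(train_fn)) train_fn <- default_cv_train_fn(config)
  out <- list()
  for (f in seq_len(k)) {
    tr <- new_manifest(manifest[fold != f, , drop = FALSE],
                       attr(manifest, "metadata"))
    ho <- new_manifest(manifest[fold == f, , drop = FALSE],
                       attr(manifest, "metadata"))
    pred <- train_fn(tr, ho)
    truth <- match(ho$label, classes)
    cm <- confusion(classes[truth], classes[pred], classes)
    rep <- class_report(cm)
    out[[f]] <- data.frame(fold = f, support = nrow(ho),
                           accuracy = attr(rep, "accuracy"),
                           macro_precision = attr(rep, "macro")["precision"],
                           macro_recall = attr(rep, "macro")["recall"],
                           macro_f1 = attr(rep, "macro")["f1"])
  }
  structure(do.call(rbind, out), class = c("fold_results", "data.frame"),
            row.names = seq_len(k))
}

default_cv_train_fn <- function(config, size = 64,
                                channels = c(16, 32, 64, 128)) {
  function(tr_manifest, ho_manifest) {
    tr <- load_split(tr_manifest, split = NULL, size = size)
    ho <- load_split(ho_manifest, split = NULL, size = size)
    st <- channel_stats_from_array(tr$x)
    tr$x <- standardize(tr$x, st)
    ho$x <- standardize(ho$x, st)
    cfg <- lsetnet_config(input_size = size, channels = channels,
                          num_classes = length(tr$classes),
                          heads = 4, head_hidden = 2 * channels[4])
    model <- build_lsetnet(cfg, seed = config$seed)
    fit <- train_model(model, tr, tr, config)  # no inner val: monitor train fold
    probs <- predict(fit$model, ho$x)
    max.col(probs, ties.method = "first")
  }
}
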