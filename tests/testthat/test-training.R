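test_that("cross-entropy follows its closed forms and monotonicity", {
  onehot <- c(0, 1, 0)
  expect_equal(cross_entropy(onehot, c(0, 1, 0)), 0)
  expect_equal(cross_entropy(c(1, rep(0, 11)), rep(1 / 12, 12)), log(12))
  expect_equal(round(cross_entropy(c(1, rep(0, 11)), rep(1 / 12, 12)), 4),
               2.4849)
  # strictly decreasing in the correct-class probability
  losses <- vapply(seq(0.1, 0.9, by = 0.1), function(p) {
    pr <- c(p, rep((1 - p) / 11, 11))
    cross_entropy(c(1, rep(0, 11)), pr)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(cross_entropy(c(1, 0), c(0.9, 0.3)), "not normalized")
  # batch form: mean over samples
  yp <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(cross_entropy(c(1L, 1L), yp),
               mean(-log(c(0.5, 0.9))))
})

test_that("the learning-rate schedule hits its endpoints and never increases", {
  expect_equal(lr_schedule(0), 1e-3)
  expect_equal(lr_schedule(49), 1e-4, tolerance = 1e-12)
  expect_equal(lr_schedule(45), 1e-4, tolerance = 1e-12)
  lrs <- vapply(0:49, lr_schedule, numeric(1))
  expect_true(all(diff(lrs) <= 1e-15))
  expect_equal(lr_schedule(14), 1e-3)  # first step at epoch 15
  expect_lt(lr_schedule(15), 1e-3)
})

test_that("training early-stops on a flat monitor and restores the best weights", {
  # two trivially separable classes: the monitor saturates at epoch 0
  set.seed(21)
  mk <- function(n, shift) {
    x <- array(rnorm(32 * 32 * 3 * n, mean = shift), c(32, 32, 3, n))
    x
  }
  x <- array(0, c(32, 32, 3, 40))
  x[, , , 1:20] <- mk(20, -2)
  x[, , , 21:40] <- mk(20, 2)
  y <- rep(1:2, each = 20)
  tr <- list(x = x, y = y)
  cfg <- run_config(seed = 42, max_epochs = 8, patience = 2, batch_size = 16)
  model <- build_lsetnet(tiny_config(num_classes = 2), seed = 42)
  fit <- train_model(model, tr, tr, cfg)
  h <- fit$history
  expect_equal(attr(h, "stop_reason"), "early_stop")
  best <- attr(h, "best_epoch")
  expect_equal(nrow(h), best + 1 + cfg$patience)  # stopped patience after best
  expect_lte(best, max(h$epoch))
  expect_equal(h$val_macro_f1[best + 1], max(h$val_macro_f1))
  # restored weights reproduce the best epoch's monitored metric
  ev <- lsetnet:::eval_on(fit$model, tr$x, tr$y, 16)
  expect_equal(ev$macro_f1, h$val_macro_f1[best + 1], tolerance = 1e-9)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(33)
  x <- array(rnorm(32 * 32 * 3 * 24), c(32, 32, 3, 24))
  y <- rep(1:3, each = 8)
  tr <- list(x = x, y = y)
  cfg <- run_config(seed = 7, max_epochs = 2, batch_size = 8)
  f1 <- train_model(build_lsetnet(tiny_config(), seed = 7), tr, tr, cfg)
  f2 <- train_model(build_lsetnet(tiny_config(), seed = 7), tr, tr, cfg)
  expect_equal(as.data.frame(f1$history), as.data.frame(f2$history),
               tolerance = 1e-12)
  expect_equal(f1$history$train_loss[1], f2$history$train_loss[1],
               tolerance = 1e-6)
})

test_that("training refuses a manifest that fails the leakage audit", {
  m <- fake_manifest(28)
  s <- stratified_split(m, split_plan(seed = 1))
  aug <- augment_to_quota(s, split_plan(seed = 1))
  bad <- aug
  i <- which(bad$origin == "augmented")[1]
  bad$split[i] <- setdiff(c("train", "val", "test"), bad$split[i])[1]
  tr <- list(x = array(0, c(32, 32, 3, 2)), y = c(1L, 2L))
  model <- build_lsetnet(tiny_config(), seed = 1)
  expect_error(train_model(model, tr, tr, run_config(max_epochs = 1),
                           manifest = bad),
               "leakage audit failed")
})

test_that("fold plans are stratified, disjoint, family-atomic, and exactly balanced", {
  # 700 per class in 20 families of 35: folds of exactly 140 per class
  m <- fake_manifest(28)
  s <- stratified_split(m, split_plan(seed = 42))
  aug <- augment_to_quota(s, split_plan(seed = 42))
  train_m <- lsetnet:::new_manifest(aug[aug$split == "train", ])
  fold <- kfold_plan(train_m, k = 5, seed = 42)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 1680))
  expect_true(all(table(train_m$label, fold) == 140))
  # an original and its children never straddle folds
  fam_folds <- tapply(fold, train_m$parent_id, function(f) length(unique(f)))
  expect_true(all(fam_folds == 1))
  # plan is a function of (manifest, k, seed) only
  expect_identical(fold, kfold_plan(train_m, 5, 42))
  expect_false(identical(fold, kfold_plan(train_m, 5, 43)))
})

test_that("cross-validation evaluates each held-out fold with the injected learner", {
  m <- fixture_dataset(10, size = 32, seed = 42)
  # nearest-centroid learner on downsampled pixels: cheap but real
  centroid_fn <- function(tr_m, ho_m) {
    feat <- function(mm) t(vapply(mm$path, function(p)
      as.numeric(resize_image(read_image(p), 8)), numeric(8 * 8 * 3)))
    Xtr <- feat(tr_m); Xho <- feat(ho_m)
    classes <- attr(tr_m, "classes")
    cent <- t(vapply(classes, function(cl)
      colMeans(Xtr[tr_m$label == cl, , drop = FALSE]), numeric(ncol(Xtr))))
    apply(Xho, 1, function(r) which.min(colSums((t(cent) - r)^2)))
  }
  res <- kfold_cv(m, k = 5, config = run_config(seed = 42),
                  train_fn = centroid_fn)
  expect_s3_class(res, "fold_results")
  expect_equal(nrow(res), 5)
  expect_equal(sum(res$support), nrow(m))  # folds partition the manifest
  expect_true(all(res$accuracy > 0.5))
  expect_true(all(res$macro_f1 >= 0 & res$macro_f1 <= 1))
})
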