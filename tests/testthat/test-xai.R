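test_that("Grad-CAM matches a finite-difference oracle on the target activations", {
  model <- build_lsetnet(tiny_config(), seed = 3)
  img <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  e <- grad_cam(model, img, target_class = 2, target_layer = "extra_conv")
  # numerical dy/dA at the extra_conv output (1x1x16 here), Eq-form map
  fw <- model_forward(model, img, record = TRUE)
  A <- fw$acts$extra_conv
  h <- 1e-5
  alpha_num <- numeric(dim(A)[3])
  for (k in seq_along(alpha_num)) {
    Ap <- A; Am <- A
    Ap[, , k, 1] <- Ap[, , k, 1] + h
    Am[, , k, 1] <- Am[, , k, 1] - h
    alpha_num[k] <- (tail_logit(model, Ap, class_idx = 2) -
                       tail_logit(model, Am, class_idx = 2)) / (2 * h)
  }
  alpha_num <- alpha_num / prod(dim(A)[1:2])
  map_num <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha_num)) map_num <- map_num + alpha_num[k] * A[, , k, 1]
  map_num <- pmax(map_num, 0)
  if (max(map_num) > 0) map_num <- map_num / max(map_num)
  expect_equal(e$map, map_num, tolerance = 1e-4)
  expect_true(all(e$map >= 0 & e$map <= 1))
  expect_equal(dim(e$overlay), c(32, 32))
})

test_that("a feature-blind head yields an all-zero attribution map", {
  model <- build_lsetnet(tiny_config(), seed = 4)
  model$stages$head$params$fc1$W[] <- 0
  model$stages$head$params$fc2$W[] <- 0
  img <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  e <- grad_cam(model, img, target_class = 1)
  expect_equal(max(abs(e$map)), 0)
  expect_equal(e$mean_intensity, 0)
  expect_equal(e$top5_mean, 0)
  expect_error(grad_cam(model, img, target_layer = "gap"), "spatial")
})

test_that("heatmap statistics follow order-statistic arithmetic", {
  m <- c(1, rep(0, 99))
  s <- heatmap_stats(m)
  expect_equal(s[["mean_intensity"]], 0.01)
  expect_equal(s[["top5_mean"]], 0.2)  # top 5 of 100 values: 1,0,0,0,0
  expect_equal(heatmap_stats(rep(0, 49)),
               c(mean_intensity = 0, top5_mean = 0))
  cst <- heatmap_stats(matrix(0.5, 10, 10))
  expect_equal(unname(cst), c(0.5, 0.5))
  set.seed(5)
  r <- heatmap_stats(runif(64))
  expect_gte(r[["top5_mean"]], r[["mean_intensity"]])
})

test_that("LIME recovers a mask-linear black box exactly under full enumeration", {
  # image with three homogeneous color blocks = three superpixels
  img <- array(0, c(12, 12, 3))
  img[, 1:4, ] <- rep(c(200, 30, 30), each = 12 * 4)
  img[, 5:8, ] <- rep(c(30, 200, 30), each = 12 * 4)
  img[, 9:12, ] <- rep(c(30, 30, 200), each = 12 * 4)
  img <- img + array(runif(12 * 12 * 3, -5, 5), c(12, 12, 3))  # non-degenerate
  seg <- slic_segments(img, 3)
  expect_equal(sort(unique(as.vector(seg))), 1:3)
  # presence of segment s = pixels of s untouched relative to the original
  present <- function(im) vapply(1:3, function(s)
    as.numeric(max(abs(im[, , 1][seg == s] - img[, , 1][seg == s])) < 1e-9),
    numeric(1))
  f <- function(im) { z <- present(im); 2 + 3 * z[1] - z[2] }
  e <- lime_explain(f, img, n_segments = 3, ridge = 0, enumerate = TRUE,
                    target_class = 1)
  expect_equal(e$weights, c(2, 3, -1, 0), tolerance = 1e-8)
  expect_equal(e$fidelity, 1, tolerance = 1e-8)
  expect_equal(e$top5$segment[1], 1)  # largest weight reported first
  # sampled fit still explains a mask-linear box almost perfectly
  e2 <- lime_explain(f, img, n_segments = 3, n_samples = 200, ridge = 0.01,
                     seed = 11, target_class = 1)
  expect_gte(e2$fidelity, 0.99)
  expect_error(lime_explain(f, img, n_segments = 1), "2 segments")
})

test_that("LIME is deterministic in its seed and flat on constant predictors", {
  img <- random_image(16, 16, seed = 12)
  fconst <- function(im) c(0.7, 0.3)
  e <- lime_explain(fconst, img, n_segments = 6, n_samples = 80, seed = 3)
  expect_equal(e$weights[1], 0.7, tolerance = 1e-6)
  expect_equal(max(abs(e$weights[-1])), 0, tolerance = 1e-6)
  f2 <- function(im) c(mean(im) / 255, 1 - mean(im) / 255)
  a <- lime_explain(f2, img, n_segments = 6, n_samples = 60, seed = 9)
  b <- lime_explain(f2, img, n_segments = 6, n_samples = 60, seed = 9)
  expect_identical(a$weights, b$weights)
  expect_equal(nrow(a$top5), 5)
})

test_that("GAP embeddings have the contracted shape and respond to learning", {
  model <- build_lsetnet(tiny_config(), seed = 5)
  set.seed(6)
  x <- array(rnorm(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  emb <- extract_embeddings(model, x)
  expect_equal(dim(emb), c(4, 16))
  # duplicate inputs give identical rows
  x[, , , 2] <- x[, , , 1]
  emb2 <- extract_embeddings(model, x)
  expect_equal(emb2[1, ], emb2[2, ])
  # one training step moves the embeddings
  tr <- list(x = x, y = c(1L, 1L, 2L, 3L))
  fit <- train_model(model, tr, tr, run_config(seed = 1, max_epochs = 1,
                                               batch_size = 4))
  emb3 <- extract_embeddings(fit$model, x)
  expect_gt(max(abs(emb3 - emb2)), 1e-6)
})

test_that("KL divergence vanishes only at equality", {
  set.seed(7)
  P <- matrix(runif(25), 5); P <- P / sum(P)
  expect_equal(kl_divergence(P, P), 0)
  Q <- matrix(runif(25), 5); Q <- Q / sum(Q)
  expect_gt(kl_divergence(P, Q), 0)
})

test_that("t-SNE separates well-separated Gaussian clusters", {
  set.seed(8)
  X <- rbind(matrix(rnorm(100 * 5, 0, 0.1), ncol = 5),
             matrix(rnorm(100 * 5, 10, 0.1), ncol = 5),
             matrix(rnorm(100 * 5, -10, 0.1), ncol = 5))
  labels <- rep(c("a", "b", "c"), each = 100)
  pr <- project_tsne(X, labels, perplexity = 30, seed = 42)
  expect_gt(pr$silhouette, 0.9)
  expect_gte(pr$silhouette, -1); expect_lte(pr$silhouette, 1)
  expect_gt(pr$kl_divergence, 0)
  # per-class spread is the per-axis standard deviation
  ya <- pr$coords[labels == "a", ]
  expect_equal(pr$clusters$spread_x[pr$clusters$class == "a"], sd(ya[, 1]))
  expect_equal(pr$clusters$centroid_y[pr$clusters$class == "a"], mean(ya[, 2]))
  expect_error(project_tsne(X[1:20, ], labels[1:20], perplexity = 15),
               "too few")
})

test_that("silhouette sanity: splitting one cluster into two labels scores low", {
  set.seed(9)
  X <- matrix(rnorm(80 * 4), ncol = 4)
  labels <- rep(c("p", "q"), 40)
  pr <- project_tsne(X, labels, perplexity = 10, seed = 1, max_iter = 250)
  expect_lt(pr$silhouette, 0.1)
})

test_that("the failure panel lists exactly the misclassified samples", {
  model <- build_lsetnet(tiny_config(), seed = 10)
  set.seed(11)
  x <- array(rnorm(32 * 32 * 3 * 6), c(32, 32, 3, 6))
  probs <- predict(model, x)
  pred <- max.col(probs, ties.method = "first")
  classes <- c("u", "v", "w")
  # labels equal to the model's own predictions: an empty panel
  fp0 <- failure_panel(model, list(x = x, y = pred), classes, explain = FALSE)
  expect_length(fp0$entries, 0)
  # flip one label: exactly one entry whose probability matches the softmax
  y <- pred
  y[3] <- (pred[3] %% 3) + 1
  fp1 <- failure_panel(model, list(x = x, y = y), classes)
  expect_length(fp1$entries, 1)
  e <- fp1$entries[[1]]
  expect_equal(e$index, 3)
  expect_equal(e$true_label, classes[y[3]])
  expect_equal(e$predicted_label, classes[pred[3]])
  expect_equal(e$probability, probs[3, pred[3]])
  expect_equal(unname(e$class_probs), unname(probs[3, ]))
  expect_s3_class(e$grad_cam, "explanation_map")
})
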