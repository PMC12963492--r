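test_that("the full-size model reproduces the pinned parameter budgets", {
  model <- build_lsetnet(lsetnet_config(), seed = 42)
  bc <- lsetnet_budget_check(model)
  hard <- bc[bc$constraint == "hard", ]
  expect_equal(hard$actual, hard$expected)
  rep <- count_parameters(model)
  expect_equal(attr(rep, "total"), 9387688)
  expect_equal(attr(rep, "trainable"), 9381160)
  expect_equal(attr(rep, "non_trainable"), 6528)
  expect_equal(attr(rep, "size_mb"), 4 * 9387688 / 2^20, tolerance = 1e-9)
  expect_equal(attr(rep, "total"),
               attr(rep, "trainable") + attr(rep, "non_trainable"))
})

test_that("squeeze-excitation parameter counts follow the bottleneck closed form", {
  se_count <- function(C, r) lsetnet:::count_array_list(lsetnet:::init_se(C, r))
  expect_equal(se_count(64, 16), 580)    # 64*4+4 + 4*64+64
  expect_equal(se_count(128, 16), 2184)  # 128*8+8 + 8*128+128
})

test_that("multi-head attention matches a brute-force oracle and normalizes rows", {
  for (case in list(c(N = 3, d = 4, h = 2), c(N = 5, d = 8, h = 4))) {
    set.seed(case[["N"]])
    w <- lsetnet:::init_mhsa(case[["d"]])
    tok <- matrix(rnorm(case[["N"]] * case[["d"]]), case[["N"]])
    out <- mhsa(tok, w, heads = case[["h"]], return_attention = TRUE)
    oracle <- naive_mhsa(tok, w, case[["h"]])
    expect_equal(unclass(out), oracle, tolerance = 1e-5,
                 ignore_attr = TRUE)
    for (A in attr(out, "attention"))
      expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
  }
  # single token: softmax of one logit is 1, so out = (x Wv + bv) Wo + bo
  set.seed(1)
  w <- lsetnet:::init_mhsa(6)
  x <- matrix(rnorm(6), 1)
  v <- x %*% t(w$Wv$W) + w$Wv$b
  expect_equal(as.numeric(mhsa(x, w, heads = 3)),
               as.numeric(v %*% t(w$Wo$W) + w$Wo$b), tolerance = 1e-10)
})

test_that("tokenization is a row-major bijection", {
  x <- array(seq_len(3 * 4 * 2), c(3, 4, 2, 1))
  tok <- tokenize(x)
  expect_equal(nrow(tok), 12)
  expect_equal(detokenize(tok), x)
  # token k corresponds to pixel (k %/% W, k %% W) in row-major order
  for (k in 0:11) {
    i <- k %/% 4 + 1; j <- k %% 4 + 1
    expect_equal(tok[k + 1, ], x[i, j, , 1])
  }
})

test_that("global average pooling follows its defining arithmetic", {
  const <- array(3.5, c(7, 7, 4))
  expect_equal(gap(const), rep(3.5, 4))
  single <- array(0, c(7, 7, 2))
  single[3, 5, 1] <- 1
  expect_equal(gap(single), c(1 / 49, 0))
  a <- array(rnorm(7 * 7 * 3), c(7, 7, 3))
  b <- array(rnorm(7 * 7 * 3), c(7, 7, 3))
  expect_equal(gap(2 * a + 3 * b), 2 * gap(a) + 3 * gap(b), tolerance = 1e-12)
})

test_that("saturated excitation gates make the SE block an identity", {
  p <- lsetnet:::init_se(8, 4)
  p$fc2$b <- rep(30, 8)  # sigmoid saturates at 1
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  out <- lsetnet:::se_forward(x, p)$out
  expect_equal(out, x, tolerance = 1e-8)
  # gates always lie strictly inside (0, 1)
  p2 <- lsetnet:::init_se(8, 4)
  g <- lsetnet:::se_forward(x, p2)$cache$g
  expect_true(all(g > 0 & g < 1))
})

test_that("a zeroed main path reduces the residual block to maxpool", {
  spec <- list(kind = "residual_se", in_channels = 8, out_channels = 8,
               kernel = 3L, se_reduction = 4)
  set.seed(2)
  st <- lsetnet:::init_stage(spec, lsetnet_config())
  st$params$conv2$W[] <- 0
  st$params$conv2$b[] <- 0
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  out <- lsetnet:::stage_forward(st, x, training = FALSE)$out
  expect_equal(out, lsetnet:::maxpool_forward(x)$out, tolerance = 1e-10)
})

test_that("forward passes respect the downsampling schedule and the simplex", {
  model <- build_lsetnet(lsetnet_config(), seed = 42)
  set.seed(3)
  x <- array(rnorm(248 * 248 * 3), c(248, 248, 3, 1))
  fw <- model_forward(model, x, record = TRUE)
  sizes <- vapply(fw$acts[c("stem", "se_pool", "res1", "res2", "res3",
                            "extra_conv")], function(a) dim(a)[1], numeric(1))
  expect_equal(unname(sizes), c(248, 124, 62, 31, 15, 7))
  expect_equal(dim(fw$acts$transformer), c(7, 7, 512, 1))
  expect_equal(sum(fw$probs), 1, tolerance = 1e-9)
  expect_length(fw$probs, 12)
  expect_error(lsetnet_config(input_size = 16), "input_size")
})

test_that("model builds are deterministic in the seed", {
  cfg <- tiny_config()
  m1 <- build_lsetnet(cfg, seed = 9)
  m2 <- build_lsetnet(cfg, seed = 9)
  m3 <- build_lsetnet(cfg, seed = 10)
  expect_identical(m1$stages, m2$stages)
  expect_false(identical(m1$stages$stem$params$conv$W,
                         m3$stages$stem$params$conv$W))
})

test_that("backpropagation matches central finite differences", {
  cfg <- tiny_config()
  model <- build_lsetnet(cfg, seed = 1)
  set.seed(7)
  N <- 2
  x <- array(rnorm(32 * 32 * 3 * N), c(32, 32, 3, N))
  y <- c(1L, 3L)
  loss_of <- function(m) {
    fw <- model_forward(m, x, training = TRUE)
    -sum(log(pmax(fw$probs[cbind(y, 1:N)], 1e-12)))
  }
  fw <- model_forward(model, x, training = TRUE)
  dlog <- fw$probs
  dlog[cbind(y, 1:N)] <- dlog[cbind(y, 1:N)] - 1
  bw <- lsetnet:::model_backward(model, fw$caches, dlog)
  checks <- list(
    list(c("stem", "conv", "W"), 5),
    list(c("res1", "conv_sc", "W"), 3),
    list(c("res2", "se", "fc2", "W"), 7),
    list(c("extra_conv", "conv", "W"), 20),
    list(c("transformer", "mhsa", "Wq", "W"), 9),
    list(c("transformer", "ffn1", "W"), 11),
    list(c("head", "fc1", "W"), 13))
  h <- 1e-6
  for (chk in checks) {
    path <- chk[[1]]; idx <- chk[[2]]
    g_an <- bw$grads
    for (p in path) g_an <- g_an[[p]]
    g_an <- g_an[idx]
    bump <- function(delta) {
      mm <- model
      expr <- paste0("mm$stages[['", path[1], "']]$params",
                     paste0("[['", path[-1], "']]", collapse = ""))
      eval(parse(text = paste0(expr, "[idx] <- ", expr, "[idx] + delta")))
      mm
    }
    g_nu <- (loss_of(bump(h)) - loss_of(bump(-h))) / (2 * h)
    expect_equal(g_an, g_nu, tolerance = 1e-3,
                 label = paste(path, collapse = "."))
  }
})

test_that("parameter accounting is additive and BN-free models count zero buffers", {
  model <- build_lsetnet(tiny_config(), seed = 1)
  rep <- count_parameters(model)
  expect_equal(attr(rep, "total"),
               attr(rep, "trainable") + attr(rep, "non_trainable"))
  # strip every BN buffer: non-trainable collapses to zero
  for (nm in names(model$stages)) model$stages[[nm]]$buffers <- list()
  expect_equal(attr(count_parameters(model), "non_trainable"), 0)
})
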