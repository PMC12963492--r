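classes12 <- leaf_class_names()

# Reconstruct the worked-example test set: 150 per class with exactly five
# cross-class errors (web blight confused with yellow/spot/healthy look-alikes).
five_error_labels <- function() {
  y_true <- rep(classes12, each = 150)
  y_pred <- y_true
  flip <- function(yp, from, to) {
    i <- which(y_true == from & yp == from)[1]
    yp[i] <- to
    yp
  }
  y_pred <- flip(y_pred, "Kalanchoe_Web_Blight", "Kalanchoe_Yellow")
  y_pred <- flip(y_pred, "Kalanchoe_Yellow_Blight", "Kalanchoe_Yellow")
  y_pred <- flip(y_pred, "Neem_Web_Blight", "Neem_Spot")
  y_pred <- flip(y_pred, "Tulsi_Healthy", "Tulsi_Web_Blight")
  y_pred <- flip(y_pred, "Tulsi_Web_Blight", "Tulsi_Healthy")
  list(y_true = y_true, y_pred = y_pred)
}

test_that("confusion matrices count correctly and ignore sample order", {
  y <- c("a", "b", "a", "c")
  cm <- confusion(y, y, c("a", "b", "c"))
  expect_equal(unclass(cm), diag(c(2, 1, 1)), ignore_attr = TRUE)
  expect_equal(attr(class_report(cm), "accuracy"), 1)
  set.seed(4)
  l <- five_error_labels()
  cm12 <- confusion(l$y_true, l$y_pred, classes12)
  expect_equal(sum(diag(cm12)), 1795)
  expect_equal(sum(cm12) - sum(diag(cm12)), 5)
  expect_true(all(cm12[cm12 > 0 & row(cm12) != col(cm12)] == 1))
  perm <- sample(length(l$y_true))
  expect_equal(confusion(l$y_true[perm], l$y_pred[perm], classes12), cm12)
  expect_error(confusion(c("a", "zz"), c("a", "a"), c("a", "b")), "unknown label")
})

test_that("the five-misclassification worked example reproduces the printed metrics", {
  l <- five_error_labels()
  cm <- confusion(l$y_true, l$y_pred, classes12)
  rep <- class_report(cm)
  expect_equal(round(attr(rep, "accuracy"), 4), 0.9972)
  expect_equal(attr(rep, "accuracy"), 1795 / 1800)
  ky <- rep[rep$class == "Kalanchoe_Yellow", ]
  expect_equal(ky$precision, 150 / 152)
  expect_equal(round(ky$precision, 2), 0.99)
  expect_equal(ky$recall, 1)
  expect_equal(rep$support, rep(150L, 12))
})

test_that("degenerate report shapes behave: single class and empty matrices", {
  cm1 <- matrix(7, 1, 1, dimnames = list("only", "only"))
  r <- class_report(cm1)
  expect_equal(attr(r, "accuracy"), 1)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)
  expect_error(class_report(matrix(numeric(0), 0, 0)), "empty")
  # zero-division convention: absent predicted class reports 0 and flags
  cm2 <- matrix(c(5, 3, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  r2 <- class_report(cm2)
  expect_equal(r2$precision[2], 0)
  expect_true(attr(r2, "zero_division"))
})

test_that("macro F1 is invariant under class relabeling", {
  set.seed(5)
  y <- sample(letters[1:3], 300, replace = TRUE)
  p <- sample(letters[1:3], 300, replace = TRUE)
  r1 <- class_report(confusion(y, p, letters[1:3]))
  swap <- c(a = "c", b = "a", c = "b")
  r2 <- class_report(confusion(unname(swap[y]), unname(swap[p]),
                               sort(unname(swap))))
  expect_equal(attr(r1, "macro")["f1"], attr(r2, "macro")["f1"])
})

test_that("one-vs-rest AUC matches its extremes, chance level, and the trapezoid", {
  set.seed(6)
  y <- rep(c("pos", "neg"), each = 100)
  sc <- cbind(pos = c(runif(100, 0.6, 1), runif(100, 0, 0.4)))
  sc <- cbind(sc, neg = 1 - sc[, 1])
  r <- roc_auc_ovr(sc, y, c("pos", "neg"))
  expect_equal(unname(r$auc), c(1, 1))
  # anti-correlated scores
  r2 <- roc_auc_ovr(cbind(pos = -sc[, 1], neg = -sc[, 2]), y, c("pos", "neg"))
  expect_equal(unname(r2$auc), c(0, 0))
  # random scores hover at 0.5
  set.seed(7)
  y3 <- sample(c("x", "y"), 2000, replace = TRUE)
  sc3 <- cbind(x = runif(2000), y = runif(2000))
  r3 <- roc_auc_ovr(sc3, y3, c("x", "y"))
  expect_lt(abs(r3$auc[["x"]] - 0.5), 0.03)
  # midrank method equals the explicit trapezoidal integral, ties included
  set.seed(8)
  s <- sample(seq(0, 1, by = 0.1), 60, replace = TRUE)  # heavy ties
  pos <- runif(60) < plogis(4 * (s - 0.5))
  auc_rank <- roc_auc_ovr(cbind(k = s), ifelse(pos, "k", "o"),
                          c("k", "o"))$auc[["k"]]
  expect_equal(auc_rank, roc_curve(s, pos)$auc, tolerance = 1e-12)
  # absent class reports NA and is excluded from the macro
  r4 <- roc_auc_ovr(cbind(a = runif(10), b = runif(10)),
                    rep("a", 10), c("a", "b"))
  expect_true(is.na(r4$auc[["b"]]))
})

test_that("the midrank AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- rnorm(200)
  pos <- runif(200) < plogis(s)
  ours <- roc_auc_ovr(cbind(p = s), ifelse(pos, "p", "n"), c("p", "n"))$auc[["p"]]
  ref <- as.numeric(pROC::auc(pROC::roc(as.integer(pos), s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("confusion and ROC figures render to PNG files", {
  l <- five_error_labels()
  cm <- confusion(l$y_true, l$y_pred, classes12)
  f1 <- file.path(tempdir(), "cm.png")
  plot_confusion(cm, f1)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  set.seed(10)
  sc <- matrix(runif(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  f2 <- file.path(tempdir(), "roc.png")
  plot_roc(sc, sample(c("a", "b", "c"), 60, replace = TRUE),
           c("a", "b", "c"), f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
})
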