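# Evaluation: confusion matrices (rows = truth, columns = prediction),
# per-class and macro precision/recall/F1, accuracy, and one-vs-rest
# ROC/AUC by the midrank method.

#' Confusion matrix
#'
#' @param y_true,y_pred label vectors (character or factor) of equal
#'   length; every label must appear in `classes`.
#' @param classes ordered class names defining rows/columns.
#' @return `K x K` integer matrix of class `confusion_matrix`; rows are
#'   true classes, columns predicted.
#' @export
confusion <- function(y_true, y_pred, classes) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length")
  if (!all(y_true %in% classes) || !all(y_pred %in% classes))
    stop("unknown label outside the class list")
  cm <- table(factor(y_true, levels = classes),
              factor(y_pred, levels = classes))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("true", "predicted")
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Per-class and aggregate classification report
#'
#' Precision `cm[k,k]/colsum_k`, recall `cm[k,k]/rowsum_k`, F1 their
#' harmonic mean; zero denominators report 0 and are flagged. Accuracy is
#' `trace/total`; macro averages are unweighted class means, weighted
#' averages are support-weighted.
#'
#' @param cm a [confusion()] matrix.
#' @return data frame of class `class_report` (per-class rows) with
#'   attributes `accuracy`, `macro`, `weighted`, `zero_division`.
#' @export
class_report <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) == 0) stop("empty confusion matrix")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  support <- rowSums(cm)
  colsum <- colSums(cm)
  zd_p <- colsum == 0
  zd_r <- support == 0
  precision <- ifelse(zd_p, 0, diag(cm) / pmax(colsum, 1))
  recall <- ifelse(zd_r, 0, diag(cm) / pmax(support, 1))
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  rep <- data.frame(class = rownames(cm), precision = precision,
                    recall = recall, f1 = f1, support = as.integer(support),
                    row.names = NULL)
  w <- support / total
  structure(rep,
            accuracy = sum(diag(cm)) / total,
            macro = c(precision = mean(precision), recall = mean(recall),
                      f1 = mean(f1)),
            weighted = c(precision = sum(w * precision),
                         recall = sum(w * recall), f1 = sum(w * f1)),
            zero_division = any(zd_p | zd_r),
            class = c("class_report", "data.frame"))
}

#' @export
print.class_report <- function(x, digits = 2, ...) {
  y <- x
  for (cc in c("precision", "recall", "f1")) y[[cc]] <- round(y[[cc]], digits)
  print.data.frame(y, row.names = FALSE)
  cat(sprintf("Overall: Accuracy = %.4f, Macro P/R/F1 = %.2f/%.2f/%.2f\n",
              attr(x, "accuracy"), attr(x, "macro")["precision"],
              attr(x, "macro")["recall"], attr(x, "macro")["f1"]))
  invisible(x)
}

#' One-vs-rest ROC AUC
#'
#' Per-class AUC by the midrank (Mann-Whitney) method, equivalent to the
#' trapezoidal area under the ROC curve with tie-midpoint handling. Classes
#' absent from `y_true` get `NA` and are excluded from the macro average.
#'
#' @param scores `N x K` matrix of class scores (columns follow `classes`).
#' @param y_true true labels (character/factor in `classes`, or integer
#'   indices).
#' @param classes class names.
#' @return list with `auc` (named per-class vector) and `macro_auc`.
#' @export
roc_auc_ovr <- function(scores, y_true, classes = colnames(scores)) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (is.numeric(y_true)) y_true <- classes[y_true]
  K <- length(classes)
  auc <- stats::setNames(rep(NA_real_, K), classes)
  named <- !is.null(colnames(scores))
  for (k in seq_len(K)) {
    col <- if (named) match(classes[k], colnames(scores)) else k
    if (is.na(col) || col > ncol(scores)) next
    pos <- y_true == classes[k]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) next
    r <- rank(scores[, col], ties.method = "average")
    auc[k] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(auc = auc, macro_auc = mean(auc, na.rm = TRUE))
}

#' ROC curve points
#'
#' Explicit (FPR, TPR) staircase for one class-vs-rest score vector,
#' including the trapezoidal AUC (used as the independent cross-check of
#' the midrank method).
#'
#' @param score numeric score vector.
#' @param pos logical positive-class indicator.
#' @return list with data frame `curve` (`fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(score, pos) {
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]; pos <- pos[ord]
  # group ties: one step per distinct threshold
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / max(sum(pos), 1))
  fpr <- c(0, fp[last] / max(sum(!pos), 1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Confusion-matrix heatmap and ROC figure
#'
#' @param cm a [confusion()] matrix.
#' @param file optional PNG path; when given the plot is written there.
#' @export
plot_confusion <- function(cm, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 800)
    on.exit(grDevices::dev.off())
  }
  K <- nrow(cm)
  op <- graphics::par(mar = c(9, 9, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(K), seq_len(K), t(cm[K:1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", main = "Confusion matrix")
  graphics::axis(1, seq_len(K), colnames(cm), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(K), rev(rownames(cm)), las = 2, cex.axis = 0.8)
  for (i in seq_len(K)) for (j in seq_len(K))
    graphics::text(j, K + 1 - i, cm[i, j], cex = 0.7)
  invisible(NULL)
}

#' @rdname plot_confusion
#' @param scores,y_true,classes as in [roc_auc_ovr()].
#' @export
plot_roc <- function(scores, y_true, classes = colnames(scores), file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 700)
    on.exit(grDevices::dev.off())
  }
  if (is.numeric(y_true)) y_true <- classes[y_true]
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "gray",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "One-vs-rest ROC")
  cols <- grDevices::hcl.colors(length(classes), "Dark 3")
  for (k in seq_along(classes)) {
    rc <- roc_curve(scores[, k], y_true == classes[k])
    graphics::lines(rc$curve$fpr, rc$curve$tpr, col = cols[k])
  }
  graphics::legend("bottomright", classes, col = cols, lty = 1, cex = 0.6)
  invisible(NULL)
}
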