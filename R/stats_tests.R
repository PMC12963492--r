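# Statistical model comparison: paired Student's t on per-fold scores,
# McNemar's chi-squared on discordant counts (no continuity correction),
# the Friedman rank test with midrank ties, and the Nemenyi critical
# difference. All tests are two-tailed at alpha = 0.05 by default.

new_stat_test <- function(test, statistic, df, p_value, inputs,
                          alpha = 0.05, degenerate = FALSE) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, inputs = inputs, alpha = alpha,
                 two_tailed = TRUE, degenerate = degenerate),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %s%s\n", x$test,
              format(x$statistic, digits = 6),
              paste(x$df, collapse = ", "),
              format(x$p_value, digits = 4),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Paired Student's t-test on per-fold scores
#'
#' `t = dbar / sqrt(s_d^2 / n)` with the sample variance (n-1 denominator)
#' of the differences `d = a - b`; df = n-1; two-tailed p. A zero-variance
#' difference vector is flagged degenerate (infinite or undefined t), never
#' silently zero.
#'
#' @param a,b equal-length numeric score vectors (n >= 2).
#' @param alpha significance level.
#' @return a `stat_test_result` with the differences echoed in `inputs`.
#' @export
paired_t_test <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least two paired scores")
  d <- a - b
  dbar <- mean(d)
  s2 <- stats::var(d)
  if (s2 == 0) {
    return(new_stat_test("paired_t", if (dbar == 0) NaN else sign(dbar) * Inf,
                         n - 1, if (dbar == 0) NA_real_ else 0,
                         list(differences = d), alpha, degenerate = TRUE))
  }
  t_stat <- dbar / sqrt(s2 / n)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  new_stat_test("paired_t", t_stat, n - 1, p, list(differences = d), alpha)
}

#' McNemar's test on discordant counts
#'
#' `chi^2 = (b - c)^2 / (b + c)` without continuity correction; df = 1.
#'
#' @param b,c discordant counts (model A right / B wrong, and vice versa).
#' @param alpha significance level.
#' @return a `stat_test_result`; `b + c = 0` is flagged degenerate.
#' @export
mcnemar_test <- function(b, c, alpha = 0.05) {
  if (b < 0 || c < 0) stop("discordant counts must be non-negative")
  if (b + c == 0)
    return(new_stat_test("mcnemar", NaN, 1, NA_real_,
                         list(b = b, c = c), alpha, degenerate = TRUE))
  chi2 <- (b - c)^2 / (b + c)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  new_stat_test("mcnemar", chi2, 1, p, list(b = b, c = c), alpha)
}

#' Friedman rank test
#'
#' Ranks models within each dataset row (midranks on ties), then
#' `chi2_F = 12 N / (k (k+1)) * sum_j R_j^2 - 3 N (k+1)` with `R_j` the
#' average rank of model j; df = k-1.
#'
#' @param scores `N x k` matrix: rows are datasets (or folds), columns are
#'   models. Higher scores rank better (rank k).
#' @param alpha significance level.
#' @return a `stat_test_result` with the rank table echoed in `inputs`.
#' @export
friedman_rank_test <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  N <- nrow(scores); k <- ncol(scores)
  if (k < 2) stop("need at least two models (columns)")
  if (N < 1) stop("need at least one dataset (row)")
  ranks <- t(apply(scores, 1, rank, ties.method = "average"))
  if (k == 2 && N == 1) ranks <- matrix(ranks, 1, k)
  R <- colMeans(ranks)
  chi2 <- 12 * N / (k * (k + 1)) * sum(R^2) - 3 * N * (k + 1)
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  new_stat_test("friedman", chi2, k - 1, p,
                list(ranks = ranks, avg_ranks = R), alpha)
}

#' Nemenyi critical difference
#'
#' `CD = q_alpha(k) * sqrt(k (k+1) / (6 N))`, with `q_alpha(k)` the
#' studentized-range quantile at infinite df divided by sqrt(2) (so
#' `q_0.05(2) = 1.960`). Two models whose average Friedman ranks differ by
#' more than CD are significantly different.
#'
#' @param k number of models (2..50).
#' @param N number of datasets.
#' @param alpha significance level.
#' @return the critical difference (scalar).
#' @export
nemenyi_cd <- function(k, N, alpha = 0.05) {
  if (k < 2 || k > 50) stop("k outside the supported table range [2, 50]")
  if (N < 1) stop("N must be at least 1")
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * N))
}

#' Compare models from a folds-by-models score table
#'
#' Runs the Friedman omnibus test, the Nemenyi critical difference, and all
#' pairwise paired t-tests (optionally Holm-corrected).
#'
#' @param scores `N x k` score matrix with model names as columns.
#' @param alpha significance level.
#' @param holm apply Holm correction to the pairwise t-test p-values.
#' @return list with `friedman`, `cd`, and a data frame `pairwise`.
#' @export
compare_models <- function(scores, alpha = 0.05, holm = FALSE) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (is.null(colnames(scores))) colnames(scores) <- paste0("model_", seq_len(k))
  fr <- friedman_rank_test(scores, alpha)
  cd <- nemenyi_cd(k, nrow(scores), alpha)
  pairs <- utils::combn(k, 2)
  pw <- apply(pairs, 2, function(ij) {
    tt <- paired_t_test(scores[, ij[1]], scores[, ij[2]], alpha)
    data.frame(model_a = colnames(scores)[ij[1]],
               model_b = colnames(scores)[ij[2]],
               t = tt$statistic, df = tt$df, p = tt$p_value,
               degenerate = tt$degenerate)
  })
  pw <- do.call(rbind, pw)
  if (holm) pw$p_holm <- stats::p.adjust(pw$p, method = "holm")
  list(friedman = fr, cd = cd, pairwise = pw)
}
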