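## Classification and ranking metrics, and multi-seed summaries.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with midrank tie handling.
#'
#' @param truth Vector in {0, 1} (or {-1, 1}).
#' @param probs Numeric scores.
#' @return AUROC in [0, 1]; `NA` when only one class is present.
#' @export
auroc <- function(truth, probs) {
  pos <- truth == 1
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Confusion-matrix and ranking metrics at a threshold
#'
#' Precision (positive predictive value), recall (sensitivity), F1 (their
#' harmonic mean), threshold-free AUROC, and NDCG, on the 0-100 display
#' scale. Predictions are positive when `probs > threshold`.
#'
#' @param truth Vector in {0, 1} (or {-1, 1}; anything equal to 1 is
#'   positive).
#' @param probs Predicted probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `metric_report`: list with `precision`, `recall`,
#'   `f1`, `auroc`, `ndcg` (each in [0, 100], AUROC `NA`-flagged for
#'   one-class truth), `n`, and `threshold`.
#' @export
classification_metrics <- function(truth, probs, threshold = 0.5) {
  truth <- as.integer(truth == 1)
  pred <- as.integer(probs > threshold)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  au <- auroc(truth, probs)
  nd <- if (sum(truth) > 0) ndcg(truth, probs) else NA_real_
  structure(list(precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1,
                 auroc = 100 * au, ndcg = 100 * nd,
                 n = length(truth), threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "precision %.1f | recall %.1f | F1 %.1f | AUROC %s | NDCG %s (n = %d, threshold %.3f)\n",
    x$precision, x$recall, x$f1,
    ifelse(is.na(x$auroc), "NA", sprintf("%.1f", x$auroc)),
    ifelse(is.na(x$ndcg), "NA", sprintf("%.1f", x$ndcg)),
    x$n, x$threshold))
  invisible(x)
}

#' Normalized discounted cumulative gain
#'
#' Instances are ranked by descending probability (ties keep input order via
#' stable sort); each positive carries relevance 1 and contributes
#' `1 / log2(i + 1)` at 1-based rank i, summed over all instances and
#' divided by the DCG of a perfect ranking.
#'
#' @param truth Vector in {0, 1} (or {-1, 1}).
#' @param probs Predicted probabilities.
#' @return NDCG in [0, 1], with attribute `ties` flagging tied scores.
#' @export
ndcg <- function(truth, probs) {
  rel <- as.integer(truth == 1)
  if (sum(rel) == 0) stop("NDCG undefined without positive instances",
                          call. = FALSE)
  ord <- order(-probs)                      # stable: ties keep input order
  disc <- 1 / log2(seq_along(rel) + 1)
  dcg <- sum(rel[ord] * disc)
  ideal <- sum(disc[seq_len(sum(rel))])
  out <- dcg / ideal
  attr(out, "ties") <- anyDuplicated(probs) > 0
  out
}

#' Mean and 95% confidence interval over seeds
#'
#' Student-t interval (the seed count is small); with fewer than 2 values
#' the mean is returned and the CI flagged absent.
#'
#' @param values Per-seed metric values.
#' @return List with `mean`, `ci_lower`, `ci_upper`, `n`, `has_ci`.
#' @export
summarize_runs <- function(values) {
  n <- length(values)
  mu <- mean(values)
  if (n < 2) {
    return(list(mean = mu, ci_lower = NA_real_, ci_upper = NA_real_,
                n = n, has_ci = FALSE))
  }
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  list(mean = mu, ci_lower = mu - half, ci_upper = mu + half,
       n = n, has_ci = TRUE)
}

#' Plain-text results table over multi-seed runs
#'
#' Collapses a per-run results table (as returned in
#' \code{scaleup_experiment()$runs}) into one row per model/size with
#' "mean [lower, upper]" entries per metric, in the conventional
#' Precision / Recall / F1 / AUROC / NDCG column layout.
#'
#' @param runs data.frame with columns `model`, `size`, and per-run
#'   `precision`, `recall`, `f1`, `auroc`, `ndcg`.
#' @return data.frame of formatted strings.
#' @export
metric_table <- function(runs) {
  fmt <- function(v) {
    s <- summarize_runs(v)
    if (!s$has_ci) return(sprintf("%.1f", s$mean))
    sprintf("%.1f [%.1f, %.1f]", s$mean, s$ci_lower, s$ci_upper)
  }
  groups <- unique(runs[, c("model", "size")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- runs$model == groups$model[i] & runs$size == groups$size[i]
    data.frame(model = groups$model[i], size = groups$size[i],
               precision = fmt(runs$precision[sel]),
               recall = fmt(runs$recall[sel]),
               f1 = fmt(runs$f1[sel]),
               auroc = fmt(runs$auroc[sel]),
               ndcg = fmt(runs$ndcg[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
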