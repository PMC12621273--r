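#' Confusion matrix at a decision threshold
#'
#' Scores at or above the threshold are predicted positive (ties count as
#' positive).
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric scores, same length.
#' @param threshold Decision threshold. Default 0.5.
#' @return List with integer fields `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stop("labels and scores differ in length")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1L & labels == 1L),
       FP = sum(pred == 1L & labels == 0L),
       FN = sum(pred == 0L & labels == 1L),
       TN = sum(pred == 0L & labels == 0L))
}

# rank-based AUROC (Mann-Whitney; ties get half credit)
auroc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# non-interpolated average precision: step sum over distinct thresholds
ap_step <- function(labels, scores) {
  P <- sum(labels == 1)
  if (P == 0 || all(labels == 1)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]; s <- scores[ord]
  grp_end <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- cumsum(l)[grp_end]
  np <- seq_along(l)[grp_end]
  rec <- tp / P
  prec <- tp / np
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

# ROC curve coordinates at distinct thresholds (descending), with (0,0)
roc_curve <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]; s <- scores[ord]
  grp_end <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(1 - l)[grp_end]
  data.frame(threshold = c(Inf, s[grp_end]),
             fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

pr_curve <- function(labels, scores) {
  P <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]; s <- scores[ord]
  grp_end <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[grp_end]
  np <- seq_along(l)[grp_end]
  data.frame(threshold = s[grp_end], recall = tp / P, precision = tp / np)
}

#' Binary classification metrics report
#'
#' Computes accuracy, precision, recall, F1 at the threshold, plus the
#' threshold-free average precision (non-interpolated step sum over the
#' precision-recall curve) and AUROC (rank-based Mann-Whitney statistic with
#' half credit for ties, equal to the area under the ROC curve). With only
#' one class present, AP and AUROC are reported as `NA` and flagged.
#' Undefined precision (no predicted positives) is reported as 0 with
#' `precision_defined = FALSE` so F1 stays defined.
#'
#' @inheritParams confusion
#' @return A `metrics_report` list: scalar metrics, the confusion matrix,
#'   `roc_points` and `pr_points` data frames, and the threshold used.
#' @export
binary_metrics <- function(labels, scores, threshold = 0.5) {
  cm <- confusion(labels, scores, threshold)
  labels <- as.integer(labels)
  n <- length(labels)
  prec_def <- (cm$TP + cm$FP) > 0
  precision <- if (prec_def) cm$TP / (cm$TP + cm$FP) else 0
  recall <- if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  one_class <- length(unique(labels)) < 2L
  structure(list(
    accuracy = (cm$TP + cm$TN) / n,
    precision = precision, recall = recall, f1 = f1,
    ap = if (one_class) NA_real_ else ap_step(labels, scores),
    auroc = if (one_class) NA_real_ else auroc_rank(labels, scores),
    confusion = cm, threshold = threshold,
    precision_defined = prec_def, one_class = one_class,
    roc_points = if (one_class) NULL else roc_curve(labels, scores),
    pr_points = if (one_class) NULL else pr_curve(labels, scores)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Binary classification metrics (threshold",
      format(x$threshold), ")\n")
  cat(sprintf("  accuracy  %.3f\n  precision %.3f%s\n  recall    %.3f\n",
              x$accuracy, x$precision,
              if (!x$precision_defined) " (no predicted positives)" else "",
              x$recall))
  cat(sprintf("  F1        %.3f\n  AP        %s\n  AUROC     %s\n",
              x$f1,
              if (is.na(x$ap)) "undefined (one class)" else sprintf("%.3f", x$ap),
              if (is.na(x$auroc)) "undefined (one class)"
              else sprintf("%.3f", x$auroc)))
  cm <- x$confusion
  cat(sprintf("  confusion TP=%d FP=%d FN=%d TN=%d\n",
              cm$TP, cm$FP, cm$FN, cm$TN))
  invisible(x)
}

#' Serialise a metrics report
#'
#' Writes the scalar metrics and confusion matrix as JSON and, when curves
#' are available, the ROC and PR curves as TSV next to it.
#'
#' @param report A `metrics_report`.
#' @param path Output JSON path; curves go to `<path>.roc.tsv` and
#'   `<path>.pr.tsv`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  scalars <- report[c("accuracy", "precision", "recall", "f1", "ap",
                      "auroc", "threshold")]
  scalars$confusion <- report$confusion
  jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(report$roc_points))
    utils::write.table(report$roc_points, paste0(path, ".roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$pr_points))
    utils::write.table(report$pr_points, paste0(path, ".pr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
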