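# Binary-classifier evaluation: the five criteria (accuracy, recall,
# precision, specificity, F1) plus ROC/AUC, with virus as the positive
# class throughout.

#' Confusion counts from calls and labels
#'
#' @param calls character vector of predicted classes (`virus`/`host`).
#' @param labels character vector of true classes.
#' @return object of class `gv_confusion`: list with integer `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(calls, labels) {
  stopifnot(length(calls) == length(labels),
            all(calls %in% CLASSES), all(labels %in% CLASSES))
  structure(
    list(TP = sum(calls == "virus" & labels == "virus"),
         FP = sum(calls == "virus" & labels == "host"),
         TN = sum(calls == "host" & labels == "host"),
         FN = sum(calls == "host" & labels == "virus")),
    class = "gv_confusion"
  )
}

#' The five criteria from confusion counts
#'
#' accuracy = (TP+TN)/total, recall = TP/(TP+FN), precision = TP/(TP+FP),
#' specificity = TN/(TN+FP), F1 = 2PR/(P+R). A ratio with a zero
#' denominator is reported as `NaN` with a warning, never silently as 0.
#'
#' @param counts a [confusion_counts()] object (or a list with fields
#'   `TP`, `FP`, `TN`, `FN`).
#' @return one-row tibble with columns `accuracy`, `recall`, `precision`,
#'   `specificity`, `f1`.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total == 0) stop("No evaluated records.", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NaN.",
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  recall <- safe_div(tp, tp + fn, "recall")
  precision <- safe_div(tp, tp + fp, "precision")
  f1 <- if (is.nan(recall) || is.nan(precision) ||
            (precision + recall) == 0) {
    warning("F1 undefined; reported as NaN.", call. = FALSE)
    NaN
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(
    accuracy = (tp + tn) / total,
    recall = recall,
    precision = precision,
    specificity = safe_div(tn, tn + fp, "specificity"),
    f1 = f1
  )
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive outscores a random
#' negative, with ties counted 1/2 (the rank-sum formulation). ROC points
#' are emitted at every distinct threshold.
#'
#' @param scores numeric scores (higher = more virus-like).
#' @param labels true classes (`virus` positive).
#' @return object of class `gv_roc`: list with `auc` and `points` (tibble
#'   with `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "virus"
  if (!any(pos) || all(pos)) {
    stop("Both classes must be present to compute ROC/AUC.", call. = FALSE)
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- pos[o]
  last <- !duplicated(s, fromLast = TRUE)  # last row of each tie block
  tpr <- cumsum(p)[last] / n_pos
  fpr <- cumsum(!p)[last] / n_neg
  points <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  structure(list(auc = auc, points = points,
                 n_pos = n_pos, n_neg = n_neg), class = "gv_roc")
}

#' @export
#' @method print gv_roc
print.gv_roc <- function(x, ...) {
  cat("<gv_roc> AUC = ", signif(x$auc, 4), " (", x$n_pos, " positives, ",
      x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

#' Evaluate predictions against labels
#'
#' Joins predictions and labels on `id`, thresholds the scores and returns
#' the confusion counts, the five criteria and the AUC in one report.
#'
#' @param predictions tibble with columns `id`, `score` (e.g. from
#'   [predict.gv_classifier()]); an existing `call` column is ignored and
#'   recomputed from the threshold.
#' @param labels tibble with columns `id`, `label`.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `gv_eval`: list with `counts`, `metrics`
#'   (one-row tibble incl. `auc` and `n`), and `roc`.
#' @export
evaluate_predictions <- function(predictions, labels, threshold = 0.5) {
  if (anyDuplicated(labels$id)) {
    stop("Duplicated ids in labels: ",
         paste(utils::head(unique(labels$id[duplicated(labels$id)]), 10),
               collapse = ", "), call. = FALSE)
  }
  m <- match(predictions$id, labels$id)
  if (anyNA(m)) {
    stop("Predictions without labels: ",
         paste(utils::head(predictions$id[is.na(m)], 10), collapse = ", "),
         call. = FALSE)
  }
  truth <- labels$label[m]
  calls <- ifelse(predictions$score >= threshold, "virus", "host")
  counts <- confusion_counts(calls, truth)
  roc <- roc_auc(predictions$score, truth)
  metrics <- confusion_metrics(counts)
  metrics$auc <- roc$auc
  metrics$n <- length(calls)
  structure(list(counts = counts, metrics = metrics, roc = roc,
                 threshold = threshold), class = "gv_eval")
}

#' @export
#' @method print gv_eval
print.gv_eval <- function(x, ...) {
  cat("<gv_eval> n = ", x$metrics$n, ", threshold = ", x$threshold, "\n",
      sep = "")
  print(x$metrics)
  invisible(x)
}

#' Write a metrics report as JSON or one-row TSV
#' @param eval a [evaluate_predictions()] result.
#' @param path output path; format chosen by extension (`.json` or `.tsv`).
#' @export
write_metrics <- function(eval, path) {
  stopifnot(inherits(eval, "gv_eval"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      c(as.list(eval$metrics), unclass(eval$counts)),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    utils::write.table(eval$metrics, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
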