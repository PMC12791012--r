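# Classification metrics and the cross-validation harness.

#' Confusion counts at a score threshold
#'
#' A pair is predicted cognate when its score is greater than or equal to
#' the threshold (a score exactly at the threshold counts as positive).
#'
#' @param labels Integer labels (1 = cognate, 0 = shuffled).
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0) stop("empty input", call. = FALSE)
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length", call. = FALSE)
  }
  pred <- scores >= threshold
  truth <- labels == 1
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

# Mann-Whitney AUC with ties counting one half
auc_rank <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics report
#'
#' Accuracy, precision, recall, F1, Matthews correlation coefficient and
#' area under the ROC curve (computed as the Mann-Whitney U statistic
#' normalised by `n_pos * n_neg`, ties contributing one half). Metrics
#' that are undefined on the input (e.g. MCC or AUC on a single-class set,
#' precision with no positive predictions) are reported as `NA`, never
#' coerced to zero.
#'
#' @param labels Integer labels (1 = cognate, 0 = shuffled).
#' @param scores Numeric scores.
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report`: one-row tibble with columns `n`,
#'   `threshold`, `accuracy`, `precision`, `recall`, `f1`, `mcc`,
#'   `auc_roc`, `tp`, `fp`, `tn`, `fn`.
#' @export
metrics <- function(labels, scores, threshold = 0.5) {
  cc <- confusion(labels, scores, threshold)
  n <- length(labels)
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else
    (tp * tn - fp * fn) / mcc_den
  out <- tibble::tibble(
    n = n, threshold = threshold,
    accuracy = (tp + tn) / n, precision = precision, recall = recall,
    f1 = f1, mcc = mcc, auc_roc = auc_rank(labels, scores),
    tp = tp, fp = fp, tn = tn, fn = fn)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Cross-validated training with a common withheld test set
#'
#' For each training fold `f` of a cluster-disjoint split, a model is
#' trained on the remaining K-1 folds and evaluated on the single common
#' test partition (every fold model faces the same withheld clonotypes).
#' Returns per-fold reports, their mean/spread, and a report for a model
#' trained on all folds.
#'
#' @param dataset A `pair_dataset`.
#' @param split A [split_by_cluster()] assignment.
#' @param trainer Function `(pairs, seed) -> pair_scorer` (see
#'   [scorer_trainer()]).
#' @param seed Base seed; fold `f` trains with `seed + f`.
#' @param threshold Decision threshold for the reports.
#' @return List with `fold_reports` (tibble, one row per fold),
#'   `summary` (mean and sd of each metric over folds), and `full_model`
#'   plus `full_report` for the all-folds model.
#' @export
cross_validate <- function(dataset, split, trainer, seed = 1,
                           threshold = 0.5) {
  pairs <- if (inherits(dataset, "pair_dataset")) dataset$pairs else dataset
  part <- split$partition[match(pairs$pair_id, split$pair_id)]
  if (anyNA(part)) stop("split does not cover all pairs", call. = FALSE)
  folds <- sort(unique(part[part != "test"]))
  test_pairs <- pairs[part == "test", ]
  if (nrow(test_pairs) == 0) stop("empty test partition", call. = FALSE)
  test_labels <- pair_labels(test_pairs)
  reports <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    train_pairs <- pairs[part != "test" & part != folds[i], ]
    if (length(unique(train_pairs$label)) < 2) {
      stop("fold ", folds[i], " leaves single-class training data",
           call. = FALSE)
    }
    model <- trainer(train_pairs, seed = seed + i)
    rep_i <- metrics(test_labels, score_pairs(model, test_pairs),
                     threshold)
    rep_i$fold <- folds[i]
    reports[[i]] <- rep_i
  }
  fold_reports <- dplyr::bind_rows(reports)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "mcc",
                   "auc_roc")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(fold_reports[[m]]),
                  numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(fold_reports[[m]]),
                numeric(1)))
  full_model <- trainer(pairs[part != "test", ], seed = seed)
  full_report <- metrics(test_labels, score_pairs(full_model, test_pairs),
                         threshold)
  list(fold_reports = fold_reports, summary = summary,
       full_model = full_model, full_report = full_report)
}

#' Write a metrics report (or fold table) as JSON and TSV
#'
#' @param report A `metrics_report` or tibble of reports.
#' @param path_json,path_tsv Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, path_json = NULL, path_tsv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(as.list(report), path_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(path_tsv)) {
    write.table(as.data.frame(report), path_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
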