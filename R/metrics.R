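#' Build a confusion matrix
#'
#' Rows index the true class, columns the predicted class, in the order of
#' `labels` (or sorted unique truth labels when omitted).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param labels Optional character vector fixing class order; every label
#'   in `y_true`/`y_pred` must appear in it.
#' @return A `K x K` integer matrix of class `confusion_matrix`.
#' @export
build_confusion <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must be nonempty and of equal length.")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  labels <- as.character(labels)
  if (!all(c(y_true, y_pred) %in% labels)) {
    abort("Labels outside the declared class set.")
  }
  cm <- table(factor(y_true, levels = labels),
              factor(y_pred, levels = labels))
  cm <- matrix(as.integer(cm), nrow = length(labels),
               dimnames = list(true = labels, predicted = labels))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Confusion matrix directly from per-class diagonals
#'
#' Utility for reconstructing published one-vs-rest recalls when only the
#' confusion diagonal (correct counts per class) and the per-class totals
#' are known. Off-diagonal errors are distributed proportionally to the
#' other classes' totals; per-class recall, and hence the macro recall,
#' depend only on the diagonal and the totals, not on that distribution.
#'
#' @param diagonal Correct counts per class.
#' @param totals True sample counts per class (`diagonal <= totals`).
#' @param labels Optional class names.
#' @return A `confusion_matrix`.
#' @export
confusion_from_diagonal <- function(diagonal, totals, labels = NULL) {
  if (length(diagonal) != length(totals)) {
    abort("`diagonal` and `totals` must have equal length.")
  }
  if (any(diagonal > totals) || any(diagonal < 0)) {
    abort("Diagonal counts must lie in [0, totals].")
  }
  K <- length(totals)
  if (is.null(labels)) labels <- paste0("class", seq_len(K))
  cm <- matrix(0L, K, K, dimnames = list(true = labels, predicted = labels))
  for (k in seq_len(K)) {
    cm[k, k] <- as.integer(diagonal[k])
    miss <- totals[k] - diagonal[k]
    if (miss > 0) {
      others <- setdiff(seq_len(K), k)
      w <- totals[others] / sum(totals[others])
      alloc <- floor(miss * w)
      rem <- miss - sum(alloc)
      if (rem > 0) {
        top <- order(miss * w - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[top] <- alloc[top] + 1L
      }
      cm[k, others] <- as.integer(alloc)
    }
  }
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

one_vs_rest_counts <- function(cm, k) {
  total <- sum(cm)
  TP <- cm[k, k]
  FN <- sum(cm[k, ]) - TP
  FP <- sum(cm[, k]) - TP
  TN <- total - TP - FN - FP
  list(TP = TP, FN = FN, FP = FP, TN = TN, total = total)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-class one-vs-rest metrics
#'
#' For each class `k` the matrix is binarized (class `k` positive, all
#' others negative) and seven metrics are computed on the unrounded
#' counts, reported in percent: accuracy `(TP+TN)/n`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F-score
#' `2PR/(P+R)`, Matthews correlation coefficient, and G-mean
#' `sqrt(recall * specificity)`. A zero denominator yields 0 for that
#' metric and sets the `degenerate` flag for the class (small runs can
#' leave a class unpredicted).
#'
#' @param cm A `confusion_matrix` (or any square count matrix).
#' @return A tibble with one row per class, metric columns in percent
#'   (unrounded; round at report time), and a logical `degenerate` column.
#' @export
per_class_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0) {
    abort("`cm` must be a nonempty square count matrix.")
  }
  labels <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  rows <- purrr::map(seq_len(nrow(cm)), function(k) {
    ct <- one_vs_rest_counts(cm, k)
    precision <- safe_ratio(ct$TP, ct$TP + ct$FP)
    recall <- safe_ratio(ct$TP, ct$TP + ct$FN)
    specificity <- safe_ratio(ct$TN, ct$TN + ct$FP)
    fscore <- if (is.na(precision) || is.na(recall) ||
                  precision + recall == 0) NA_real_
              else 2 * precision * recall / (precision + recall)
    mcc_den <- sqrt(as.numeric(ct$TP + ct$FP) * (ct$TP + ct$FN) *
                      (ct$TN + ct$FP) * (ct$TN + ct$FN))
    mcc <- if (mcc_den == 0) NA_real_ else
      (as.numeric(ct$TP) * ct$TN - as.numeric(ct$FP) * ct$FN) / mcc_den
    gmean <- if (is.na(recall) || is.na(specificity)) NA_real_ else
      sqrt(recall * specificity)
    vals <- c(accuracy = (ct$TP + ct$TN) / ct$total, precision = precision,
              recall = recall, specificity = specificity, fscore = fscore,
              mcc = mcc, gmean = gmean)
    degenerate <- any(is.na(vals))
    vals[is.na(vals)] <- 0
    tibble::tibble(class = labels[k], !!!as.list(100 * vals),
                   degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}

#' Macro (unweighted) average of per-class metrics
#'
#' @param report A [per_class_metrics()] tibble.
#' @return A one-row tibble with `class = "Average"` and the arithmetic
#'   mean of each metric over classes.
#' @export
macro_average <- function(report) {
  if (nrow(report) == 0L) abort("`report` must have at least one class row.")
  metric_cols <- c("accuracy", "precision", "recall", "specificity",
                   "fscore", "mcc", "gmean")
  avg <- dplyr::summarise(report,
                          dplyr::across(dplyr::all_of(metric_cols), mean))
  dplyr::bind_cols(tibble::tibble(class = "Average"), avg,
                   tibble::tibble(degenerate = any(report$degenerate)))
}

#' Full metrics report (per class plus macro row)
#'
#' @param cm A `confusion_matrix`.
#' @param digits Decimal places for rounding (half-up) at report time;
#'   `NULL` leaves values unrounded.
#' @return A tibble of per-class rows followed by the `Average` row, of
#'   class `metrics_report`.
#' @export
metrics_report <- function(cm, digits = 2) {
  per <- per_class_metrics(cm)
  out <- dplyr::bind_rows(per, macro_average(per))
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                            ~ round_half_up(.x, digits)))
  }
  class(out) <- c("metrics_report", class(out))
  out
}

#' Overall (multiclass) accuracy of a confusion matrix, in percent
#'
#' The trace over the grand total; complements [fitness_error_rate()]
#' exactly: `overall_accuracy(cm) == 100 - error rate`.
#'
#' @param cm A `confusion_matrix`.
#' @return Accuracy percentage.
#' @export
overall_accuracy <- function(cm) 100 * sum(diag(cm)) / sum(cm)

#' Write a metrics report as CSV or JSON
#'
#' @param report A [metrics_report()] tibble.
#' @param path Output file; format chosen by extension (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(report, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    abort("Use a .csv or .json path.")
  }
  invisible(path)
}
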