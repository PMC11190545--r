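# Confusion-matrix metrics on the 0-100 scale, and the stratified
# train/test split. "cancerous" is the positive class throughout.

as_binary <- function(x, what) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    bad <- setdiff(unique(x), c("cancerous", "non-cancerous"))
    if (length(bad) > 0L) {
      rlang::abort(paste0(what, " labels must be cancerous/non-cancerous."))
    }
    as.integer(x == "cancerous")
  } else {
    if (!all(x %in% c(0, 1))) rlang::abort(paste0(what, " must be 0/1."))
    as.integer(x)
  }
}

#' Confusion counts for binary predictions
#'
#' @param predictions,labels 0/1 vectors (1 = positive) or
#'   cancerous/non-cancerous character vectors; equal nonzero length.
#' @return A one-row tibble with `TP`, `TN`, `FP`, `FN` (their sum is
#'   the number of samples).
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    rlang::abort("`predictions` and `labels` must have equal length.")
  }
  if (length(labels) == 0L) rlang::abort("Empty input.")
  p <- as_binary(predictions, "predictions")
  y <- as_binary(labels, "labels")
  tibble::tibble(
    TP = sum(p == 1L & y == 1L), TN = sum(p == 0L & y == 0L),
    FP = sum(p == 1L & y == 0L), FN = sum(p == 0L & y == 1L)
  )
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics on the 0-100 scale
#'
#' Computes accuracy, sensitivity (recall), specificity, precision,
#' F1-score and the Matthews correlation coefficient, each multiplied by
#' 100 as conventionally reported. Ratios with a zero denominator are
#' returned as `NA` ("not applicable"). MCC uses the standard numerator
#' `TP*TN - FP*FN`, which keeps it within [-100, 100].
#'
#' @param counts A one-row tibble/list with `TP`, `TN`, `FP`, `FN` (see
#'   [confusion_counts()]).
#' @return A tibble with columns `metric` and `value`, metrics in report
#'   order: Precision, Accuracy, Specificity, Sensitivity, F1-score,
#'   MCC.
#' @export
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0)))
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) rlang::abort("Confusion counts are all zero.")
  precision <- safe_ratio(TP, TP + FP)
  sensitivity <- safe_ratio(TP, TP + FN)
  specificity <- safe_ratio(TN, TN + FP)
  accuracy <- (TP + TN) / total
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            (precision + sensitivity) == 0) {
    NA_real_
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  den2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den2 == 0) NA_real_ else {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den2)
  }
  tibble::tibble(
    metric = c("Precision", "Accuracy", "Specificity", "Sensitivity",
               "F1-score", "MCC"),
    value = 100 * c(precision, accuracy, specificity, sensitivity, f1, mcc)
  )
}

#' Stratified train/test split
#'
#' Splits an image set (or any tibble with a `label` column) into
#' disjoint train and test subsets, stratified by label. The train size
#' is `floor(train_fraction * n + 0.5)` overall, allocated per class by
#' largest remainder (ties broken in favor of the cancerous class), so
#' each class's train share is within one sample of `train_fraction`.
#'
#' @param data A tibble with a `label` column; every class needs at
#'   least 2 samples.
#' @param train_fraction Train share (default 0.7).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list with `train` and `test` tibbles partitioning `data`.
#' @export
split_train_test <- function(data, train_fraction = 0.7, seed = NULL) {
  counts <- table(data$label)
  if (any(counts < 2L)) {
    rlang::abort("Every class needs at least 2 samples to split.")
  }
  classes <- names(counts)
  classes <- c(intersect("cancerous", classes),
               setdiff(classes, "cancerous"))
  n_train_total <- floor(train_fraction * nrow(data) + 0.5)
  quota <- train_fraction * as.numeric(counts[classes])
  base <- floor(quota)
  extra <- n_train_total - sum(base)
  if (extra > 0) {
    ord <- order(-(quota - base), seq_along(classes))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  } else if (extra < 0) {
    ord <- order(quota - base, seq_along(classes))
    base[ord[seq_len(-extra)]] <- base[ord[seq_len(-extra)]] - 1
  }
  pick <- function() {
    idx_train <- integer(0)
    for (j in seq_along(classes)) {
      idx <- which(data$label == classes[j])
      idx_train <- c(idx_train, sample(idx, base[j]))
    }
    sort(idx_train)
  }
  idx_train <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  list(train = data[idx_train, ], test = data[-idx_train, ])
}
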