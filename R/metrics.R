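# Confusion-matrix machinery and per-class performance metrics.

#' Confusion-matrix cell counts ("classification groups")
#'
#' Counts samples per (true class, predicted class) cell — e.g. "NREM1
#' samples classified as REM". These cells are the unit of all global
#' importance aggregation.
#'
#' @param true_labels,predicted_labels Equal-length vectors of stage labels.
#' @return 5 x 5 integer matrix, rows = true class, columns = predicted
#'   class, of class `group_counts`.
#' @export
confusion_group_counts <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    abort("label vectors must have equal length")
  }
  tl <- as.character(true_labels); pl <- as.character(predicted_labels)
  bad <- setdiff(unique(c(tl, pl)), stage_levels())
  if (length(bad)) {
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  }
  counts <- table(factor(tl, levels = stage_levels()),
                  factor(pl, levels = stage_levels()))
  m <- matrix(as.integer(counts), 5L, 5L,
              dimnames = list(true = stage_levels(), predicted = stage_levels()))
  class(m) <- c("group_counts", class(m))
  m
}

#' Long-format view of group counts
#'
#' @param counts A [confusion_group_counts()] matrix.
#' @return Tibble with `true`, `predicted`, `n`.
#' @export
group_counts_tbl <- function(counts) {
  tibble(true = rep(stage_levels(), times = 5),
         predicted = rep(stage_levels(), each = 5),
         n = as.integer(counts[cbind(rep(1:5, times = 5), rep(1:5, each = 5))]))
}

#' Per-class precision, recall and F1 across folds
#'
#' For each fold's confusion counts: precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2PR/(P+R), reported in percent. Ratios with a zero
#' denominator are undefined, reported as missing and excluded from the
#' cross-fold mean and sd (sample sd, n-1).
#'
#' @param counts_per_fold List of [confusion_group_counts()] matrices, one
#'   per fold.
#' @return Tibble with columns `class`, `metric` (`precision`/`recall`/`f1`),
#'   `mean`, `sd`, `n_folds` (folds where the metric was defined).
#' @export
per_class_metrics <- function(counts_per_fold) {
  if (!length(counts_per_fold)) abort("need at least one fold")
  per_fold <- bind_rows(lapply(seq_along(counts_per_fold), function(f) {
    m <- counts_per_fold[[f]]
    tp <- diag(m)
    fp <- colSums(m) - tp
    fn <- rowSums(m) - tp
    precision <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
    recall <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
    f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
                 2 * precision * recall / (precision + recall), NA_real_)
    tibble(fold = f, class = stage_levels(),
           precision = precision, recall = recall, f1 = f1)
  }))
  per_fold |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    group_by(.data$class, .data$metric) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = stats::sd(.data$value, na.rm = TRUE),
              n_folds = sum(!is.na(.data$value)), .groups = "drop") |>
    mutate(mean = ifelse(.data$n_folds == 0, NA_real_, .data$mean))
}
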