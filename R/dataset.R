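#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter group_by summarise ungroup arrange select
#'   bind_rows left_join across all_of n
NULL

#' Sleep-stage class labels
#'
#' The five stage labels used throughout the package, in canonical order:
#' Awake, NREM1, NREM2, NREM3, REM. NREM4 never appears in an assembled
#' dataset; it is merged into NREM3 during epoching.
#'
#' @return Character vector of length 5.
#' @export
stage_levels <- function() c("Awake", "NREM1", "NREM2", "NREM3", "REM")

#' Modality (channel) names
#'
#' Fixed channel-to-modality mapping used in every sample tensor and every
#' result table: channel 1 = EEG (Fpz-Cz), channel 2 = EOG, channel 3 = EMG.
#'
#' @return Character vector of length 3.
#' @export
modality_names <- function() c("EEG", "EOG", "EMG")

SAMPLES_PER_EPOCH <- 3000L  # 30 s at 100 Hz

#' Construct an epoched dataset
#'
#' The container all classifiers and explainers consume: an `n x 3000 x 3`
#' numeric array of z-scored 30-s samples plus a per-sample metadata tibble.
#'
#' @param samples Numeric array `n x 3000 x 3` (samples x timepoints x
#'   modalities, channel order EEG, EOG, EMG).
#' @param meta Data frame with one row per sample and columns `label`
#'   (factor over [stage_levels()]), `subject_id`, `recording_id`,
#'   `medication` (`"placebo"`/`"temazepam"`), `sex` (`"female"`/`"male"`),
#'   `age` (years), `epoch_index` (chronological position within recording,
#'   1-based).
#' @return An object of class `epoched_dataset`.
#' @export
epoched_dataset <- function(samples, meta) {
  if (length(dim(samples)) != 3L ||
      dim(samples)[2] != SAMPLES_PER_EPOCH || dim(samples)[3] != 3L) {
    abort(sprintf("`samples` must be n x %d x 3, got %s",
                  SAMPLES_PER_EPOCH, paste(dim(samples), collapse = " x ")))
  }
  meta <- as_tibble(meta)
  need <- c("label", "subject_id", "recording_id", "medication", "sex",
            "age", "epoch_index")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(paste0("`meta` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(meta) != dim(samples)[1]) {
    abort("`meta` must have one row per sample")
  }
  meta$label <- factor(as.character(meta$label), levels = stage_levels())
  if (anyNA(meta$label)) abort("labels must be among the five stage levels")
  dimnames(samples) <- list(NULL, NULL, modality_names())
  structure(list(samples = samples, meta = meta), class = "epoched_dataset")
}

#' @export
print.epoched_dataset <- function(x, ...) {
  cat(sprintf("<epoched_dataset> %d samples x %d timepoints x %d modalities\n",
              nrow(x$meta), dim(x$samples)[2], dim(x$samples)[3]))
  cat("  subjects:", length(unique(x$meta$subject_id)),
      " recordings:", length(unique(x$meta$recording_id)), "\n")
  print(table(x$meta$label))
  invisible(x)
}

#' @export
dim.epoched_dataset <- function(x) dim(x$samples)

#' Number of samples in an epoched dataset
#' @param ds An `epoched_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) dim(ds$samples)[1]

#' Subset an epoched dataset by sample index
#'
#' @param ds An `epoched_dataset`.
#' @param idx Integer or logical index over samples.
#' @return An `epoched_dataset` containing the selected samples.
#' @export
subset_samples <- function(ds, idx) {
  epoched_dataset(ds$samples[idx, , , drop = FALSE], ds$meta[idx, , drop = FALSE])
}

#' Combine epoched datasets
#'
#' @param ... `epoched_dataset` objects.
#' @return A single `epoched_dataset` with samples concatenated in order.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "epoched_dataset")) {
    parts <- parts[[1]]
  }
  samples <- do.call(rbind_array3, lapply(parts, function(p) p$samples))
  meta <- bind_rows(lapply(parts, function(p) p$meta))
  epoched_dataset(samples, meta)
}

# bind 3-d arrays along the first axis without abind
rbind_array3 <- function(...) {
  arrs <- list(...)
  d2 <- dim(arrs[[1]])[2]; d3 <- dim(arrs[[1]])[3]
  ns <- vapply(arrs, function(a) dim(a)[1], integer(1))
  out <- array(0, c(sum(ns), d2, d3))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1]
    out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}
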