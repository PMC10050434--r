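# Preprocessing: raw multimodal recordings -> labeled, z-scored 30-s samples.

#' Construct a polysomnography recording
#'
#' @param signals Numeric matrix `time x 3` (EEG Fpz-Cz, EOG, EMG) sampled at
#'   100 Hz.
#' @param sampling_rate Sampling rate in Hz (must be 100).
#' @param error_marker Optional logical vector, one flag per second, `TRUE`
#'   where the acquisition system marked a recording error.
#' @return An object of class `psg_recording`.
#' @export
psg_recording <- function(signals, sampling_rate = 100, error_marker = NULL) {
  signals <- as.matrix(signals)
  if (ncol(signals) != 3L) abort("`signals` must have 3 channels (EEG, EOG, EMG)")
  if (sampling_rate != 100) abort("sampling rate must be 100 Hz")
  if (!all(is.finite(signals))) abort("signals must be finite")
  colnames(signals) <- modality_names()
  if (!is.null(error_marker)) error_marker <- as.logical(error_marker)
  structure(list(signals = signals, sampling_rate = sampling_rate,
                 error_marker = error_marker),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d timepoints (%.1f min) x 3 channels @ %g Hz\n",
              nrow(x$signals), nrow(x$signals) / x$sampling_rate / 60,
              x$sampling_rate))
  invisible(x)
}

#' Read a polysomnography EDF file
#'
#' Selects the Fpz-Cz EEG, EOG and EMG channels (dropping Pz-Oz if present),
#' checks that all three run at 100 Hz, and extracts a 1-Hz error-marker
#' channel when one exists.
#'
#' @param path Path to a `*-PSG.edf` file.
#' @return A [psg_recording()].
#' @export
read_psg_edf <- function(path) {
  edf <- read_edf(path)
  labels <- vapply(edf$signals, `[[`, "", "label")
  pick <- function(pattern, what) {
    hit <- grep(pattern, labels, ignore.case = TRUE)
    hit <- setdiff(hit, grep("Pz-Oz|marker|Annotations", labels, ignore.case = TRUE))
    if (!length(hit)) abort(sprintf("EDF is missing required channel: %s", what))
    hit[1]
  }
  idx <- c(pick("Fpz-Cz", "EEG Fpz-Cz"), pick("EOG", "EOG"), pick("EMG", "EMG"))
  rates <- vapply(edf$signals[idx], `[[`, numeric(1), "sampling_rate")
  if (any(rates != 100)) {
    abort(sprintf("channel(s) not sampled at 100 Hz: %s",
                  paste(labels[idx][rates != 100], collapse = ", ")))
  }
  signals <- do.call(cbind, lapply(edf$signals[idx], `[[`, "data"))
  marker_idx <- grep("marker", labels, ignore.case = TRUE)
  error_marker <- NULL
  if (length(marker_idx)) {
    m <- edf$signals[[marker_idx[1]]]
    if (m$sampling_rate == 1) error_marker <- m$data != 0
  }
  psg_recording(signals, 100, error_marker)
}

# Sleep-EDF annotation text -> raw stage token
stage_token <- function(text) {
  map <- c("Sleep stage W" = "W", "Sleep stage 1" = "1", "Sleep stage 2" = "2",
           "Sleep stage 3" = "3", "Sleep stage 4" = "4", "Sleep stage R" = "R",
           "Movement time" = "Movement", "Sleep stage ?" = "unknown")
  out <- unname(map[trimws(text)])
  out[is.na(out)] <- "unknown"
  out
}

#' Read a hypnogram annotation file
#'
#' Parses an EDF+ hypnogram into `(onset, duration, stage)` rows with raw
#' Rechtschaffen-Kales stage tokens (`W`, `1`–`4`, `R`, `Movement`,
#' `unknown`). Stage 4 is retained here; merging into NREM3 happens during
#' epoching.
#'
#' @param path Path to a `*-Hypnogram.edf` file.
#' @return Tibble with columns `onset`, `duration` (seconds) and `stage`.
#' @export
read_hypnogram <- function(path) {
  ann <- read_edf_annotations(path)
  tibble(onset = ann$onset, duration = ann$duration,
         stage = stage_token(ann$annotation))
}

#' Z-score each channel of a recording
#'
#' Standardizes every channel over the full recording (mean 0, sd 1),
#' separately per channel — applied per recording before epoching so that
#' cross-subject amplitude differences do not dominate learned patterns.
#'
#' @param recording A [psg_recording()].
#' @return The recording with standardized channels.
#' @export
zscore_channels <- function(recording) {
  x <- recording$signals
  for (j in seq_len(ncol(x))) {
    s <- stats::sd(x[, j])
    if (!is.finite(s) || s == 0) {
      abort(sprintf("channel %s has zero variance; cannot z-score",
                    colnames(x)[j]))
    }
    x[, j] <- (x[, j] - mean(x[, j])) / s
  }
  recording$signals <- x
  recording
}

#' Segment a recording into labeled 30-s samples
#'
#' Cuts consecutive non-overlapping 3000-point windows anchored at the
#' recording start, labels each from the hypnogram entry whose span covers
#' the window onset, merges stage 4 into NREM3, and drops windows labeled
#' Movement or unknown, windows overlapping any flagged error-marker second,
#' and any trailing partial window.
#'
#' @param recording A z-scored [psg_recording()].
#' @param hypnogram Tibble from [read_hypnogram()] (or equivalent with
#'   `onset`, `duration`, `stage`).
#' @param subject_id,recording_id,medication,sex,age Per-recording metadata
#'   attached to every retained sample.
#' @return An [epoched_dataset()].
#' @export
epoch_and_label <- function(recording, hypnogram,
                            subject_id = NA_integer_, recording_id = NA_character_,
                            medication = NA_character_, sex = NA_character_,
                            age = NA_real_) {
  epoch_len <- SAMPLES_PER_EPOCH
  n_epochs <- nrow(recording$signals) %/% epoch_len
  if (n_epochs < 1L) abort("recording shorter than one 30-s epoch")

  onsets <- (seq_len(n_epochs) - 1L) * 30
  raw_stage <- rep("uncovered", n_epochs)
  for (i in seq_len(nrow(hypnogram))) {
    covered <- onsets >= hypnogram$onset[i] &
      onsets < hypnogram$onset[i] + hypnogram$duration[i]
    raw_stage[covered] <- hypnogram$stage[i]
  }
  n_uncovered <- sum(raw_stage == "uncovered")
  if (n_uncovered > 1L) {
    abort(sprintf("hypnogram does not cover the recording: %d epochs unlabeled",
                  n_uncovered))
  }

  label_map <- c("W" = "Awake", "1" = "NREM1", "2" = "NREM2",
                 "3" = "NREM3", "4" = "NREM3", "R" = "REM")
  label <- unname(label_map[raw_stage])          # NA for Movement/unknown/uncovered

  err_drop <- rep(FALSE, n_epochs)
  if (!is.null(recording$error_marker)) {
    flagged <- which(recording$error_marker)     # flagged seconds, 1-based
    if (length(flagged)) {
      err_drop <- vapply(seq_len(n_epochs), function(e) {
        any(flagged > (e - 1L) * 30 & flagged <= e * 30)
      }, logical(1))
    }
  }

  keep <- which(!is.na(label) & !err_drop)
  if (!length(keep)) abort("no epochs retained after filtering")

  samples <- array(0, c(length(keep), epoch_len, 3L))
  for (i in seq_along(keep)) {
    e <- keep[i]
    samples[i, , ] <- recording$signals[((e - 1L) * epoch_len + 1L):(e * epoch_len), ]
  }
  meta <- tibble(label = label[keep],
                 subject_id = subject_id, recording_id = recording_id,
                 medication = medication, sex = sex, age = age,
                 epoch_index = keep)
  epoched_dataset(samples, meta)
}

#' Build a subject-wise cross-validation plan
#'
#' Draws `n_folds` independent random train/validation/test partitions at
#' the subject level (both recordings of a subject always land in the same
#' partition). With 22 subjects the split is 17/2/3; other cohort sizes use
#' proportional sizes (rounded, minimum 1 per partition).
#'
#' @param subject_ids Vector of unique subject identifiers.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed controlling the whole plan.
#' @return A tibble of class `fold_plan` with columns `fold`, `subject_id`,
#'   `role` (`train`/`validation`/`test`).
#' @export
make_folds <- function(subject_ids, n_folds = 10L, seed = 1L) {
  if (n_folds < 1L) abort("`n_folds` must be at least 1")
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n == 22L) {
    n_test <- 3L; n_val <- 2L
  } else {
    n_test <- max(1L, as.integer(round(n * 3 / 22)))
    n_val <- max(1L, as.integer(round(n * 2 / 22)))
  }
  n_train <- n - n_test - n_val
  if (n_train < 1L) abort(sprintf("cohort of %d subjects is too small to split", n))

  plan <- with_local_seed(seed, {
    bind_rows(lapply(seq_len(n_folds), function(f) {
      perm <- sample(subject_ids, n)
      tibble(fold = f, subject_id = perm,
             role = rep(c("test", "validation", "train"),
                        times = c(n_test, n_val, n_train)))
    }))
  })
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' Subjects in one partition of one fold
#'
#' @param plan A [make_folds()] plan.
#' @param fold Fold number.
#' @param role `"train"`, `"validation"`, or `"test"`.
#' @return Vector of subject ids.
#' @export
fold_subjects <- function(plan, fold, role) {
  plan$subject_id[plan$fold == fold & plan$role == role]
}

#' Load a Sleep Telemetry-style directory into an epoched dataset
#'
#' Scans `dir` for `*-PSG.edf` / `*-Hypnogram.edf` pairs (paired on the
#' shared 7-character prefix of the ST naming scheme, e.g. `ST7041J`), reads,
#' z-scores and epochs each recording, and concatenates the results. Subject
#' number and night are parsed from the prefix (`ST7<ss><n>`; night 1 =
#' placebo, night 2 = temazepam); `subjects_meta` can supply `age` and `sex`
#' per `subject_id`.
#'
#' @param dir Directory containing the EDF pairs.
#' @param subjects_meta Optional data frame with columns `subject_id`, `age`,
#'   `sex`.
#' @return An [epoched_dataset()].
#' @export
read_sleep_edf_dir <- function(dir, subjects_meta = NULL) {
  psg <- sort(list.files(dir, pattern = "-PSG\\.edf$", full.names = TRUE))
  if (!length(psg)) abort(sprintf("no *-PSG.edf files in %s", dir))
  parts <- lapply(psg, function(p) {
    prefix <- substr(basename(p), 1L, 7L)
    hyp <- list.files(dir, pattern = paste0("^", prefix, ".*-Hypnogram\\.edf$"),
                      full.names = TRUE)
    if (!length(hyp)) abort(sprintf("no hypnogram found for %s", basename(p)))
    sid <- suppressWarnings(as.integer(substr(prefix, 4L, 5L)))
    night <- suppressWarnings(as.integer(substr(prefix, 6L, 6L)))
    med <- if (!is.na(night) && night == 2L) "temazepam" else "placebo"
    age <- NA_real_; sex <- NA_character_
    if (!is.null(subjects_meta) && !is.na(sid)) {
      row <- subjects_meta[subjects_meta$subject_id == sid, , drop = FALSE]
      if (nrow(row)) { age <- row$age[1]; sex <- as.character(row$sex[1]) }
    }
    rec <- zscore_channels(read_psg_edf(p))
    epoch_and_label(rec, read_hypnogram(hyp[1]),
                    subject_id = sid, recording_id = prefix,
                    medication = med, sex = sex, age = age)
  })
  bind_datasets(parts)
}

#' Dataset composition summary
#'
#' Sample count and percentage share of each stage class — the
#' dataset-construction numbers quoted when describing a corpus.
#'
#' @param ds An [epoched_dataset()].
#' @return Tibble with columns `label`, `n`, `share_pct`; total sample count
#'   in attribute `n_total`.
#' @export
dataset_composition <- function(ds) {
  tab <- table(ds$meta$label)
  out <- tibble(label = names(tab), n = as.integer(tab),
                share_pct = 100 * as.integer(tab) / sum(tab))
  attr(out, "n_total") <- sum(tab)
  out
}

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so that seeded generators never disturb the
#' surrounding random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
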