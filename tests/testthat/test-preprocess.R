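# Preprocessing: EDF round trips, epoching and labeling, fold plans, and
# the directory ingest path exercised on synthetic Sleep-EDF-style files.

test_that("EDF write/read round trip is exact up to 16-bit quantization", {
  tmp <- withr::local_tempfile(fileext = ".edf")
  set.seed(21)
  eeg <- rnorm(300, sd = 40)           # 3 s at 100 Hz
  marker <- c(0, 1, 0)                 # 3 s at 1 Hz
  write_edf(tmp, list(`EEG Fpz-Cz` = eeg, `Marker` = marker),
            sampling_rates = c(100L, 1L))
  edf <- read_edf(tmp)
  expect_equal(length(edf$signals), 2)
  labels <- vapply(edf$signals, `[[`, "", "label")
  expect_equal(labels, c("EEG Fpz-Cz", "Marker"))
  expect_equal(edf$signals[[1]]$sampling_rate, 100)
  step <- (max(eeg) - min(eeg)) / 65535
  expect_lt(max(abs(edf$signals[[1]]$data - eeg)), step)
  expect_equal(edf$signals[[2]]$data, marker, tolerance = 1e-4)
})

test_that("EDF+ annotation round trip preserves onsets, durations and text", {
  tmp <- withr::local_tempfile(fileext = ".edf")
  onsets <- c(0, 30, 90)
  durations <- c(30, 60, 30)
  texts <- c("Sleep stage W", "Sleep stage 2", "Sleep stage R")
  write_edf_annotations(tmp, onsets, durations, texts)
  ann <- read_edf_annotations(tmp)
  expect_equal(ann$onset, onsets)
  expect_equal(ann$duration, durations)
  expect_equal(ann$annotation, texts)
})

test_that("stage tokens map Sleep-EDF texts including stage 4 and movement", {
  expect_equal(modex:::stage_token(c("Sleep stage W", "Sleep stage 4",
                             "Movement time", "Sleep stage ?", "garbage")),
               c("W", "4", "Movement", "unknown", "unknown"))
})

test_that("z-scoring standardizes each channel and rejects flat channels", {
  set.seed(31)
  sig <- cbind(rnorm(6000, 5, 3), rnorm(6000, -2, 0.5), rnorm(6000))
  rec <- zscore_channels(psg_recording(sig))
  for (j in 1:3) {
    expect_equal(mean(rec$signals[, j]), 0, tolerance = 1e-12)
    expect_equal(sd(rec$signals[, j]), 1, tolerance = 1e-12)
  }
  flat <- cbind(rnorm(6000), rep(1, 6000), rnorm(6000))
  expect_error(zscore_channels(psg_recording(flat)), "zero variance")
})

test_that("epoching labels windows from the hypnogram and merges stage 4", {
  set.seed(41)
  sig <- matrix(rnorm(5 * 3000 * 3), 5 * 3000, 3)
  hyp <- tibble::tibble(onset = c(0, 30, 60, 90, 120),
                        duration = rep(30, 5),
                        stage = c("W", "1", "4", "Movement", "R"))
  ds <- epoch_and_label(psg_recording(sig), hyp, subject_id = 7L)
  expect_equal(as.character(ds$meta$label),
               c("Awake", "NREM1", "NREM3", "REM"))   # stage 4 -> NREM3
  expect_equal(ds$meta$epoch_index, c(1L, 2L, 3L, 5L)) # Movement dropped
  expect_equal(dim(ds$samples), c(4, 3000, 3))
  # window content is the exact slice of the recording
  expect_equal(unname(ds$samples[2, , ]), sig[3001:6000, ])
  expect_true(all(ds$meta$subject_id == 7L))
})

test_that("one long hypnogram entry labels many epochs; partial windows drop", {
  sig <- matrix(rnorm(2.5 * 3000 * 3), 2.5 * 3000, 3)
  hyp <- tibble::tibble(onset = 0, duration = 300, stage = "2")
  ds <- epoch_and_label(psg_recording(sig), hyp)
  expect_equal(nrow(ds$meta), 2)                      # trailing half dropped
  expect_true(all(ds$meta$label == "NREM2"))
})

test_that("epochs overlapping flagged error seconds are dropped", {
  sig <- matrix(rnorm(3 * 3000 * 3), 3 * 3000, 3)
  marker <- rep(FALSE, 90)
  marker[35] <- TRUE                                  # second 35 -> epoch 2
  hyp <- tibble::tibble(onset = 0, duration = 90, stage = "W")
  ds <- epoch_and_label(psg_recording(sig, error_marker = marker), hyp)
  expect_equal(ds$meta$epoch_index, c(1L, 3L))
})

test_that("an uncovered recording tail beyond one epoch is an error", {
  sig <- matrix(rnorm(4 * 3000 * 3), 4 * 3000, 3)
  hyp <- tibble::tibble(onset = 0, duration = 60, stage = "W")
  expect_error(epoch_and_label(psg_recording(sig), hyp), "does not cover")
  # exactly one uncovered epoch is tolerated (dropped silently)
  hyp2 <- tibble::tibble(onset = 0, duration = 90, stage = "W")
  ds <- epoch_and_label(psg_recording(sig), hyp2)
  expect_equal(nrow(ds$meta), 3)
})

test_that("fold plans use the 17/2/3 split at 22 subjects and scale otherwise", {
  plan <- make_folds(1:22, n_folds = 10, seed = 2)
  expect_s3_class(plan, "fold_plan")
  counts <- table(plan$role[plan$fold == 1])
  expect_equal(as.vector(counts[c("train", "validation", "test")]),
               c(17L, 2L, 3L))
  # every fold is a full partition of the subjects
  for (f in c(1, 10)) {
    expect_setequal(plan$subject_id[plan$fold == f], 1:22)
    expect_equal(length(intersect(fold_subjects(plan, f, "train"),
                                  fold_subjects(plan, f, "test"))), 0)
  }
  # 11 subjects -> proportional 8/1/2
  plan11 <- make_folds(1:11, n_folds = 2, seed = 3)
  counts11 <- table(plan11$role[plan11$fold == 1])
  expect_equal(as.vector(counts11[c("train", "validation", "test")]),
               c(8L, 1L, 2L))
  expect_identical(make_folds(1:22, 3, seed = 9), make_folds(1:22, 3, seed = 9))
  expect_error(make_folds(1:2, 1), "too small")
})

test_that("dataset_composition reports counts and percentage shares", {
  meta <- tibble::tibble(label = c(rep("Awake", 3), rep("NREM2", 6),
                                   "REM"),
                         subject_id = 1L, recording_id = "r", medication = "placebo",
                         sex = "male", age = 30, epoch_index = 1:10)
  ds <- epoched_dataset(array(0, c(10, 3000, 3)), meta)
  comp <- dataset_composition(ds)
  expect_equal(comp$n[comp$label == "NREM2"], 6)
  expect_equal(comp$share_pct[comp$label == "Awake"], 30)
  expect_equal(attr(comp, "n_total"), 10)
  expect_equal(sum(comp$share_pct), 100)
})

test_that("synthetic Sleep-EDF pairs ingest through the real-data path", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(epochs_per_recording = 4)
  cohort <- make_cohort(2, seed = 51)
  # subject 1, both nights; subject 2, night 1 with an error second
  write_sleep_edf_pair(synth_recording(cohort[1, ], "placebo", cfg, seed = 61),
                       dir, subject_id = 1, night = 1)
  write_sleep_edf_pair(synth_recording(cohort[1, ], "temazepam", cfg, seed = 62),
                       dir, subject_id = 1, night = 2)
  write_sleep_edf_pair(synth_recording(cohort[2, ], "placebo", cfg, seed = 63),
                       dir, subject_id = 2, night = 1,
                       error_seconds = 40L)        # second 40 -> epoch 2
  meta <- tibble::tibble(subject_id = cohort$subject_id,
                         age = cohort$age, sex = cohort$sex)
  ds <- read_sleep_edf_dir(dir, meta)
  expect_s3_class(ds, "epoched_dataset")
  # 4 + 4 epochs for subject 1, 3 for subject 2 (one dropped by the marker)
  expect_equal(n_samples(ds), 11)
  expect_equal(sum(ds$meta$subject_id == 2), 3)
  expect_false(2L %in% ds$meta$epoch_index[ds$meta$subject_id == 2])
  expect_setequal(unique(ds$meta$medication[ds$meta$subject_id == 1]),
                  c("placebo", "temazepam"))
  expect_equal(unique(ds$meta$sex[ds$meta$subject_id == 1]),
               cohort$sex[1])
  # the ingested signal matches the generated one up to z-scoring and
  # 16-bit quantization
  rec <- synth_recording(cohort[1, ], "placebo", cfg, seed = 61)
  z <- scale(rec$signals[, 1])
  got <- as.vector(t(ds$samples[ds$meta$subject_id == 1 &
                                  ds$meta$medication == "placebo", , 1]))
  expect_gt(cor(got, as.vector(z)), 0.999)
  expect_error(read_sleep_edf_dir(withr::local_tempdir()), "no \\*-PSG")
})

test_that("read_psg_edf selects Fpz-Cz/EOG/EMG and enforces 100 Hz", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x-PSG.edf")
  write_edf(path, list(`EEG Fpz-Cz` = rnorm(200), `EEG Pz-Oz` = rnorm(200),
                       `EOG horizontal` = rnorm(200),
                       `EMG submental` = rnorm(200)),
            sampling_rates = 100L)
  rec <- read_psg_edf(path)
  expect_equal(ncol(rec$signals), 3)
  # missing EMG errors
  path2 <- file.path(dir, "y-PSG.edf")
  write_edf(path2, list(`EEG Fpz-Cz` = rnorm(200),
                        `EOG horizontal` = rnorm(200)),
            sampling_rates = 100L)
  expect_error(read_psg_edf(path2), "EMG")
  # wrong sampling rate errors
  path3 <- file.path(dir, "z-PSG.edf")
  write_edf(path3, list(`EEG Fpz-Cz` = rnorm(100), `EOG horizontal` = rnorm(200),
                        `EMG submental` = rnorm(200)),
            sampling_rates = c(50L, 100L, 100L))
  expect_error(read_psg_edf(path3), "100 Hz")
})

test_that("datasets subset and bind consistently", {
  meta <- tibble::tibble(label = rep("Awake", 4), subject_id = 1:4,
                         recording_id = "r", medication = "placebo",
                         sex = "male", age = 30, epoch_index = 1:4)
  ds <- epoched_dataset(array(rnorm(4 * 3000 * 3), c(4, 3000, 3)), meta)
  sub <- subset_samples(ds, c(2, 4))
  expect_equal(n_samples(sub), 2)
  expect_equal(sub$meta$subject_id, c(2L, 4L))
  expect_equal(sub$samples[1, , ], ds$samples[2, , ])
  both <- bind_datasets(sub, subset_samples(ds, 1))
  expect_equal(n_samples(both), 3)
  expect_equal(both$meta$subject_id, c(2L, 4L, 1L))
})
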