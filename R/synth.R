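# Synthetic multimodal sleep-like recordings with known ground truth.
#
# Each 30-s epoch of a synthetic recording is a class-specific band-limited
# oscillation per modality (frequency drawn inside the configured band,
# random phase) plus white noise. Covariate effects multiply the oscillation
# amplitude of targeted (class, modality) cells, which is the simplest
# mechanism the downstream covariate regression can recover.

#' Generate a synthetic subject cohort
#'
#' Ages are drawn from a normal distribution (default mean 40, sd 18)
#' truncated below at `age_min`; sex is drawn with probability `p_female`
#' (default 15/22, the female share of a typical insomnia telemetry cohort).
#' Every subject gets two recording slots, one per medication condition.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed.
#' @param age_mean,age_sd,age_min Age distribution parameters (years).
#' @param p_female Probability of female sex.
#' @return Tibble with columns `subject_id`, `age`, `sex`, `n_recordings`.
#' @export
make_cohort <- function(n_subjects, seed = 1L, age_mean = 40, age_sd = 18,
                        age_min = 18, p_female = 15 / 22) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1L) {
    abort("`n_subjects` must be a positive integer")
  }
  n_subjects <- as.integer(n_subjects)
  with_local_seed(seed, {
    age <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      repeat {
        a <- stats::rnorm(1, age_mean, age_sd)
        if (a >= age_min) break
      }
      age[i] <- a
    }
    sex <- ifelse(stats::runif(n_subjects) < p_female, "female", "male")
    tibble(subject_id = seq_len(n_subjects), age = age, sex = sex,
           n_recordings = 2L)
  })
}

#' Configuration for the synthetic generator
#'
#' @param epochs_per_recording 30-s epochs per recording.
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param epoch_len Epoch length in seconds (default 30).
#' @param profiles Class spectral profiles: a data frame with columns
#'   `label`, `modality`, `freq` (center frequency, Hz), `bandwidth` (Hz),
#'   `amplitude` (oscillation amplitude in noise-sd units). All 5 classes
#'   must be present. Defaults loosely mimic sleep physiology (slow
#'   high-amplitude EEG in NREM3, EOG-dominant NREM1, ...) but are pure test
#'   fixtures.
#' @param covariate_effects Optional data frame with columns `variable`
#'   (`"sex"`, `"medication"`, or `"age"`), `label`, `modality`, `effect`.
#'   For sex/medication the targeted cell's amplitude is multiplied by
#'   `effect` when the indicator is 1 (female / temazepam); for age it is
#'   multiplied by `1 + effect * (age - 40)` (per-year fractional change
#'   around the cohort center).
#' @param noise_sd White-noise standard deviation before z-scoring (fixed
#'   1.0 by design; signal-to-noise is controlled via profile amplitudes).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(epochs_per_recording = 50L, sampling_rate = 100,
                         epoch_len = 30, profiles = default_profiles(),
                         covariate_effects = NULL, noise_sd = 1) {
  if ((sampling_rate * epoch_len) %% 1 != 0) {
    abort("sampling_rate x epoch_len must give an integer number of samples")
  }
  profiles <- as_tibble(profiles)
  if (!all(stage_levels() %in% profiles$label)) {
    abort("`profiles` must cover all 5 stage classes")
  }
  if (any(profiles$amplitude < 0)) abort("profile amplitudes must be >= 0")
  if (!is.null(covariate_effects)) covariate_effects <- as_tibble(covariate_effects)
  structure(list(epochs_per_recording = as.integer(epochs_per_recording),
                 sampling_rate = sampling_rate, epoch_len = epoch_len,
                 profiles = profiles, covariate_effects = covariate_effects,
                 noise_sd = noise_sd),
            class = "synth_config")
}

#' Default class spectral profiles
#'
#' Sleep-flavored fixtures: alpha-band EEG plus muscle tone when awake,
#' EOG-dominant NREM1, spindle-band EEG for NREM2, slow high-amplitude EEG
#' for NREM3, and active EOG with muscle atonia for REM.
#'
#' @return Tibble with columns `label`, `modality`, `freq`, `bandwidth`,
#'   `amplitude`.
#' @export
default_profiles <- function() {
  tibble(
    label = rep(stage_levels(), each = 3),
    modality = rep(modality_names(), times = 5),
    freq      = c(10, 2.0, 35,   7, 0.7, 30,   13, 0.5, 30,   1, 0.3, 30,   8, 0.8, 25),
    bandwidth = c( 2, 0.5,  8,   2, 0.3,  8,    2, 0.3,  8, 0.5, 0.2,  8,   2, 0.4,  8),
    amplitude = c(0.6, 0.3, 0.9,  0.3, 1.0, 0.3,  1.0, 0.2, 0.2,  1.5, 0.2, 0.1,  0.4, 0.9, 0.05)
  )
}

#' Profiles where a single modality carries all class information
#'
#' Classes differ only in the target channel's oscillation frequency; the
#' other channels carry no oscillation at all by default (white noise only),
#' so the target modality is the only one carrying class information. Used
#' to plant a known ground-truth modality importance.
#'
#' @param modality The discriminative modality (default `"EEG"`).
#' @param amplitude Oscillation amplitude of the discriminative channel.
#' @param background_amplitude Amplitude of the non-discriminative channels.
#' @return Profile tibble for [synth_config()].
#' @export
planted_modality_profiles <- function(modality = "EEG", amplitude = 1.5,
                                      background_amplitude = 0) {
  mods <- modality_names()
  if (!modality %in% mods) abort("unknown modality")
  freqs <- c(2, 6, 10, 16, 22)                       # one per class, well separated
  bg_freq <- c(EEG = 10, EOG = 1, EMG = 30)
  rows <- list()
  for (ci in seq_along(stage_levels())) {
    for (m in mods) {
      target <- m == modality
      f <- if (target) freqs[ci] else unname(bg_freq[m])
      a <- if (target) amplitude else background_amplitude
      rows[[length(rows) + 1L]] <- tibble(
        label = stage_levels()[ci], modality = m,
        freq = f, bandwidth = 1, amplitude = a)
    }
  }
  bind_rows(rows)
}

# amplitude multiplier from the configured covariate effects
covariate_multiplier <- function(effects, label, modality, age, sex, medication) {
  if (is.null(effects)) return(1)
  rows <- effects[effects$label == label & effects$modality == modality, , drop = FALSE]
  mult <- 1
  for (i in seq_len(nrow(rows))) {
    v <- rows$variable[i]; e <- rows$effect[i]
    if (v == "sex" && sex == "female") mult <- mult * e
    if (v == "medication" && medication == "temazepam") mult <- mult * e
    if (v == "age") mult <- mult * (1 + e * (age - 40))
  }
  max(mult, 0)
}

#' Synthesize one recording
#'
#' The hypnogram cycles deterministically through the five stages so that
#' every class appears; each epoch's signal is the class's band-limited
#' oscillation per modality plus white noise.
#'
#' @param subject One row of a [make_cohort()] tibble.
#' @param medication `"placebo"` or `"temazepam"`.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List of class `synth_recording` with `signals` (time x 3),
#'   `hypnogram` (onset/duration/stage tokens), `subject_id`, `medication`.
#' @export
synth_recording <- function(subject, medication, config, seed = 1L) {
  if (!medication %in% c("placebo", "temazepam")) {
    abort("`medication` must be \"placebo\" or \"temazepam\"")
  }
  fs <- config$sampling_rate
  spe <- as.integer(fs * config$epoch_len)
  n_ep <- config$epochs_per_recording
  labels <- rep(stage_levels(), length.out = n_ep)
  t_ep <- (seq_len(spe) - 1) / fs
  token <- c(Awake = "W", NREM1 = "1", NREM2 = "2", NREM3 = "3", REM = "R")

  signals <- with_local_seed(seed, {
    out <- matrix(0, n_ep * spe, 3)
    for (e in seq_len(n_ep)) {
      lab <- labels[e]
      for (mi in seq_len(3L)) {
        m <- modality_names()[mi]
        pr <- config$profiles[config$profiles$label == lab &
                                config$profiles$modality == m, , drop = FALSE]
        x <- stats::rnorm(spe, 0, config$noise_sd)
        if (nrow(pr) && pr$amplitude[1] > 0) {
          f <- stats::runif(1, pr$freq[1] - pr$bandwidth[1] / 2,
                            pr$freq[1] + pr$bandwidth[1] / 2)
          phase <- stats::runif(1, 0, 2 * pi)
          amp <- pr$amplitude[1] *
            covariate_multiplier(config$covariate_effects, lab, m,
                                 subject$age, subject$sex, medication)
          x <- x + amp * sin(2 * pi * f * t_ep + phase)
        }
        out[((e - 1L) * spe + 1L):(e * spe), mi] <- x
      }
    }
    out
  })
  structure(list(signals = signals,
                 hypnogram = tibble(onset = (seq_len(n_ep) - 1) * config$epoch_len,
                                    duration = config$epoch_len,
                                    stage = unname(token[labels])),
                 subject_id = subject$subject_id, medication = medication),
            class = "synth_recording")
}

#' Assemble a full synthetic dataset
#'
#' Generates one recording per (subject, medication condition), z-scores and
#' epochs each through the preprocessing operations, and concatenates
#' everything with full metadata.
#'
#' @param cohort A [make_cohort()] tibble.
#' @param config A [synth_config()].
#' @param seed Integer seed for the whole dataset.
#' @return An [epoched_dataset()].
#' @export
synth_dataset <- function(cohort, config, seed = 1L) {
  if (!nrow(cohort)) abort("`cohort` must contain at least one subject")
  parts <- list()
  idx <- 0L
  for (si in seq_len(nrow(cohort))) {
    subj <- cohort[si, ]
    for (med in c("placebo", "temazepam")) {
      idx <- idx + 1L
      rec_seed <- (as.integer(seed) + 7919L * idx) %% 2147483562L
      rec <- synth_recording(subj, med, config, seed = rec_seed)
      psg <- zscore_channels(psg_recording(rec$signals, config$sampling_rate))
      parts[[idx]] <- epoch_and_label(
        psg, rec$hypnogram,
        subject_id = subj$subject_id,
        recording_id = sprintf("S%02d-%s", subj$subject_id, med),
        medication = med, sex = subj$sex, age = subj$age)
    }
  }
  bind_datasets(parts)
}

#' Ground-truth modality ranking implied by a configuration
#'
#' Ranks modalities per class by their configured oscillation amplitude —
#' the oracle against which importance-recovery tests compare explanation
#' methods. Ties share a rank.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `label`, `modality`, `amplitude`, `rank`
#'   (1 = most discriminative amplitude; ties share the minimum rank).
#' @export
ground_truth_ranking <- function(config) {
  config$profiles |>
    group_by(.data$label) |>
    mutate(rank = rank(-.data$amplitude, ties.method = "min")) |>
    ungroup() |>
    select("label", "modality", "amplitude", "rank") |>
    arrange(.data$label, .data$rank)
}

#' Write a synthetic recording as a Sleep-EDF-style file pair
#'
#' Emits `<prefix>00-PSG.edf` (EEG Fpz-Cz, Pz-Oz placeholder, EOG, EMG and a
#' 1-Hz marker channel) and `<prefix>0C-Hypnogram.edf` using the ST naming
#' scheme, so the real-data ingest path can be exercised offline on fully
#' synthetic files.
#'
#' @param rec A [synth_recording()].
#' @param dir Output directory.
#' @param subject_id Two-digit subject number used in the file name.
#' @param night Night number (1 = placebo, 2 = temazepam).
#' @param error_seconds Optional integer vector of 1-based seconds to flag in
#'   the error-marker channel.
#' @return Invisibly, the two file paths.
#' @export
write_sleep_edf_pair <- function(rec, dir, subject_id, night,
                                 error_seconds = NULL) {
  prefix <- sprintf("ST7%02d%dJ", subject_id, night)
  psg_path <- file.path(dir, paste0(prefix, "0-PSG.edf"))
  hyp_path <- file.path(dir, paste0(prefix, "C-Hypnogram.edf"))
  n_sec <- nrow(rec$signals) %/% 100L
  marker <- numeric(n_sec)
  if (!is.null(error_seconds)) marker[error_seconds] <- 1
  write_edf(psg_path,
            signals = list(`EEG Fpz-Cz` = rec$signals[, 1],
                           `EEG Pz-Oz` = rec$signals[, 1] * 0,
                           `EOG horizontal` = rec$signals[, 2],
                           `EMG submental` = rec$signals[, 3],
                           `Marker` = marker),
            sampling_rates = c(100L, 100L, 100L, 100L, 1L))
  token_text <- c("W" = "Sleep stage W", "1" = "Sleep stage 1",
                  "2" = "Sleep stage 2", "3" = "Sleep stage 3",
                  "4" = "Sleep stage 4", "R" = "Sleep stage R",
                  "Movement" = "Movement time", "unknown" = "Sleep stage ?")
  write_edf_annotations(hyp_path, rec$hypnogram$onset, rec$hypnogram$duration,
                        unname(token_text[rec$hypnogram$stage]))
  invisible(c(psg_path, hyp_path))
}

#' Band power of a signal
#'
#' Mean squared FFT magnitude inside a frequency band — used by generator
#' sanity checks to verify planted spectral structure.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param lo,hi Band edges (Hz, inclusive).
#' @return Scalar band power.
#' @export
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= lo & freqs <= hi & freqs <= fs / 2
  sum(sp[keep]) / n
}
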