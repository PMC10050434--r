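# Global and local ablation importance.
#
# Ablation replaces one modality wholesale — with zeros, or with simulated
# mains interference (a 50-Hz sinusoid plus Gaussian noise) — and measures
# the change in model behavior. At a 100-Hz sampling rate 50 Hz sits exactly
# at Nyquist, where a phase-0 sinusoid samples to all zeros; the default
# phase of pi/2 makes it survive sampling as the alternating sequence
# +a, -a, +a, ...

#' Ablation specification
#'
#' @param method `"zero"` or `"line_noise"`.
#' @param modality Channel to replace: `"EEG"`, `"EOG"`, `"EMG"` or index
#'   1-3.
#' @param freq Sinusoid frequency in Hz (default 50, mains interference).
#' @param amplitude Sinusoid amplitude (default 0.1, in z-scored units).
#' @param noise_mean,noise_sd Gaussian noise parameters (defaults 0 and 0.1).
#' @param phase Sinusoid phase in radians (default `pi/2`; see module notes
#'   on the Nyquist limit).
#' @param seed Integer seed for the noise stream (fresh noise per sample,
#'   reproducible per call).
#' @return An object of class `ablation_spec`.
#' @export
ablation_spec <- function(method = c("zero", "line_noise"), modality = "EEG",
                          freq = 50, amplitude = 0.1, noise_mean = 0,
                          noise_sd = 0.1, phase = pi / 2, seed = 1L) {
  method <- match.arg(method)
  if (is.character(modality)) {
    modality <- match(modality, modality_names())
  }
  if (is.na(modality) || modality < 1L || modality > 3L) {
    abort("`modality` must be EEG, EOG, EMG or an index 1-3")
  }
  if (amplitude < 0 || noise_sd < 0) abort("amplitude and noise sd must be >= 0")
  structure(list(method = method, modality = as.integer(modality), freq = freq,
                 amplitude = amplitude, noise_mean = noise_mean,
                 noise_sd = noise_sd, phase = phase, seed = as.integer(seed)),
            class = "ablation_spec")
}

#' Replace one modality across samples
#'
#' The target channel is fully replaced (never added to): by zeros, or by
#' `amplitude * sin(2*pi*freq*t + phase) + N(noise_mean, noise_sd^2)`
#' evaluated on the 100-Hz sample grid with noise drawn independently per
#' sample. All other channels are returned bit-identical.
#'
#' @param samples Numeric array `n x timepoints x 3`, or an
#'   [epoched_dataset()] (its samples array is used).
#' @param spec An [ablation_spec()].
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @return The modified sample array.
#' @export
ablate_modality <- function(samples, spec, sampling_rate = 100) {
  if (inherits(samples, "epoched_dataset")) samples <- samples$samples
  if (length(dim(samples)) == 2L) samples <- array(samples, c(1L, dim(samples)))
  d <- dim(samples)
  m <- spec$modality
  if (spec$method == "zero") {
    samples[, , m] <- 0
    return(samples)
  }
  tt <- (seq_len(d[2]) - 1) / sampling_rate
  sinusoid <- spec$amplitude * sin(2 * pi * spec$freq * tt + spec$phase)
  noise <- with_local_seed(spec$seed, {
    matrix(stats::rnorm(d[1] * d[2], spec$noise_mean, spec$noise_sd), d[1], d[2])
  })
  samples[, , m] <- sweep(noise, 2L, -sinusoid)        # noise + sinusoid
  samples
}

#' Percent change
#'
#' `100 * (modified - unmodified) / unmodified`; undefined (NA) where the
#' unmodified value is zero.
#'
#' @param modified,unmodified Numeric vectors.
#' @return Numeric vector of percent changes.
#' @export
percent_change <- function(modified, unmodified) {
  ifelse(unmodified == 0, NA_real_, 100 * (modified - unmodified) / unmodified)
}

#' Global ablation importance for one fold
#'
#' Computes confusion-group counts on the unmodified test set, re-evaluates
#' after replacing each modality in turn, and reports the percent change in
#' each (true class, predicted class) cell count. Cells empty before
#' ablation are undefined and propagate as missing.
#'
#' @param model A trained [build_cnn()] model.
#' @param test_set [epoched_dataset()] of the fold's test subjects.
#' @param method `"zero"` or `"line_noise"`.
#' @param fold Fold identifier attached to the result.
#' @param ... Further arguments to [ablation_spec()] (noise parameters,
#'   seed).
#' @return Tibble of class `global_ablation` with columns `fold`, `true`,
#'   `predicted`, `modality`, `method`, `unmodified_n`, `modified_n`, `pcg`.
#' @export
global_ablation <- function(model, test_set, method = "zero", fold = 1L, ...) {
  if (!n_samples(test_set)) abort("empty test set")
  true <- test_set$meta$label
  base_pred <- predict_classes(model, test_set)
  base_counts <- confusion_group_counts(true, base_pred)
  out <- list()
  for (m in 1:3) {
    spec <- ablation_spec(method = method, modality = m, ...)
    mod_pred <- predict_classes(model, ablate_modality(test_set$samples, spec))
    mod_counts <- confusion_group_counts(true, mod_pred)
    base_tbl <- group_counts_tbl(base_counts)
    out[[m]] <- tibble(fold = fold, true = base_tbl$true,
                       predicted = base_tbl$predicted,
                       modality = modality_names()[m], method = method,
                       unmodified_n = base_tbl$n,
                       modified_n = group_counts_tbl(mod_counts)$n,
                       pcg = percent_change(group_counts_tbl(mod_counts)$n,
                                            base_tbl$n))
  }
  res <- bind_rows(out)
  class(res) <- c("global_ablation", class(res))
  res
}

#' Local ablation importance of one sample
#'
#' Fixes the top class of the unmodified prediction, replaces one modality,
#' and reports the percent change of the top-class probability.
#'
#' @param model A trained model.
#' @param sample Numeric `timepoints x 3` matrix (or `1 x timepoints x 3`).
#' @param spec An [ablation_spec()].
#' @return One-row tibble with `modality`, `top_class`, `p_unmodified`,
#'   `p_modified`, `pcg`.
#' @export
local_ablation_pcg <- function(model, sample, spec) {
  if (length(dim(sample)) == 2L) sample <- array(sample, c(1L, dim(sample)))
  p0 <- predict_proba(model, sample)[1, ]
  top <- as.integer(which.max(p0))
  p1 <- predict_proba(model, ablate_modality(sample, spec))[1, ]
  tibble(modality = modality_names()[spec$modality],
         top_class = stage_levels()[top],
         p_unmodified = unname(p0[top]), p_modified = unname(p1[top]),
         pcg = percent_change(unname(p1[top]), unname(p0[top])))
}

#' Local ablation over a dataset
#'
#' Vectorized [local_ablation_pcg()] over every sample and every modality.
#'
#' @param model A trained model.
#' @param dataset An [epoched_dataset()].
#' @param method `"zero"` or `"line_noise"`.
#' @param fold Fold identifier attached to the records.
#' @param ... Further arguments to [ablation_spec()].
#' @return Tibble of class `local_ablation` with one row per (sample,
#'   modality): `sample_id`, `fold`, `true`, `predicted` (top class),
#'   `modality`, `method`, `pcg`, plus the sample's covariate metadata
#'   (`subject_id`, `medication`, `sex`, `age`, `epoch_index`).
#' @export
local_ablation <- function(model, dataset, method = "zero", fold = 1L, ...) {
  if (!n_samples(dataset)) abort("empty dataset")
  p0 <- predict_proba(model, dataset$samples)
  top <- max.col(p0, ties.method = "first")
  n <- nrow(p0)
  p0_top <- p0[cbind(seq_len(n), top)]
  out <- list()
  for (m in 1:3) {
    spec <- ablation_spec(method = method, modality = m, ...)
    p1 <- predict_proba(model, ablate_modality(dataset$samples, spec))
    out[[m]] <- tibble(sample_id = seq_len(n), fold = fold,
                       true = as.character(dataset$meta$label),
                       predicted = stage_levels()[top],
                       modality = modality_names()[m], method = method,
                       pcg = percent_change(p1[cbind(seq_len(n), top)], p0_top),
                       subject_id = dataset$meta$subject_id,
                       medication = dataset$meta$medication,
                       sex = dataset$meta$sex, age = dataset$meta$age,
                       epoch_index = dataset$meta$epoch_index)
  }
  res <- bind_rows(out)
  class(res) <- c("local_ablation", class(res))
  res
}

#' Aggregate local ablation records to global importance
#'
#' Within each fold, the mean absolute percent change over a classification
#' group's samples; across folds, the median. Groups empty in a fold are
#' excluded from that fold.
#'
#' @param records A [local_ablation()] tibble (possibly several folds bound
#'   together).
#' @return Tibble with `true`, `predicted`, `modality`, `value` (median
#'   across folds of the per-fold mean |PCG|), `n_folds`.
#' @export
local_to_global <- function(records) {
  if (!nrow(records)) abort("no local ablation records")
  records |>
    filter(!is.na(.data$pcg)) |>
    group_by(.data$fold, .data$true, .data$predicted, .data$modality) |>
    summarise(mean_abs = mean(abs(.data$pcg)), .groups = "drop") |>
    group_by(.data$true, .data$predicted, .data$modality) |>
    summarise(value = stats::median(.data$mean_abs), n_folds = n(),
              .groups = "drop")
}

#' Compare two global ablation methods with t-tests
#'
#' Per (true class, predicted class, modality): a two-tailed two-sample
#' t-test on the per-fold PCG values of the two methods (pooled variance by
#' default; Welch via `var_equal = FALSE`; paired optional). Folds where a
#' cell is undefined under either method are dropped pairwise; cells with
#' fewer than two defined folds are flagged-skipped.
#'
#' @param result_zero,result_noise [global_ablation()] tibbles covering the
#'   same folds.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @param paired Pair folds instead of treating them as independent samples.
#' @return Tibble with `true`, `predicted`, `modality`, `t`, `p_value`,
#'   `n_folds`, `skipped`.
#' @export
compare_methods_ttests <- function(result_zero, result_noise,
                                   var_equal = TRUE, paired = FALSE) {
  key <- c("true", "predicted", "modality")
  joined <- dplyr::inner_join(
    result_zero |> select(all_of(c(key, "fold", "pcg"))) |>
      dplyr::rename(pcg_zero = "pcg"),
    result_noise |> select(all_of(c(key, "fold", "pcg"))) |>
      dplyr::rename(pcg_noise = "pcg"),
    by = c(key, "fold"))
  joined |>
    group_by(across(all_of(key))) |>
    summarise({
      ok <- !is.na(.data$pcg_zero) & !is.na(.data$pcg_noise)
      x <- .data$pcg_zero[ok]; y <- .data$pcg_noise[ok]
      if (length(x) < 2L) {
        tibble(t = NA_real_, p_value = NA_real_, n_folds = length(x),
               skipped = TRUE)
      } else if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        d <- mean(x) - mean(y)
        tibble(t = if (d == 0) 0 else sign(d) * Inf,
               p_value = if (d == 0) 1 else 0,
               n_folds = length(x), skipped = FALSE)
      } else {
        tt <- stats::t.test(x, y, var.equal = var_equal, paired = paired)
        tibble(t = unname(tt$statistic), p_value = tt$p.value,
               n_folds = length(x), skipped = FALSE)
      }
    }, .groups = "drop")
}
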