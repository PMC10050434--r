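# Regression of local-explanation magnitudes on clinical/demographic
# covariates, with Benjamini-Hochberg FDR control.
#
# One ordinary-least-squares fit per (modality, true class, predicted
# class) cell: absolute importance ~ age + medication + sex, all three main
# effects jointly. Coding: sex female = 1, male = 0 (a positive sex
# coefficient means female samples carry more importance); medication
# temazepam = 1, placebo = 0. FDR families are the 25 classification-group
# p-values per (variable, modality).

#' Build the regression design for one cell
#'
#' @param rows Data frame with columns `importance`, `age`, `sex`
#'   (`"female"`/`"male"`), `medication` (`"placebo"`/`"temazepam"`).
#' @return List with `response` (numeric), `predictors` (tibble with `age`,
#'   `medication`, `sex` columns, 0/1 coded), and `skip` (character reason,
#'   or `NULL` if the design is usable).
#' @export
build_design_matrix <- function(rows) {
  predictors <- tibble(age = rows$age,
                       medication = as.integer(rows$medication == "temazepam"),
                       sex = as.integer(rows$sex == "female"))
  skip <- NULL
  for (v in names(predictors)) {
    if (length(unique(predictors[[v]])) < 2L) {
      skip <- c(skip, sprintf("constant predictor: %s", v))
    }
  }
  list(response = rows$importance, predictors = predictors, skip = skip)
}

#' Ordinary least squares with per-coefficient p-values
#'
#' @param response Numeric response vector.
#' @param predictors Data frame of numeric predictors (an intercept is added).
#' @return Tibble with `term`, `estimate`, `p_value`; or `NULL` with a
#'   warning if the design is rank deficient or has too few rows.
#' @export
ols_fit <- function(response, predictors) {
  df <- cbind(data.frame(.y = response), as.data.frame(predictors))
  if (nrow(df) <= ncol(predictors) + 1L) return(NULL)
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) return(NULL)
  cf <- summary(fit)$coefficients
  tibble(term = rownames(cf), estimate = unname(cf[, 1]),
         p_value = unname(cf[, 4])) |>
    filter(.data$term != "(Intercept)")
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR control at level `alpha` over one family of p-values.
#'
#' @param p_values Numeric vector (one family; NAs allowed and never
#'   significant).
#' @param alpha FDR level (default 0.05).
#' @return Logical vector of the same length.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(logical(0))
  out <- rep(FALSE, length(p_values))
  ok <- !is.na(p_values)
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH") <= alpha
  out
}

# normalize explanation records to the common importance schema
as_importance_table <- function(records, response = NULL) {
  if (is.null(response)) {
    response <- if ("percent_abs" %in% names(records)) "percent_abs"
                else if ("pcg" %in% names(records)) "abs_pcg"
                else abort("records carry neither `pcg` nor `percent_abs`")
  }
  importance <- switch(response,
    abs_pcg = abs(records$pcg),
    percent_abs = records$percent_abs,
    abort("`response` must be \"abs_pcg\" or \"percent_abs\""))
  tibble(importance = importance,
         modality = records$modality, true = records$true,
         predicted = records$predicted, fold = records$fold,
         subject_id = records$subject_id, medication = records$medication,
         sex = records$sex, age = records$age,
         epoch_index = records$epoch_index)
}

#' Covariate analysis of local explanations
#'
#' Regresses absolute importance on age, medication and sex per (modality,
#' true class, predicted class) cell, then applies Benjamini-Hochberg FDR at
#' `alpha` over each (variable, modality) family of classification-group
#' p-values. Accepts [local_ablation()] records (response `|PCG|`) or
#' [lrp_dataset()] records (response percent absolute relevance).
#'
#' @param records Explanation records, possibly pooled across folds. When a
#'   sample appears in several folds (re-randomized splits), only its first
#'   fold is kept.
#' @param response `"abs_pcg"`, `"percent_abs"`, or `NULL` to auto-detect.
#' @param alpha FDR level (default 0.05).
#' @return Tibble of class `covariate_effects` with `variable`, `modality`,
#'   `true`, `predicted`, `coefficient`, `p_value`, `fdr_significant`, `n`
#'   (rows used), `skipped` (reason, or NA).
#' @export
importance_covariate_analysis <- function(records, response = NULL,
                                          alpha = 0.05) {
  tab <- as_importance_table(records, response)
  tab <- tab |>
    filter(!is.na(.data$importance)) |>
    group_by(.data$modality, .data$subject_id, .data$medication,
             .data$epoch_index) |>
    filter(.data$fold == min(.data$fold)) |>
    ungroup()

  cells <- tidyr::expand_grid(modality = modality_names(),
                              true = stage_levels(),
                              predicted = stage_levels())
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- tab |>
      filter(.data$modality == cell$modality, .data$true == cell$true,
             .data$predicted == cell$predicted)
    base <- tibble(variable = c("age", "medication", "sex"),
                   modality = cell$modality, true = cell$true,
                   predicted = cell$predicted, coefficient = NA_real_,
                   p_value = NA_real_, n = nrow(sub), skipped = NA_character_)
    if (!nrow(sub)) {
      base$skipped <- "empty cell"
      return(base)
    }
    design <- build_design_matrix(sub)
    if (!is.null(design$skip)) {
      base$skipped <- paste(design$skip, collapse = "; ")
      return(base)
    }
    fit <- ols_fit(design$response, design$predictors)
    if (is.null(fit)) {
      base$skipped <- "rank-deficient or underdetermined design"
      return(base)
    }
    base$coefficient <- fit$estimate[match(base$variable, fit$term)]
    base$p_value <- fit$p_value[match(base$variable, fit$term)]
    base
  })
  out <- bind_rows(rows) |>
    group_by(.data$variable, .data$modality) |>
    mutate(fdr_significant = bh_fdr(.data$p_value, alpha)) |>
    ungroup() |>
    select("variable", "modality", "true", "predicted", "coefficient",
           "p_value", "fdr_significant", "n", "skipped")
  class(out) <- c("covariate_effects", class(out))
  out
}
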