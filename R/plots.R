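# ggplot2 views of the result tables.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_tile
#'   facet_grid facet_wrap labs scale_fill_manual scale_fill_gradient2
#'   geom_rect theme_minimal vars
NULL

#' @export
ggplot2::autoplot

modality_fill <- function() {
  scale_fill_manual(values = c(EEG = "#d73027", EOG = "#1a9850",
                               EMG = "#4575b4"))
}

#' Plot global ablation importance
#'
#' Percent change in group counts per modality, faceted by classification
#' group (true class as rows, predicted class as columns). By default only
#' correct classification groups are shown.
#'
#' @param object A [global_ablation()] tibble (several folds allowed; values
#'   are averaged across folds per cell).
#' @param correct_only Show only the diagonal groups (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.global_ablation <- function(object, correct_only = TRUE, ...) {
  df <- object |>
    filter(!is.na(.data$pcg)) |>
    group_by(.data$true, .data$predicted, .data$modality, .data$method) |>
    summarise(pcg = mean(.data$pcg), .groups = "drop")
  if (correct_only) df <- filter(df, .data$true == .data$predicted)
  ggplot(df, aes(x = .data$pcg, y = .data$modality, fill = .data$modality)) +
    geom_col() +
    facet_grid(rows = vars(.data$true), cols = vars(.data$predicted)) +
    modality_fill() +
    labs(x = "percent change in group count", y = NULL,
         title = sprintf("Global ablation (%s)", df$method[1])) +
    theme_minimal()
}

#' Plot modality-level relevance percentages
#'
#' @param object A [modality_percent_relevance()] tibble.
#' @param correct_only Show only correct classification groups.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modality_relevance <- function(object, correct_only = TRUE, ...) {
  df <- object
  if (correct_only) df <- filter(df, .data$true == .data$predicted)
  ggplot(df, aes(x = .data$percent, y = .data$modality, fill = .data$modality)) +
    geom_col() +
    facet_grid(rows = vars(.data$true), cols = vars(.data$predicted)) +
    modality_fill() +
    labs(x = "percent of absolute relevance", y = NULL) +
    theme_minimal()
}

#' Plot covariate effect heatmaps
#'
#' Regression coefficients per (true class, predicted class), faceted by
#' variable and modality; FDR-significant cells get a black outline.
#'
#' @param object An [importance_covariate_analysis()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.covariate_effects <- function(object, ...) {
  ggplot(object, aes(x = .data$predicted, y = .data$true,
                     fill = .data$coefficient)) +
    geom_tile() +
    geom_tile(data = filter(object, .data$fdr_significant),
              colour = "black", linewidth = 0.8, fill = NA) +
    facet_grid(rows = vars(.data$variable), cols = vars(.data$modality)) +
    scale_fill_gradient2(low = "#4575b4", mid = "white", high = "#d73027") +
    labs(x = "predicted class", y = "true class") +
    theme_minimal()
}

#' Plot a modality-relevance time course
#'
#' @param tc A [relevance_time_course()] tibble.
#' @return A ggplot object.
#' @export
plot_time_course <- function(tc) {
  ggplot(tc, aes(x = .data$epoch_index / 2, y = .data$percent,
                 colour = .data$modality)) +
    geom_line() +
    labs(x = "time (min)", y = "percent of absolute relevance",
         colour = NULL) +
    theme_minimal()
}
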