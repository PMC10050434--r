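# Layer-wise relevance propagation through the 1-D CNN.
#
# Relevance starts as 1.0 on the pre-softmax logit of the assigned class
# (softmax-level propagation is degenerate, so the logit is the start node)
# and flows backward: affine layers (dense and, via the im2col unfolding,
# convolutions) use the epsilon or alpha-beta rule; max pooling routes
# relevance winner-take-all to the maximal input (ties to the earliest
# index); dropout and flatten pass relevance through unchanged. Biases
# participate in the denominators but receive no further propagation, so
# with zero biases and epsilon -> 0 (or alpha-beta(1,0)) the total
# relevance reaching the input equals the start relevance exactly.

#' Relevance propagation rule
#'
#' @param kind `"epsilon"` or `"alphabeta"`.
#' @param epsilon Stabilizer >= 0 for the epsilon rule. The two working
#'   values are 0.01 (near-exhaustive propagation) and 100 (aggressive
#'   filtering of weak contributions).
#' @param alpha,beta Non-negative pool weights for the alpha-beta rule with
#'   `alpha - beta = 1`; the default (1, 0) propagates only positive
#'   relevance.
#' @return An object of class `relevance_rule`.
#' @export
relevance_rule <- function(kind = c("epsilon", "alphabeta"), epsilon = 0.01,
                           alpha = 1, beta = 0) {
  kind <- match.arg(kind)
  if (kind == "epsilon" && epsilon < 0) abort("`epsilon` must be >= 0")
  if (kind == "alphabeta") {
    if (alpha < 0 || beta < 0) abort("`alpha` and `beta` must be >= 0")
    if (abs(alpha - beta - 1) > 1e-12) abort("`alpha - beta` must equal 1")
  }
  structure(list(kind = kind, epsilon = epsilon, alpha = alpha, beta = beta),
            class = "relevance_rule")
}

#' @export
print.relevance_rule <- function(x, ...) {
  if (x$kind == "epsilon") {
    cat(sprintf("<relevance_rule> epsilon rule, epsilon = %g\n", x$epsilon))
  } else {
    cat(sprintf("<relevance_rule> alpha-beta rule, alpha = %g, beta = %g\n",
                x$alpha, x$beta))
  }
  invisible(x)
}

sign1 <- function(z) ifelse(z >= 0, 1, -1)     # sign with sign(0) = +1

# Relevance through a generic affine map a %*% W + b under a rule.
# `R_upper` is n x K, `a` is n x J, `W` is J x K. Returns n x J.
relevance_affine <- function(R_upper, a, W, b, rule) {
  if (rule$kind == "epsilon") {
    Z <- add_bias(a %*% W, b)
    denom <- Z + rule$epsilon * sign1(Z)
    S <- ifelse(denom == 0, 0, R_upper / denom)
    a * tcrossprod(S, W)
  } else {
    ap <- pmax(a, 0); an <- pmin(a, 0)
    Wp <- pmax(W, 0); Wn <- pmin(W, 0)
    P <- add_bias(ap %*% Wp + an %*% Wn, pmax(b, 0))
    N <- add_bias(ap %*% Wn + an %*% Wp, pmin(b, 0))
    Sp <- ifelse(P > 0, rule$alpha * R_upper / P, 0)
    Sn <- ifelse(N < 0, rule$beta * R_upper / N, 0)
    (ap * tcrossprod(Sp, Wp) + an * tcrossprod(Sp, Wn)) -
      (ap * tcrossprod(Sn, Wn) + an * tcrossprod(Sn, Wp))
  }
}

#' Propagate relevance through one affine layer
#'
#' Applies the epsilon or alpha-beta propagation rule to a dense affine map
#' `z_k = sum_j a_j w_jk + b_k`. The epsilon rule distributes
#' `a_j w_jk / (z_k + epsilon * sign(z_k))` shares of each `R_k`; the
#' alpha-beta rule normalizes positive and negative contribution pools
#' separately and combines them with weights `alpha` and `-beta`. The
#' stabilizer is applied as `epsilon * sign(z_k)` so that negative
#' denominators move away from zero rather than across it.
#'
#' @param R_upper Relevance of the deeper layer: numeric vector of length K
#'   or matrix `n x K`.
#' @param activations Input activations `a_j`: vector of length J or matrix
#'   `n x J`.
#' @param weights Weight matrix `J x K`.
#' @param bias Bias vector of length K (participates in the denominator;
#'   its relevance share is absorbed).
#' @param rule A [relevance_rule()].
#' @return Relevance of the shallower layer, same shape convention as the
#'   inputs.
#' @export
propagate_affine <- function(R_upper, activations, weights, bias = NULL,
                             rule = relevance_rule()) {
  vec_in <- is.null(dim(R_upper))
  if (vec_in) R_upper <- matrix(R_upper, 1L)
  if (is.null(dim(activations))) activations <- matrix(activations, 1L)
  if (is.null(bias)) bias <- numeric(ncol(weights))
  out <- relevance_affine(R_upper, activations, weights, bias, rule)
  if (vec_in) out[1, ] else out
}

#' Propagate relevance through max pooling
#'
#' Winner-take-all: each pooled output's relevance passes entirely to the
#' maximal input of its window; ties go to the earliest index.
#'
#' @param R_upper Relevance of the pooled outputs (length `L %/% size`, or
#'   length 1 for `size = "global"`).
#' @param activations The pre-pooling activations (numeric vector).
#' @param size Pool window size (default 2) or `"global"`.
#' @return Relevance vector over the inputs.
#' @export
propagate_maxpool <- function(R_upper, activations, size = 2L) {
  L <- length(activations)
  out <- numeric(L)
  if (identical(size, "global")) {
    out[which.max(activations)] <- sum(R_upper)
    return(out)
  }
  Lo <- L %/% size
  for (w in seq_len(Lo)) {
    win <- ((w - 1L) * size + 1L):(w * size)
    out[win[which.max(activations[win])]] <- R_upper[w]
  }
  out
}

#' Propagate relevance through a pass-through layer
#'
#' Dropout (inactive at inference), spatial dropout, ReLU and flatten leave
#' relevance values unchanged; flatten only reshapes.
#'
#' @param R_upper Relevance array.
#' @param kind One of `"dropout"`, `"spatial_dropout"`, `"relu"`,
#'   `"flatten"`.
#' @param dims Target dimensions when `kind = "flatten"`.
#' @return The relevance, reshaped if requested.
#' @export
propagate_passthrough <- function(R_upper, kind = "dropout", dims = NULL) {
  if (kind == "flatten" && !is.null(dims)) dim(R_upper) <- dims
  R_upper
}

#' Assigned class and start relevance for a sample
#'
#' The sample's class is the argmax of the predicted probabilities (ties to
#' the lowest class index) and a total relevance of 1 is placed on that
#' class's pre-softmax logit node.
#'
#' @param model A trained model.
#' @param sample `timepoints x 3` matrix or `1 x timepoints x 3` array.
#' @return List with `assigned_class` (character), `class_index`, and
#'   `start_relevance` (exactly 1).
#' @export
assign_output_relevance <- function(model, sample) {
  if (length(dim(sample)) == 2L) sample <- array(sample, c(1L, dim(sample)))
  p <- predict_proba(model, sample)[1, ]
  k <- as.integer(which.max(p))
  list(assigned_class = stage_levels()[k], class_index = k, start_relevance = 1)
}

# Batched LRP: X is n x L x C; returns list(relevance = n x L x C,
# assigned = integer vector).
lrp_core <- function(model, X, rule) {
  n <- dim(X)[1]
  fw <- forward_cnn(model, X, training = FALSE, keep = TRUE)
  assigned <- max.col(fw$out, ties.method = "first")
  R <- matrix(0, n, model$n_classes)
  R[cbind(seq_len(n), assigned)] <- 1

  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    input <- fw$acts[[i]]
    if (ly$kind == "dense") {
      R <- relevance_affine(R, input, ly$W, ly$b, rule)
    } else if (ly$kind == "conv1d") {
      d <- dim(input)
      Lo <- d[2] - ly$kernel + 1L
      M <- fw$extras[[i]] %||% im2col(input, ly$kernel)
      Rm <- relevance_affine(matrix(R, n * Lo, ly$filters), M, ly$W, ly$b, rule)
      R <- col2im_add(Rm, n, d[2], d[3], ly$kernel)
    } else if (ly$kind == "maxpool") {
      d <- dim(input); Lo <- dim(fw$acts[[i + 1L]])[2]
      sel <- fw$extras[[i]]
      Rx <- array(0, d)
      Rx[, seq(1L, 2L * Lo, by = 2L), ] <- R * sel
      Rx[, seq(2L, 2L * Lo, by = 2L), ] <- R * !sel
      R <- Rx
    } else if (ly$kind == "global_maxpool") {
      d <- dim(input)
      Rx <- array(0, d)
      Rx[cbind(rep(seq_len(n), d[3]), fw$extras[[i]],
               rep(seq_len(d[3]), each = n))] <- as.vector(R)
      R <- Rx
    } else if (ly$kind == "flatten") {
      dim(R) <- dim(input)
    }
    # dropout / spatial dropout: identity at inference
  }
  list(relevance = R, assigned = assigned)
}

#' Explain one sample with layer-wise relevance propagation
#'
#' @param model A trained [build_cnn()] model.
#' @param sample `timepoints x 3` matrix (or `1 x timepoints x 3` array).
#' @param rule A [relevance_rule()].
#' @return Object of class `relevance_map`: `relevance` (signed
#'   `timepoints x 3` matrix; all entries >= 0 under alpha-beta(1,0)),
#'   `assigned_class`, `rule`, `start_relevance` (1).
#' @export
lrp_explain <- function(model, sample, rule = relevance_rule()) {
  if (length(dim(sample)) == 2L) sample <- array(sample, c(1L, dim(sample)))
  res <- lrp_core(model, sample, rule)
  rel <- matrix(res$relevance[1, , ], dim(sample)[2], dim(sample)[3])
  colnames(rel) <- modality_names()[seq_len(ncol(rel))]
  structure(list(relevance = rel,
                 assigned_class = stage_levels()[res$assigned[1]],
                 rule = rule, start_relevance = 1),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("<relevance_map> %d x %d, assigned class %s, total relevance %.4f\n",
              nrow(x$relevance), ncol(x$relevance), x$assigned_class,
              sum(x$relevance)))
  invisible(x)
}

#' Per-sample LRP records over a dataset
#'
#' Runs LRP over every sample (in memory-bounded chunks) and reduces each
#' relevance map to per-modality absolute-relevance totals and percentages.
#'
#' @param model A trained model.
#' @param dataset An [epoched_dataset()].
#' @param rule A [relevance_rule()].
#' @param fold Fold identifier attached to the records.
#' @param chunk Samples per chunk.
#' @return Tibble of class `lrp_records` with one row per (sample,
#'   modality): `sample_id`, `fold`, `true`, `predicted` (assigned class),
#'   `modality`, `abs_relevance`, `percent_abs` (share of the sample's total
#'   absolute relevance, NA if that total is zero), plus covariate metadata.
#' @export
lrp_dataset <- function(model, dataset, rule = relevance_rule(), fold = 1L,
                        chunk = 50L) {
  n <- n_samples(dataset)
  if (!n) abort("empty dataset")
  abs_rel <- matrix(0, n, 3L)
  assigned <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    res <- lrp_core(model, dataset$samples[idx, , , drop = FALSE], rule)
    assigned[idx] <- res$assigned
    for (m in seq_len(dim(res$relevance)[3])) {
      abs_rel[idx, m] <- rowSums(abs(res$relevance[, , m, drop = FALSE]))
    }
  }
  total <- rowSums(abs_rel)
  out <- bind_rows(lapply(1:3, function(m) {
    tibble(sample_id = seq_len(n), fold = fold,
           true = as.character(dataset$meta$label),
           predicted = stage_levels()[assigned],
           modality = modality_names()[m],
           abs_relevance = abs_rel[, m],
           percent_abs = ifelse(total > 0, 100 * abs_rel[, m] / total, NA_real_),
           subject_id = dataset$meta$subject_id,
           medication = dataset$meta$medication,
           sex = dataset$meta$sex, age = dataset$meta$age,
           epoch_index = dataset$meta$epoch_index)
  }))
  class(out) <- c("lrp_records", class(out))
  out
}

#' Modality-level percent relevance per classification group
#'
#' Within each fold and classification group, pools the absolute relevance
#' of the group's samples and reports each modality's percentage of the
#' pooled total (`per_sample = TRUE` instead averages per-sample
#' percentages); across folds, the median.
#'
#' @param records An [lrp_dataset()] tibble (several folds may be bound
#'   together).
#' @param per_sample Average per-sample percentages instead of pooling
#'   before normalizing.
#' @return Tibble of class `modality_relevance` with `true`, `predicted`,
#'   `modality`, `percent` (medians across folds; the three modalities of a
#'   group sum to 100 under pooling), `n_folds`.
#' @export
modality_percent_relevance <- function(records, per_sample = FALSE) {
  if (!nrow(records)) abort("no relevance records")
  per_fold <- if (per_sample) {
    records |>
      filter(!is.na(.data$percent_abs)) |>
      group_by(.data$fold, .data$true, .data$predicted, .data$modality) |>
      summarise(percent = mean(.data$percent_abs), .groups = "drop")
  } else {
    records |>
      group_by(.data$fold, .data$true, .data$predicted, .data$modality) |>
      summarise(abs_rel = sum(.data$abs_relevance), .groups = "drop") |>
      group_by(.data$fold, .data$true, .data$predicted) |>
      mutate(total = sum(.data$abs_rel),
             percent = ifelse(.data$total > 0,
                              100 * .data$abs_rel / .data$total, NA_real_)) |>
      ungroup()
  }
  out <- per_fold |>
    filter(!is.na(.data$percent)) |>
    group_by(.data$true, .data$predicted, .data$modality) |>
    summarise(percent = stats::median(.data$percent), n_folds = n(),
              .groups = "drop")
  class(out) <- c("modality_relevance", class(out))
  out
}

#' Time course of modality relevance within a recording
#'
#' Per 30-s epoch, each modality's percentage of the epoch's total absolute
#' relevance, in chronological order, with optional moving-average
#' smoothing.
#'
#' @param records [lrp_dataset()] rows from a single recording, in
#'   chronological order (strictly increasing `epoch_index`).
#' @param window Smoothing window in epochs (default 1, no smoothing).
#' @return Tibble with `epoch_index`, `modality`, `percent`.
#' @export
relevance_time_course <- function(records, window = 1L) {
  ord <- records |>
    dplyr::distinct(.data$sample_id, .data$epoch_index) |>
    arrange(.data$sample_id)
  if (is.unsorted(ord$epoch_index, strictly = TRUE)) {
    abort("records must come from one recording in chronological order")
  }
  out <- records |>
    select("epoch_index", "modality", "percent_abs") |>
    dplyr::rename(percent = "percent_abs") |>
    arrange(.data$modality, .data$epoch_index)
  if (window > 1L) {
    out <- out |>
      group_by(.data$modality) |>
      mutate(percent = stats::filter(.data$percent, rep(1 / window, window),
                                     sides = 2L)) |>
      ungroup() |>
      mutate(percent = as.numeric(.data$percent))
  }
  out
}
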