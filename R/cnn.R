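# A compact 1-D CNN for 30-s multimodal samples, implemented directly on
# BLAS matrix products. Convolutions are valid (no zero padding) and run
# through an im2col expansion: the input (n x L x C) unfolds to a
# (n*L_out x K*C) matrix whose product with the (K*C x F) weight matrix
# gives all output positions of all samples at once. The same expansion
# drives backpropagation and relevance propagation.

conv_layer <- function(filters, kernel) {
  list(kind = "conv1d", filters = as.integer(filters),
       kernel = as.integer(kernel), activation = "relu", W = NULL, b = NULL)
}
dense_layer <- function(units, activation) {
  list(kind = "dense", units = as.integer(units), activation = activation,
       W = NULL, b = NULL)
}

#' Build the sleep-staging CNN
#'
#' Eight valid (no-padding) 1-D convolution layers in four width blocks with
#' intermediate max pooling and spatial dropout, global max pooling, and
#' three dense layers ending in a 5-way softmax:
#' `conv(w1,5) x2 -> pool(2) -> conv(w2,3) x2 -> pool(2) -> conv(w3,3) x2 ->
#' pool(2) -> conv(w4,3) x2 -> global-max-pool -> dense(d1) -> dense(d2) ->
#' dense(n_classes, softmax)`, with ReLU activations on all hidden layers
#' and dropout rates 0.01/0.01/0.01/0.01/0.1/0.05. Defaults follow the full
#' architecture (widths 16/32/32/256, dense 64/64); narrower widths give a
#' proportionally cheaper model with the same topology.
#'
#' @param input_len Timepoints per sample (default 3000).
#' @param n_channels Input channels (default 3).
#' @param n_classes Output classes (default 5).
#' @param widths Filter counts of the four convolution blocks.
#' @param dense_units Sizes of the two hidden dense layers.
#' @param seed Integer seed for Glorot-uniform weight initialization.
#' @return An object of class `modex_cnn`.
#' @export
build_cnn <- function(input_len = 3000L, n_channels = 3L, n_classes = 5L,
                      widths = c(16L, 32L, 32L, 256L),
                      dense_units = c(64L, 64L), seed = 1L) {
  stopifnot(length(widths) == 4L, length(dense_units) == 2L)
  layers <- list(
    conv_layer(widths[1], 5L), conv_layer(widths[1], 5L),
    list(kind = "maxpool", size = 2L), list(kind = "spatial_dropout", rate = 0.01),
    conv_layer(widths[2], 3L), conv_layer(widths[2], 3L),
    list(kind = "maxpool", size = 2L), list(kind = "spatial_dropout", rate = 0.01),
    conv_layer(widths[3], 3L), conv_layer(widths[3], 3L),
    list(kind = "maxpool", size = 2L), list(kind = "spatial_dropout", rate = 0.01),
    conv_layer(widths[4], 3L), conv_layer(widths[4], 3L),
    list(kind = "global_maxpool"), list(kind = "dropout", rate = 0.01),
    list(kind = "flatten"),
    dense_layer(dense_units[1], "relu"), list(kind = "dropout", rate = 0.1),
    dense_layer(dense_units[2], "relu"), list(kind = "dropout", rate = 0.05),
    dense_layer(n_classes, "softmax"))

  # shape inference + receptive-field check
  L <- as.integer(input_len); C <- as.integer(n_channels)
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "conv1d") {
      if (L < ly$kernel) {
        abort(sprintf("input too short at layer %d: length %d < kernel %d",
                      i, L, ly$kernel))
      }
      layers[[i]]$in_channels <- C
      L <- L - ly$kernel + 1L
      C <- ly$filters
    } else if (ly$kind == "maxpool") {
      L <- L %/% ly$size
    } else if (ly$kind == "global_maxpool") {
      L <- 1L
    } else if (ly$kind == "flatten") {
      layers[[i]]$in_dim <- L * C
      C <- L * C; L <- 1L
    } else if (ly$kind == "dense") {
      layers[[i]]$in_dim <- C
      C <- ly$units
    }
  }

  model <- structure(list(layers = layers, input_len = as.integer(input_len),
                          n_channels = as.integer(n_channels),
                          n_classes = as.integer(n_classes)),
                     class = "modex_cnn")
  init_weights(model, seed)
}

init_weights <- function(model, seed) {
  with_local_seed(seed, {
    for (i in seq_along(model$layers)) {
      ly <- model$layers[[i]]
      if (ly$kind == "conv1d") {
        fan_in <- ly$kernel * ly$in_channels
        fan_out <- ly$kernel * ly$filters
        lim <- sqrt(6 / (fan_in + fan_out))
        model$layers[[i]]$W <- matrix(stats::runif(fan_in * ly$filters, -lim, lim),
                                      fan_in, ly$filters)
        model$layers[[i]]$b <- numeric(ly$filters)
      } else if (ly$kind == "dense") {
        lim <- sqrt(6 / (ly$in_dim + ly$units))
        model$layers[[i]]$W <- matrix(stats::runif(ly$in_dim * ly$units, -lim, lim),
                                      ly$in_dim, ly$units)
        model$layers[[i]]$b <- numeric(ly$units)
      }
    }
    model
  })
}

#' @export
print.modex_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("<modex_cnn> input %d x %d -> %d classes, %d layers, %s parameters\n",
              x$input_len, x$n_channels, x$n_classes, length(x$layers),
              format(n_par, big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained: best validation accuracy %.3f at epoch %d\n",
                max(x$history$val_accuracy), x$best_epoch))
  }
  invisible(x)
}

im2col <- function(X, K) {
  d <- dim(X)
  im2col_cpp(X, d[1], d[2], d[3], as.integer(K))
}

col2im_add <- function(dM, n, L, C, K) {
  col2im_add_cpp(dM, as.integer(n), as.integer(L), as.integer(C),
                 as.integer(K))
}

add_bias <- function(Z, b) {
  for (f in seq_along(b)) Z[, f] <- Z[, f] + b[f]
  Z
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Full forward pass. Returns final output plus, when keep = TRUE, the input
# of every layer and the bookkeeping (pool winners, dropout masks, logits)
# needed by backprop and relevance propagation.
forward_cnn <- function(model, X, training = FALSE, keep = FALSE) {
  n <- dim(X)[1]
  acts <- if (keep) vector("list", length(model$layers) + 1L)
  extras <- if (keep) vector("list", length(model$layers))
  cur <- X
  if (keep) acts[[1]] <- cur
  logits <- NULL
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$kind == "conv1d") {
      d <- dim(cur); Lo <- d[2] - ly$kernel + 1L
      M <- im2col(cur, ly$kernel)
      Z <- M %*% ly$W
      addbias_relu_inplace(Z, ly$b, ly$activation == "relu")
      if (keep) extras[[i]] <- M          # reused by backprop
      cur <- array(Z, c(n, Lo, ly$filters))
    } else if (ly$kind == "maxpool") {
      d <- dim(cur); Lo <- d[2] %/% ly$size
      A <- cur[, seq(1L, 2L * Lo, by = 2L), , drop = FALSE]
      B <- cur[, seq(2L, 2L * Lo, by = 2L), , drop = FALSE]
      sel <- A >= B                              # ties -> earliest index
      cur <- pmax(A, B)
      if (keep) extras[[i]] <- sel
    } else if (ly$kind == "global_maxpool") {
      d <- dim(cur)
      M2 <- matrix(aperm(cur, c(1L, 3L, 2L)), d[1] * d[3], d[2])
      idx <- max.col(M2, ties.method = "first")
      cur <- matrix(M2[cbind(seq_len(nrow(M2)), idx)], d[1], d[3])
      if (keep) extras[[i]] <- idx
    } else if (ly$kind %in% c("dropout", "spatial_dropout")) {
      if (training && ly$rate > 0) {
        if (ly$kind == "dropout") {
          mask <- matrix(stats::runif(length(cur)) >= ly$rate,
                         nrow(cur), ncol(cur)) / (1 - ly$rate)
        } else {
          d <- dim(cur)
          chan <- matrix(stats::runif(d[1] * d[3]) >= ly$rate, d[1], d[3]) /
            (1 - ly$rate)
          mask <- aperm(array(chan, c(d[1], d[3], d[2])), c(1L, 3L, 2L))
        }
        cur <- cur * mask
        if (keep) extras[[i]] <- mask
      }
    } else if (ly$kind == "flatten") {
      cur <- matrix(cur, n, ly$in_dim)
    } else if (ly$kind == "dense") {
      Z <- add_bias(cur %*% ly$W, ly$b)
      if (ly$activation == "relu") {
        Z[Z < 0] <- 0
      } else if (ly$activation == "softmax") {
        logits <- Z
        Z <- softmax_rows(Z)
      }
      cur <- Z
    }
    if (keep) acts[[i + 1L]] <- cur
  }
  list(out = cur, acts = acts, extras = extras, logits = logits)
}

#' Predict class probabilities
#'
#' Runs samples through the network at inference (dropout inactive) in
#' memory-bounded chunks.
#'
#' @param model A trained (or freshly built) [build_cnn()] model.
#' @param samples Numeric array `n x input_len x n_channels`, or an
#'   [epoched_dataset()].
#' @param chunk Samples per forward chunk.
#' @return Numeric matrix `n x n_classes` of probabilities (rows sum to 1),
#'   columns named by [stage_levels()].
#' @export
predict_proba <- function(model, samples, chunk = 256L) {
  if (inherits(samples, "epoched_dataset")) samples <- samples$samples
  if (length(dim(samples)) == 2L) {
    samples <- array(samples, c(1L, dim(samples)))
  }
  d <- dim(samples)
  if (length(d) != 3L || d[2] != model$input_len || d[3] != model$n_channels) {
    abort(sprintf("samples must be n x %d x %d", model$input_len, model$n_channels))
  }
  out <- matrix(0, d[1], model$n_classes)
  for (start in seq(1L, d[1], by = chunk)) {
    idx <- start:min(start + chunk - 1L, d[1])
    out[idx, ] <- forward_cnn(model, samples[idx, , , drop = FALSE])$out
  }
  colnames(out) <- stage_levels()[seq_len(model$n_classes)]
  out
}

#' Predicted class labels
#'
#' @inheritParams predict_proba
#' @return Factor of predicted labels (argmax of [predict_proba()]; ties go
#'   to the lowest class index).
#' @export
predict_classes <- function(model, samples, chunk = 256L) {
  p <- predict_proba(model, samples, chunk)
  factor(stage_levels()[max.col(p, ties.method = "first")],
         levels = stage_levels())
}
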