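# Independent oracles and hand-built toy models used to cross-check the
# production implementation. Everything here is written deliberately in the
# most literal style possible (explicit loops, path enumeration) so that it
# shares no code path with the package internals it checks.

# A fully hand-specified dense network wrapped as a model object: flatten
# followed by dense layers with ReLU on hidden layers and softmax on the
# output layer.
toy_dense_model <- function(Ws, bs, n_channels = 1L) {
  in_dim <- nrow(Ws[[1]])
  stopifnot(in_dim %% n_channels == 0)
  L <- length(Ws)
  layers <- list(list(kind = "flatten", in_dim = in_dim))
  for (l in seq_len(L)) {
    layers[[l + 1L]] <- list(kind = "dense", units = ncol(Ws[[l]]),
                             activation = if (l < L) "relu" else "softmax",
                             W = Ws[[l]], b = bs[[l]], in_dim = nrow(Ws[[l]]))
  }
  structure(list(layers = layers,
                 input_len = as.integer(in_dim / n_channels),
                 n_channels = as.integer(n_channels),
                 n_classes = ncol(Ws[[L]])),
            class = "modex_cnn")
}

# A hand-specified conv(+ReLU) -> flatten -> dense(softmax) model. `Wc` is
# the (K * C) x F convolution weight matrix with row (c - 1) * K + tap.
toy_conv_model <- function(Wc, bc, Wd, bd, input_len, n_channels = 1L) {
  K <- nrow(Wc) / n_channels
  stopifnot(K == round(K))
  Lo <- input_len - K + 1L
  layers <- list(
    list(kind = "conv1d", filters = ncol(Wc), kernel = as.integer(K),
         activation = "relu", in_channels = as.integer(n_channels),
         W = Wc, b = bc),
    list(kind = "flatten", in_dim = Lo * ncol(Wc)),
    list(kind = "dense", units = ncol(Wd), activation = "softmax",
         W = Wd, b = bd, in_dim = nrow(Wd)))
  structure(list(layers = layers, input_len = as.integer(input_len),
                 n_channels = as.integer(n_channels), n_classes = ncol(Wd)),
            class = "modex_cnn")
}

# Toeplitz-unrolled affine equivalent of a valid 1-D convolution, in the
# package's flatten ordering (output position-major, filter blocks). The
# relevance a convolution assigns must equal the relevance of this plain
# affine layer.
conv_as_dense <- function(Wc, bc, input_len, n_channels = 1L) {
  K <- nrow(Wc) / n_channels
  F_ <- ncol(Wc)
  Lo <- input_len - K + 1L
  W <- matrix(0, input_len * n_channels, Lo * F_)
  for (f in seq_len(F_)) {
    for (l in seq_len(Lo)) {
      out_idx <- l + (f - 1L) * Lo
      for (c in seq_len(n_channels)) {
        for (tap in seq_len(K)) {
          in_idx <- (l + tap - 1L) + (c - 1L) * input_len
          W[in_idx, out_idx] <- Wc[(c - 1L) * K + tap, f]
        }
      }
    }
  }
  list(W = W, b = rep(bc, each = Lo))
}

# Path-enumeration relevance oracle for a dense ReLU network (softmax
# output, relevance started as 1.0 on the argmax logit). Computes every
# input unit's relevance as an explicit sum over all paths through the
# network of the product of per-edge relevance factors.
lrp_path_oracle <- function(x, Ws, bs, rule) {
  L <- length(Ws)
  a <- list(as.numeric(x))
  z <- vector("list", L)
  for (l in seq_len(L)) {
    z[[l]] <- as.numeric(a[[l]] %*% Ws[[l]]) + bs[[l]]
    a[[l + 1L]] <- if (l < L) pmax(z[[l]], 0) else z[[l]]
  }
  cls <- which.max(z[[L]])          # softmax is monotone in the logits

  edge <- vector("list", L)
  for (l in seq_len(L)) {
    W <- Ws[[l]]; b <- bs[[l]]
    E <- matrix(0, nrow(W), ncol(W))
    for (k in seq_len(ncol(W))) {
      contrib <- a[[l]] * W[, k]
      if (rule$kind == "epsilon") {
        zk <- z[[l]][k]
        den <- zk + rule$epsilon * (if (zk >= 0) 1 else -1)
        if (den != 0) E[, k] <- contrib / den
      } else {
        P <- sum(pmax(contrib, 0)) + max(b[k], 0)
        N <- sum(pmin(contrib, 0)) + min(b[k], 0)
        pos <- if (P > 0) rule$alpha * pmax(contrib, 0) / P else 0
        neg <- if (N < 0) rule$beta * pmin(contrib, 0) / N else 0
        E[, k] <- pos - neg
      }
    }
    edge[[l]] <- E
  }

  R <- numeric(length(a[[1]]))
  hidden <- lapply(Ws[-L], ncol)
  grid <- if (length(hidden)) expand.grid(lapply(hidden, seq_len)) else NULL
  for (j in seq_along(R)) {
    if (is.null(grid)) {
      R[j] <- edge[[1]][j, cls]
      next
    }
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      path <- as.integer(grid[g, ])
      p <- edge[[1]][j, path[1]]
      if (length(path) > 1L) {
        for (l in 2:length(path)) p <- p * edge[[l]][path[l - 1L], path[l]]
      }
      tot <- tot + p * edge[[L]][path[length(path)], cls]
    }
    R[j] <- tot
  }
  list(relevance = R, class_index = cls)
}

# Deterministic small weights for toy nets (no RNG state touched).
toy_weights <- function(nr, nc, scale = 1) {
  matrix(sin(seq_len(nr * nc) * 0.7) * scale, nr, nc)
}

# A quickly trained tiny CNN on a tiny planted synthetic task, cached per
# test run. Used by conservation and plumbing tests that need a "real"
# trained model without the full recovery-scale cost.
cached_tiny_fit <- local({
  val <- NULL
  function() {
    if (!is.null(val)) return(val)
    cohort <- make_cohort(4, seed = 7)
    cfg <- synth_config(epochs_per_recording = 15,
                        profiles = planted_modality_profiles("EEG"))
    ds <- synth_dataset(cohort, cfg, seed = 77)
    plan <- make_folds(unique(ds$meta$subject_id), n_folds = 1, seed = 3)
    model <- build_cnn(widths = c(2, 2, 2, 4), dense_units = c(8, 8), seed = 5)
    fit <- train_fold(model, ds, plan, 1, max_epochs = 2, seed = 9)
    val <<- list(fit = fit, ds = ds, plan = plan)
    val
  }
})

zero_biases <- function(model) {
  for (i in seq_along(model$layers)) {
    if (!is.null(model$layers[[i]]$b)) {
      model$layers[[i]]$b <- model$layers[[i]]$b * 0
    }
  }
  model
}
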