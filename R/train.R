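# Training: class-weighted categorical cross-entropy, Adam, learning-rate
# reduction on validation-accuracy plateau, early stopping, and best-epoch
# checkpointing.

# Backward pass through a kept forward state. `dZ_out` is the gradient at
# the softmax logits (n x n_classes). Returns per-layer dW/db lists.
backward_cnn <- function(model, fw, dZ_out) {
  nl <- length(model$layers)
  grads <- vector("list", nl)
  dY <- NULL
  for (i in rev(seq_len(nl))) {
    ly <- model$layers[[i]]
    input <- fw$acts[[i]]
    output <- fw$acts[[i + 1L]]
    if (ly$kind == "dense") {
      dZ <- if (ly$activation == "softmax") dZ_out
            else if (ly$activation == "relu") dY * (output > 0)
            else dY
      grads[[i]] <- list(W = crossprod(input, dZ), b = colSums(dZ))
      dY <- tcrossprod(dZ, ly$W)
    } else if (ly$kind == "conv1d") {
      d <- dim(input); n <- d[1]
      dZ <- matrix(dY * (output > 0), n * dim(output)[2], ly$filters)
      M <- fw$extras[[i]] %||% im2col(input, ly$kernel)
      grads[[i]] <- list(W = crossprod(M, dZ), b = colSums(dZ))
      dY <- col2im_add(tcrossprod(dZ, ly$W), n, d[2], d[3], ly$kernel)
    } else if (ly$kind == "maxpool") {
      d <- dim(input); Lo <- dim(output)[2]
      dX <- array(0, d)
      sel <- fw$extras[[i]]
      dX[, seq(1L, 2L * Lo, by = 2L), ] <- dY * sel
      dX[, seq(2L, 2L * Lo, by = 2L), ] <- dY * !sel
      dY <- dX
    } else if (ly$kind == "global_maxpool") {
      d <- dim(input); n <- d[1]; C <- d[3]
      dX <- array(0, d)
      r <- seq_len(n * C)
      dX[cbind(rep(seq_len(n), C), fw$extras[[i]],
               rep(seq_len(C), each = n))] <- as.vector(dY)
      dY <- dX
    } else if (ly$kind %in% c("dropout", "spatial_dropout")) {
      if (!is.null(fw$extras[[i]])) dY <- dY * fw$extras[[i]]
    } else if (ly$kind == "flatten") {
      dY <- array(dY, dim(input))
    }
  }
  grads
}

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

adam_step <- function(model, state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b -
      lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

#' Inverse-frequency class weights
#'
#' `w_c = n_total / (n_classes * n_c)` over the classes present; equal class
#' frequencies give equal weights.
#'
#' @param class_idx Integer class indices (1-based).
#' @param n_classes Number of classes.
#' @return Numeric weight per class.
#' @export
class_weights <- function(class_idx, n_classes) {
  counts <- tabulate(class_idx, nbins = n_classes)
  if (any(counts == 0)) {
    abort(sprintf("training data has empty class(es): %s",
                  paste(which(counts == 0), collapse = ", ")))
  }
  length(class_idx) / (n_classes * counts)
}

labels_to_index <- function(labels, n_classes) {
  idx <- as.integer(factor(as.character(labels),
                           levels = stage_levels()[seq_len(n_classes)]))
  if (anyNA(idx)) abort("labels outside the model's class set")
  idx
}

#' Train a CNN on one train/validation split
#'
#' Optimizes class-weighted categorical cross-entropy with Adam (batch size
#' 100, shuffled each epoch, initial learning rate 0.001). The learning rate
#' drops by a factor of 10 when validation accuracy fails to improve for
#' `lr_patience` epochs, training stops early after `stop_patience` stagnant
#' epochs (hard cap `max_epochs`), and the returned model carries the
#' weights of the epoch with the best validation accuracy.
#'
#' @param model A [build_cnn()] model.
#' @param train,validation [epoched_dataset()] objects.
#' @param batch_size Minibatch size (default 100).
#' @param lr Initial learning rate.
#' @param lr_patience Epochs without validation improvement before dividing
#'   the learning rate by 10.
#' @param stop_patience Epochs without improvement before early stopping.
#' @param max_epochs Hard epoch cap.
#' @param seed Integer seed for shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return The model with best-epoch weights, plus `history` (per-epoch
#'   tibble), `best_epoch`, and `best_val_accuracy`.
#' @export
train_cnn <- function(model, train, validation, batch_size = 100L, lr = 1e-3,
                      lr_patience = 5L, stop_patience = 20L, max_epochs = 100L,
                      seed = 1L, verbose = FALSE) {
  y_train <- labels_to_index(train$meta$label, model$n_classes)
  y_val <- labels_to_index(validation$meta$label, model$n_classes)
  w_class <- class_weights(y_train, model$n_classes)
  n <- length(y_train)
  onehot <- diag(model$n_classes)

  state <- adam_init(model)
  best <- list(val = -Inf, epoch = 0L, weights = NULL)
  history <- list()
  t_adam <- 0L
  lr_wait <- 0L; stop_wait <- 0L

  with_local_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        nb <- length(idx)
        Xb <- train$samples[idx, , , drop = FALSE]
        yb <- y_train[idx]
        fw <- forward_cnn(model, Xb, training = TRUE, keep = TRUE)
        P <- fw$out
        wb <- w_class[yb]
        p_true <- pmax(P[cbind(seq_len(nb), yb)], 1e-12)
        epoch_loss <- epoch_loss + sum(wb * -log(p_true))
        dZ <- (P - onehot[yb, , drop = FALSE]) * (wb / nb)
        grads <- backward_cnn(model, fw, dZ)
        t_adam <- t_adam + 1L
        upd <- adam_step(model, state, grads, lr, t_adam)
        model <- upd$model; state <- upd$state
      }
      val_pred <- max.col(predict_proba(model, validation$samples),
                          ties.method = "first")
      val_acc <- mean(val_pred == y_val)
      history[[epoch]] <- tibble(epoch = epoch, loss = epoch_loss / n,
                                 val_accuracy = val_acc, lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_acc %.3f  lr %g",
                        epoch, epoch_loss / n, val_acc, lr))
      }
      if (val_acc > best$val + 1e-12) {
        best <- list(val = val_acc, epoch = epoch,
                     weights = lapply(model$layers, function(l) l[c("W", "b")]))
        lr_wait <- 0L; stop_wait <- 0L
      } else {
        lr_wait <- lr_wait + 1L; stop_wait <- stop_wait + 1L
        if (lr_wait >= lr_patience) {
          lr <- lr / 10
          lr_wait <- 0L
        }
        if (stop_wait >= stop_patience) break
      }
    }
  })

  if (!is.null(best$weights)) {
    for (i in seq_along(model$layers)) {
      if (!is.null(best$weights[[i]]$W)) {
        model$layers[[i]]$W <- best$weights[[i]]$W
        model$layers[[i]]$b <- best$weights[[i]]$b
      }
    }
  }
  model$history <- bind_rows(history)
  model$best_epoch <- best$epoch
  model$best_val_accuracy <- best$val
  model
}

#' Train on one fold of a cross-validation plan
#'
#' @param model A [build_cnn()] model.
#' @param dataset An [epoched_dataset()].
#' @param plan A [make_folds()] plan.
#' @param fold Fold number.
#' @param ... Passed to [train_cnn()].
#' @return The fitted model, tagged with `$fold`.
#' @export
train_fold <- function(model, dataset, plan, fold, ...) {
  tr <- subset_samples(dataset, dataset$meta$subject_id %in%
                         fold_subjects(plan, fold, "train"))
  va <- subset_samples(dataset, dataset$meta$subject_id %in%
                         fold_subjects(plan, fold, "validation"))
  fit <- train_cnn(model, tr, va, ...)
  fit$fold <- fold
  fit
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted CNN
#'
#' @param x A trained [build_cnn()] model.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `val_accuracy`, `lr`.
#' @export
tidy.modex_cnn <- function(x, ...) {
  if (is.null(x$history)) abort("model has not been trained")
  x$history
}

#' One-row training summary of a fitted CNN
#'
#' @param x A trained [build_cnn()] model.
#' @param ... Unused.
#' @return Tibble with `epochs_run`, `best_epoch`, `best_val_accuracy`,
#'   `final_lr`, `n_parameters`.
#' @export
glance.modex_cnn <- function(x, ...) {
  if (is.null(x$history)) abort("model has not been trained")
  tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
         best_val_accuracy = x$best_val_accuracy,
         final_lr = x$history$lr[nrow(x$history)],
         n_parameters = sum(vapply(x$layers,
                                   function(l) length(l$W) + length(l$b),
                                   numeric(1))))
}
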