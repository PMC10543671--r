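#' Training configuration
#'
#' Adam optimization of the cross-entropy loss on raw class scores, with a
#' per-epoch exponentially decaying learning rate
#' `lr(t) = lr_init * lr_decay^t`.
#'
#' The `"desk"` preset (15 epochs, batch 32, lr 1e-3, decay 0.95) is sized
#' for the bundled synthetic study; the `"paper"` preset uses the
#' full-scale recipe (50 epochs, batch 128, lr 1e-5).
#'
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param lr_init initial learning rate.
#' @param lr_decay multiplicative per-epoch decay factor (0 < d <= 1).
#' @param seed integer seed controlling shuffling (initialization is owned
#'   by [build_model()]).
#' @param preset `"desk"`, `"paper"`, or `NULL` to use the explicit
#'   arguments.
#' @return an `sfx_trainconfig`.
#' @export
train_config <- function(epochs = 15, batch_size = 32, lr_init = 1e-3,
                         lr_decay = 0.95, seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "paper"))
    if (preset == "paper") {
      epochs <- 50; batch_size <- 128; lr_init <- 1e-5; lr_decay <- 0.95
    }
  }
  stopifnot(epochs >= 0, batch_size >= 1, lr_init >= 0,
            lr_decay > 0, lr_decay <= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "sfx_trainconfig")
}

cross_entropy <- function(scores, label_index) {
  m <- max(scores)
  (m + log(sum(exp(scores - m)))) - scores[label_index]
}

#' Train a classifier on a labelled dataset
#'
#' Fits the model on the dataset's train split by minibatch Adam on the
#' softmax cross-entropy of the raw scores. With `target = "binary"` the
#' hit/miss labels from [binarize_labels()] are used (the model must then
#' have 2 output classes).
#'
#' @param model an untrained `sfx_model`.
#' @param dataset an `sfx_dataset` with a train split.
#' @param cfg an `sfx_trainconfig`.
#' @param target `"multiclass"` (five classes) or `"binary"` (hit/miss).
#' @param verbose print per-epoch progress.
#' @return list with `model` (fitted) and `history` (data.frame of per-epoch
#'   train loss, train accuracy and test accuracy).
#' @export
train <- function(model, dataset, cfg = train_config(),
                  target = c("multiclass", "binary"), verbose = FALSE) {
  target <- match.arg(target)
  stopifnot(inherits(model, "sfx_model"), inherits(dataset, "sfx_dataset"))
  labels <- if (target == "binary") {
    if (is.null(dataset$binary)) dataset <- binarize_labels(dataset)
    as.integer(dataset$binary)
  } else as.integer(dataset$labels)
  if (max(labels) > model$spec$n_classes)
    stop("label exceeds the model's class count")

  inputs <- lapply(dataset$frames, function(f) preprocess_frame(model, f))
  tr <- which(dataset$split == "train")
  te <- which(dataset$split == "test")
  if (length(tr) == 0) stop("dataset has no train split")

  params <- get_params(model)
  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), train_acc = numeric(0),
                        test_acc = numeric(0))
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr_init * cfg$lr_decay^(epoch - 1)
    ord <- sample(tr)
    ep_loss <- 0; ep_correct <- 0L
    for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
      batch <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
      gacc <- NULL
      for (i in batch) {
        fp <- forward_pass(model, inputs[[i]])
        p <- softmax(fp$scores)
        loss <- cross_entropy(fp$scores, labels[i])
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch,
               ", frame ", i, " (scores: ",
               paste(signif(fp$scores, 3), collapse = ", "), ")")
        ep_loss <- ep_loss + loss
        if (which.max(fp$scores) == labels[i]) ep_correct <- ep_correct + 1L
        dscores <- p
        dscores[labels[i]] <- dscores[labels[i]] - 1
        bp <- backward_pass(model, fp, dscores, want_params = TRUE)
        g <- flatten_pgrads(model, bp$pgrads)
        gacc <- if (is.null(gacc)) g else Map(`+`, gacc, g)
      }
      nb <- length(batch)
      step <- step + 1L
      for (k in names(params)) {
        gk <- gacc[[k]] / nb
        m_state[[k]] <- beta1 * m_state[[k]] + (1 - beta1) * gk
        v_state[[k]] <- beta2 * v_state[[k]] + (1 - beta2) * gk^2
        mhat <- m_state[[k]] / (1 - beta1^step)
        vhat <- v_state[[k]] / (1 - beta2^step)
        params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
      }
      model <- set_params(model, params)
    }
    test_acc <- if (length(te) > 0) {
      pred <- vapply(te, function(i)
        which.max(forward_pass(model, inputs[[i]])$scores), 1L)
      mean(pred == labels[te])
    } else NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / length(ord),
      train_acc = ep_correct / length(ord), test_acc = test_acc))
    if (verbose)
      message(sprintf("epoch %2d  lr %.2e  loss %.4f  train %.3f  test %.3f",
                      epoch, lr, ep_loss / length(ord),
                      ep_correct / length(ord), test_acc))
  }
  list(model = model, history = history)
}

#' Predict labels and scores for frames
#'
#' Label = argmax of the raw scores; ties break toward the lowest class
#' index.
#'
#' @param model a trained `sfx_model`.
#' @param frames list of `sfx_frame` objects (or an `sfx_dataset`).
#' @return list with `labels` (integer class indices) and `scores`
#'   (n x n_classes matrix of raw scores).
#' @export
predict_frames <- function(model, frames) {
  if (inherits(frames, "sfx_dataset")) frames <- frames$frames
  scores <- t(vapply(frames, function(f) forward(model, f),
                     numeric(model$spec$n_classes)))
  list(labels = apply(scores, 1, which.max), scores = scores)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the fitted weights in R's native serialization and
#' writes the architecture specification alongside as a YAML dump
#' (`<path>.yaml`).
#'
#' @param model an `sfx_model`.
#' @param path checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  atomic_write(function(tmp) saveRDS(model, tmp), path)
  spec <- model$spec
  class(spec) <- NULL
  yaml::write_yaml(spec, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "sfx_model"))
  model
}
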