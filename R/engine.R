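# Forward and backward machinery for the compact CNN engine.
#
# A model is an ordered list of units (conv, pool, flatten, fc, res_stage,
# gap). Each named unit's OUTPUT is its post-ReLU activation A^k; pooling is
# a separate unit so activations() and gradient capture see the feature maps
# at full block resolution. The backward pass is hand-derived layer adjoints
# (im2col/col2im convolution, argmax pooling); the `relu_mode` switch turns
# every ReLU backward into the guided-backpropagation variant, which passes
# gradient only where the forward pre-activation AND the incoming gradient
# are both positive.

relu <- function(x) pmax(x, 0)

unit_forward <- function(unit, x) {
  switch(unit$type,
    conv = {
      d <- dim(x)
      cols <- im2col_cpp(x, d[1], d[2], d[3], unit$kh, unit$kw,
                         unit$stride, unit$pad)
      ho <- conv_out_size(d[1], unit$kh, unit$stride, unit$pad)
      wo <- conv_out_size(d[2], unit$kw, unit$stride, unit$pad)
      zmat <- unit$W %*% cols + unit$b
      z <- array(t(zmat), c(ho, wo, nrow(unit$W)))
      a <- relu(z)
      list(out = a, cache = list(cols = cols, z = z, indim = d))
    },
    pool = {
      d <- dim(x)
      pr <- maxpool_fwd_cpp(x, d[1], d[2], d[3], unit$p)
      list(out = pr$out, cache = list(idx = pr$idx, indim = d))
    },
    flatten = list(out = as.numeric(x), cache = list(indim = dim(x))),
    fc = {
      z <- drop(unit$W %*% x) + unit$b
      a <- if (isTRUE(unit$relu)) relu(z) else z
      list(out = a, cache = list(v = x, z = z))
    },
    gap = {
      d <- dim(x)
      list(out = apply(x, 3, mean), cache = list(indim = d))
    },
    res_stage = {
      caches <- vector("list", length(unit$blocks))
      for (j in seq_along(unit$blocks)) {
        r <- res_block_forward(unit$blocks[[j]], x)
        x <- r$out
        caches[[j]] <- r$cache
      }
      list(out = x, cache = list(blocks = caches))
    },
    stop("unknown unit type: ", unit$type))
}

conv_apply <- function(x, W, b, kh, kw, stride, pad) {
  d <- dim(x)
  cols <- im2col_cpp(x, d[1], d[2], d[3], kh, kw, stride, pad)
  ho <- conv_out_size(d[1], kh, stride, pad)
  wo <- conv_out_size(d[2], kw, stride, pad)
  z <- array(t(W %*% cols + b), c(ho, wo, nrow(W)))
  list(z = z, cols = cols)
}

res_block_forward <- function(blk, x) {
  c1 <- conv_apply(x, blk$W1, blk$b1, 3L, 3L, blk$stride, 1L)
  h1 <- relu(c1$z)
  c2 <- conv_apply(h1, blk$W2, blk$b2, 3L, 3L, 1L, 1L)
  if (is.null(blk$proj)) {
    s <- x
    cs <- NULL
  } else {
    cs <- conv_apply(x, blk$proj, blk$proj_b, 1L, 1L, blk$stride, 0L)
    s <- cs$z
  }
  zsum <- c2$z + s
  list(out = relu(zsum),
       cache = list(indim = dim(x), cols1 = c1$cols, z1 = c1$z,
                    h1dim = dim(h1), cols2 = c2$cols,
                    colss = if (is.null(cs)) NULL else cs$cols,
                    zsum = zsum))
}

# Run the full network; returns logits plus everything the backward pass and
# the explanation methods need.
forward_pass <- function(model, input) {
  caches <- vector("list", length(model$units))
  acts <- list()
  x <- input
  for (i in seq_along(model$units)) {
    u <- model$units[[i]]
    r <- unit_forward(u, x)
    caches[[i]] <- r$cache
    x <- r$out
    acts[[u$name]] <- x
  }
  list(scores = as.numeric(x), caches = caches, acts = acts, input = input)
}

relu_backward <- function(dA, z, relu_mode) {
  dZ <- dA * (z > 0)
  if (relu_mode == "guided") dZ <- dZ * (dA > 0)
  dZ
}

conv_backward_core <- function(W, cols, dZ, indim, kh, kw, stride, pad,
                               want_params) {
  f <- nrow(W)
  dZmat <- t(matrix(dZ, length(dZ) / f, f))
  dcols <- crossprod(W, dZmat)
  dx <- col2im_cpp(dcols, indim[1], indim[2], indim[3], kh, kw, stride, pad)
  if (want_params)
    list(dx = dx, dW = tcrossprod(dZmat, cols), db = rowSums(dZmat))
  else list(dx = dx)
}

unit_backward <- function(unit, cache, dout, relu_mode, want_params) {
  switch(unit$type,
    conv = {
      dZ <- relu_backward(dout, cache$z, relu_mode)
      conv_backward_core(unit$W, cache$cols, dZ, cache$indim,
                         unit$kh, unit$kw, unit$stride, unit$pad, want_params)
    },
    pool = {
      d <- cache$indim
      list(dx = maxpool_bwd_cpp(dout, cache$idx, d[1], d[2], d[3]))
    },
    flatten = list(dx = array(dout, cache$indim)),
    fc = {
      dZ <- if (isTRUE(unit$relu)) relu_backward(dout, cache$z, relu_mode) else dout
      r <- list(dx = drop(crossprod(unit$W, dZ)))
      if (want_params) { r$dW <- tcrossprod(dZ, cache$v); r$db <- dZ }
      r
    },
    gap = {
      d <- cache$indim
      g <- array(0, d)
      for (k in seq_len(d[3])) g[, , k] <- dout[k] / (d[1] * d[2])
      list(dx = g)
    },
    res_stage = {
      dblocks <- if (want_params) vector("list", length(unit$blocks)) else NULL
      for (j in rev(seq_along(unit$blocks))) {
        r <- res_block_backward(unit$blocks[[j]], cache$blocks[[j]], dout,
                                relu_mode, want_params)
        dout <- r$dx
        if (want_params) dblocks[[j]] <- r$dparams
      }
      list(dx = dout, dblocks = dblocks)
    },
    stop("unknown unit type: ", unit$type))
}

res_block_backward <- function(blk, cache, dout, relu_mode, want_params) {
  dPre <- relu_backward(dout, cache$zsum, relu_mode)
  b2 <- conv_backward_core(blk$W2, cache$cols2, dPre, cache$h1dim,
                           3L, 3L, 1L, 1L, want_params)
  dH1 <- relu_backward(b2$dx, cache$z1, relu_mode)
  b1 <- conv_backward_core(blk$W1, cache$cols1, dH1, cache$indim,
                           3L, 3L, blk$stride, 1L, want_params)
  if (is.null(blk$proj)) {
    dx <- b1$dx + dPre
    bs <- NULL
  } else {
    bs <- conv_backward_core(blk$proj, cache$colss, dPre, cache$indim,
                             1L, 1L, blk$stride, 0L, want_params)
    dx <- b1$dx + bs$dx
  }
  dparams <- if (want_params)
    list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
         proj = if (is.null(bs)) NULL else bs$dW,
         proj_b = if (is.null(bs)) NULL else bs$db)
  else NULL
  list(dx = dx, dparams = dparams)
}

# Backward through the whole network (or, with `from_layer`, starting at a
# named unit's output with seed gradient `dout`). Returns the gradient with
# respect to the input, gradients at every named activation, and optionally
# parameter gradients.
backward_pass <- function(model, fp, dout, relu_mode = "normal",
                          want_params = FALSE, from_layer = NULL) {
  n <- length(model$units)
  start <- n
  if (!is.null(from_layer)) {
    start <- match(from_layer, model$layer_names)
    if (is.na(start)) stop("unknown layer: ", from_layer)
  }
  grads_at <- list()
  pgrads <- if (want_params) vector("list", n) else NULL
  g <- dout
  for (i in seq(start, 1L)) {
    u <- model$units[[i]]
    grads_at[[u$name]] <- g
    r <- unit_backward(u, fp$caches[[i]], g, relu_mode, want_params)
    g <- r$dx
    if (want_params) pgrads[[i]] <- r
  }
  list(dinput = g, grads_at = grads_at, pgrads = pgrads)
}

#' Class scores for a frame
#'
#' Runs the network forward and returns the raw class scores (logits,
#' before softmax). Probabilities for reporting are obtained with
#' [softmax()].
#'
#' @param model an `sfx_model`.
#' @param frame an `sfx_frame`, H x W matrix, or preprocessed input array.
#' @param preprocess apply [preprocess_frame()] first (default `TRUE`;
#'   set `FALSE` when `frame` is already an input array).
#' @return numeric vector of `n_classes` raw scores.
#' @export
forward <- function(model, frame, preprocess = TRUE) {
  input <- if (preprocess) preprocess_frame(model, frame) else frame
  forward_pass(model, input)$scores
}

#' Numerically stable softmax
#'
#' @param scores numeric vector of raw class scores.
#' @return probability vector summing to 1.
#' @export
softmax <- function(scores) {
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Post-ReLU feature maps of a named layer
#'
#' @param model an `sfx_model`.
#' @param frame frame or input array (see [forward()]).
#' @param layer layer name, e.g. `"conv3"` or `"stage2"`.
#' @param preprocess apply preprocessing first.
#' @return h x w x K activation array (or vector for fully connected
#'   layers); entries are >= 0 for every ReLU-terminated layer.
#' @export
activations <- function(model, frame, layer, preprocess = TRUE) {
  if (!layer %in% model$layer_names) stop("unknown layer: ", layer)
  input <- if (preprocess) preprocess_frame(model, frame) else frame
  forward_pass(model, input)$acts[[layer]]
}

# Continue the forward pass from a given activation at a named layer.
# Used by finite-difference oracles in tests and by the CAM cross-check.
forward_from <- function(model, layer, a) {
  i <- match(layer, model$layer_names)
  if (is.na(i)) stop("unknown layer: ", layer)
  x <- a
  for (j in seq_along(model$units)) {
    if (j <= i) next
    x <- unit_forward(model$units[[j]], x)$out
  }
  as.numeric(x)
}

#' Gradient of a class score with respect to a layer's activations
#'
#' Computes d y_c / d A^k where `y_c` is the raw (pre-softmax) score of
#' class `class_index` and `A^k` are the post-ReLU feature maps of `layer`.
#'
#' @param model an `sfx_model`.
#' @param frame frame or input array.
#' @param class_index 1-based class index.
#' @param layer layer name.
#' @param preprocess apply preprocessing first.
#' @return array shaped like the layer's activations.
#' @export
score_gradients <- function(model, frame, class_index, layer,
                            preprocess = TRUE) {
  if (!layer %in% model$layer_names) stop("unknown layer: ", layer)
  input <- if (preprocess) preprocess_frame(model, frame) else frame
  fp <- forward_pass(model, input)
  dscores <- numeric(length(fp$scores))
  dscores[class_index] <- 1
  bp <- backward_pass(model, fp, dscores)
  bp$grads_at[[layer]]
}

# ---- parameter plumbing (used by the trainer) -------------------------------

get_params <- function(model) {
  out <- list()
  for (i in seq_along(model$units)) {
    u <- model$units[[i]]
    if (u$type %in% c("conv", "fc")) {
      out[[paste0(u$name, ".W")]] <- u$W
      out[[paste0(u$name, ".b")]] <- u$b
    } else if (u$type == "res_stage") {
      for (j in seq_along(u$blocks)) {
        blk <- u$blocks[[j]]
        for (f in c("W1", "b1", "W2", "b2", "proj", "proj_b"))
          if (!is.null(blk[[f]]))
            out[[paste0(u$name, ".b", j, ".", f)]] <- blk[[f]]
      }
    }
  }
  out
}

set_params <- function(model, params) {
  for (i in seq_along(model$units)) {
    u <- model$units[[i]]
    if (u$type %in% c("conv", "fc")) {
      model$units[[i]]$W <- params[[paste0(u$name, ".W")]]
      model$units[[i]]$b <- params[[paste0(u$name, ".b")]]
    } else if (u$type == "res_stage") {
      for (j in seq_along(u$blocks)) {
        for (f in c("W1", "b1", "W2", "b2", "proj", "proj_b")) {
          key <- paste0(u$name, ".b", j, ".", f)
          if (!is.null(params[[key]])) model$units[[i]]$blocks[[j]][[f]] <- params[[key]]
        }
      }
    }
  }
  model
}

# Flatten the per-unit gradient structure from backward_pass into the same
# named layout as get_params().
flatten_pgrads <- function(model, pgrads) {
  out <- list()
  for (i in seq_along(model$units)) {
    u <- model$units[[i]]
    r <- pgrads[[i]]
    if (is.null(r)) next
    if (u$type %in% c("conv", "fc") && !is.null(r$dW)) {
      out[[paste0(u$name, ".W")]] <- r$dW
      out[[paste0(u$name, ".b")]] <- r$db
    } else if (u$type == "res_stage" && !is.null(r$dblocks)) {
      for (j in seq_along(r$dblocks)) {
        dp <- r$dblocks[[j]]
        for (f in c("W1", "b1", "W2", "b2", "proj", "proj_b"))
          if (!is.null(dp[[f]]))
            out[[paste0(u$name, ".b", j, ".", f)]] <- dp[[f]]
      }
    }
  }
  out
}
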