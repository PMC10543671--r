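#' Neuron importance weights from score gradients
#'
#' Average-pools the class-score gradients over the spatial dimensions:
#' `alpha_k = (1/Z) * sum_ij dy_c / dA^k_ij` with `Z = h * w`, one weight
#' per feature map.
#'
#' @param grads h x w x K gradient array from [score_gradients()].
#' @return numeric vector of K importance weights.
#' @export
neuron_importance <- function(grads) {
  stopifnot(length(dim(grads)) == 3)
  apply(grads, 3, mean)
}

#' Gradient-weighted class activation map
#'
#' Grad-CAM for one frame and class: (i) the gradient of the raw
#' (pre-softmax) class score with respect to the chosen convolutional
#' layer's post-ReLU feature maps; (ii) spatial average pooling of those
#' gradients into per-map importance weights; (iii) the importance-weighted
#' sum of the feature maps followed by a ReLU, keeping only positively
#' contributing regions; (iv) bilinear upsampling to the input size; and
#' (v) min-max normalization to `[0, 1]` for display (an all-zero map stays
#' all-zero). The overlay blends a jet-style colormap of the heat map onto
#' the input frame.
#'
#' @param model an `sfx_model`.
#' @param frame an `sfx_frame` or H x W matrix.
#' @param class_index 1-based class to explain; default is the predicted
#'   class.
#' @param layer convolutional layer name; default is the model's last
#'   convolutional layer (last residual stage for resnet style).
#' @param preprocess apply [preprocess_frame()] first (set `FALSE` when
#'   `frame` is already an input array).
#' @return an `sfx_gradcam`: list with `layer`, `class_index`,
#'   `importance` (alpha_k), `raw_map` (h x w, >= 0), `heatmap`
#'   (input-sized, in `[0, 1]`) and `overlay` (H x W x 3 RGB array).
#' @export
gradcam <- function(model, frame, class_index = NULL, layer = NULL,
                    preprocess = TRUE) {
  layer <- layer %||% default_explain_layer(model)
  input <- if (preprocess) preprocess_frame(model, frame) else frame
  fp <- forward_pass(model, input)
  class_index <- class_index %||% which.max(fp$scores)
  dscores <- numeric(length(fp$scores))
  dscores[class_index] <- 1
  bp <- backward_pass(model, fp, dscores)
  grads <- bp$grads_at[[layer]]
  if (is.null(grads) || length(dim(grads)) != 3)
    stop("layer '", layer, "' is not a convolutional layer of this model")
  a <- fp$acts[[layer]]
  alpha <- neuron_importance(grads)
  raw <- matrix(0, dim(a)[1], dim(a)[2])
  for (k in seq_along(alpha)) raw <- raw + alpha[k] * a[, , k]
  raw <- pmax(raw, 0)
  n <- model$spec$input_size
  heat <- bilinear_resize(raw, n, n)
  rng <- range(heat)
  heatmap <- if (rng[2] > rng[1]) (heat - rng[1]) / (rng[2] - rng[1])
             else heat * 0
  structure(list(layer = layer, class_index = class_index,
                 importance = alpha, raw_map = raw, heatmap = heatmap,
                 overlay = heat_overlay(input[, , 1], heatmap)),
            class = "sfx_gradcam")
}

# Jet-style colormap blend of a [0,1] heat map on a grayscale image.
heat_overlay <- function(gray, heatmap, alpha = 0.5) {
  g <- gray - min(gray)
  if (max(g) > 0) g <- g / max(g)
  r <- pmin(pmax(1.5 - abs(4 * heatmap - 3), 0), 1)
  gr <- pmin(pmax(1.5 - abs(4 * heatmap - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * heatmap - 1), 0), 1)
  out <- array(0, c(nrow(g), ncol(g), 3))
  out[, , 1] <- (1 - alpha) * g + alpha * r
  out[, , 2] <- (1 - alpha) * g + alpha * gr
  out[, , 3] <- (1 - alpha) * g + alpha * b
  out
}

#' Guided backpropagation saliency
#'
#' Backward pass in which every ReLU passes gradient only where its forward
#' pre-activation was positive AND the incoming gradient is positive,
#' yielding sharp signed pixel-space gradients.
#'
#' @param model an `sfx_model`.
#' @param frame an `sfx_frame` or H x W matrix.
#' @param class_index 1-based class; default is the predicted class.
#' @param preprocess apply [preprocess_frame()] first.
#' @return H x W signed gradient matrix (summed over input channel
#'   replicas).
#' @export
guided_backprop <- function(model, frame, class_index = NULL,
                            preprocess = TRUE) {
  input <- if (preprocess) preprocess_frame(model, frame) else frame
  fp <- forward_pass(model, input)
  class_index <- class_index %||% which.max(fp$scores)
  dscores <- numeric(length(fp$scores))
  dscores[class_index] <- 1
  bp <- backward_pass(model, fp, dscores, relu_mode = "guided")
  apply(bp$dinput, c(1, 2), sum)
}

#' Guided Grad-CAM
#'
#' Elementwise product of the upsampled Grad-CAM heat map and the guided
#' backpropagation gradients, combining class localization with
#' fine-grained pixel detail.
#'
#' @param gradcam_result an `sfx_gradcam` from [gradcam()].
#' @param guided matrix from [guided_backprop()] (same shape as the heat
#'   map).
#' @return H x W signed matrix.
#' @export
guided_gradcam <- function(gradcam_result, guided) {
  stopifnot(inherits(gradcam_result, "sfx_gradcam"))
  if (!all(dim(gradcam_result$heatmap) == dim(guided)))
    stop("heat map and guided gradients have mismatched shapes")
  gradcam_result$heatmap * guided
}

#' Histogram of activation values
#'
#' Equal-width binning over the value range; counts always sum to the
#' number of elements (a constant array lands in a single bin).
#'
#' @param x numeric array (heat map or activations).
#' @param n_bins number of bins (>= 1).
#' @return list with `edges` (length `n_bins + 1`) and `counts`.
#' @export
activation_histogram <- function(x, n_bins = 32) {
  stopifnot(n_bins >= 1)
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi == lo) hi <- lo + 1
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
  list(edges = edges, counts = tabulate(bin, nbins = n_bins))
}

#' Fraction of heat-map mass on ground-truth peak regions
#'
#' `sum(heatmap[mask]) / sum(heatmap)`. For a heat map that ignores peak
#' locations entirely (uniform), the score equals the mask's area fraction;
#' values above that indicate peak-seeking localization.
#'
#' @param heatmap non-negative matrix.
#' @param mask logical matrix from [peak_mask()].
#' @return fraction in `[0, 1]`; `NA` (flagged undefined) for an all-zero
#'   heat map.
#' @export
localization_score <- function(heatmap, mask) {
  stopifnot(all(dim(heatmap) == dim(mask)))
  total <- sum(heatmap)
  if (total == 0) {
    warning("all-zero heat map: localization score undefined")
    return(NA_real_)
  }
  sum(heatmap[mask]) / total
}
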