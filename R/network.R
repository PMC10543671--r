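#' Size-parameterized CNN architecture description
#'
#' Describes either an AlexNet-style network (exactly five convolutional
#' blocks followed by three fully connected layers, ReLU after every hidden
#' layer) or a residual network (stages of two-convolution residual blocks,
#' global average pooling, linear head). All sizes are free parameters so
#' the same architecture family runs at desk scale (64 x 64 inputs, small
#' filter counts) or at the full 512-class-study scale.
#'
#' @param arch `"alexnet_style"` or `"resnet_style"`.
#' @param input_size input side length in pixels.
#' @param in_channels input channel count; grayscale frames are replicated
#'   to this count during preprocessing.
#' @param conv_blocks list of 5 blocks, each `list(filters, kernel, stride,
#'   pool)` (`pool` = max-pool window after the block, 0 for none).
#'   AlexNet style only.
#' @param fc_sizes integer vector of 3 fully connected widths; the last
#'   must equal `n_classes`. AlexNet style only.
#' @param n_classes number of output classes.
#' @param residual_depth integer vector, residual blocks per stage
#'   (resnet style only).
#' @param stage_filters filter count per residual stage; defaults to
#'   `16 * 2^(stage-1)`.
#' @return a validated `sfx_netspec` object.
#' @seealso [desk_alexnet_spec()], [desk_resnet_spec()], [paper_alexnet_spec()]
#' @export
network_spec <- function(arch = c("alexnet_style", "resnet_style"),
                         input_size = 64, in_channels = 1,
                         conv_blocks = NULL, fc_sizes = NULL,
                         n_classes = 5, residual_depth = c(2, 2),
                         stage_filters = NULL) {
  arch <- match.arg(arch)
  spec <- list(arch = arch, input_size = as.integer(input_size),
               in_channels = as.integer(in_channels),
               n_classes = as.integer(n_classes))
  if (arch == "alexnet_style") {
    stopifnot(!is.null(conv_blocks), !is.null(fc_sizes))
    if (length(conv_blocks) != 5)
      stop("alexnet_style requires exactly 5 conv blocks")
    if (length(fc_sizes) != 3)
      stop("alexnet_style requires exactly 3 fully connected layers")
    if (fc_sizes[3] != n_classes)
      stop("last fully connected width must equal n_classes")
    spec$conv_blocks <- lapply(conv_blocks, function(b) {
      stopifnot(all(c("filters", "kernel", "stride") %in% names(b)))
      b$pool <- b$pool %||% 0L
      b$pad <- b$pad %||% (b$kernel %/% 2L)
      b
    })
    spec$fc_sizes <- as.integer(fc_sizes)
  } else {
    stopifnot(length(residual_depth) >= 1, all(residual_depth >= 1))
    spec$residual_depth <- as.integer(residual_depth)
    spec$stage_filters <- as.integer(stage_filters %||%
                                       (16L * 2L^(seq_along(residual_depth) - 1L)))
    stopifnot(length(spec$stage_filters) == length(spec$residual_depth))
  }
  structure(spec, class = "sfx_netspec")
}

#' Desk-scale AlexNet-style specification
#'
#' Five conv blocks with modest filter counts on 64 x 64 inputs; spatial
#' resolution 64 -> 32 (stride-2 conv) -> 16 -> 8 -> 8 -> 8 -> 4 (pools).
#'
#' @param n_classes number of output classes.
#' @param input_size input side length.
#' @return an `sfx_netspec`.
#' @export
desk_alexnet_spec <- function(n_classes = 5, input_size = 64) {
  network_spec("alexnet_style", input_size = input_size, in_channels = 1,
               conv_blocks = list(
                 list(filters = 16L, kernel = 5L, stride = 2L, pool = 2L),
                 list(filters = 32L, kernel = 3L, stride = 1L, pool = 2L),
                 list(filters = 48L, kernel = 3L, stride = 1L, pool = 0L),
                 list(filters = 48L, kernel = 3L, stride = 1L, pool = 0L),
                 list(filters = 32L, kernel = 3L, stride = 1L, pool = 2L)),
               fc_sizes = c(128L, 64L, n_classes), n_classes = n_classes)
}

#' Full-scale AlexNet-style specification
#'
#' The canonical filter counts (96/256/384/384/256 convolutions,
#' 4096/4096/k fully connected) on 227 x 227 three-channel inputs. Provided
#' as a configuration choice for full-scale runs; the desk-scale preset is
#' what the bundled study and tests exercise.
#'
#' @param n_classes number of output classes.
#' @return an `sfx_netspec`.
#' @export
paper_alexnet_spec <- function(n_classes = 5) {
  network_spec("alexnet_style", input_size = 227, in_channels = 3,
               conv_blocks = list(
                 list(filters = 96L, kernel = 11L, stride = 4L, pool = 2L, pad = 0L),
                 list(filters = 256L, kernel = 5L, stride = 1L, pool = 2L),
                 list(filters = 384L, kernel = 3L, stride = 1L, pool = 0L),
                 list(filters = 384L, kernel = 3L, stride = 1L, pool = 0L),
                 list(filters = 256L, kernel = 3L, stride = 1L, pool = 2L)),
               fc_sizes = c(4096L, 4096L, n_classes), n_classes = n_classes)
}

#' Desk-scale residual network specification
#'
#' Two stages of two residual blocks each (stride-2 projection between
#' stages), global average pooling and a linear head. The last residual
#' stage is the default explanation layer, mirroring the "layer 4"
#' convention for deep residual networks.
#'
#' @param n_classes number of output classes.
#' @param input_size input side length.
#' @param residual_depth blocks per stage.
#' @return an `sfx_netspec`.
#' @export
desk_resnet_spec <- function(n_classes = 5, input_size = 64,
                             residual_depth = c(2, 2)) {
  network_spec("resnet_style", input_size = input_size, in_channels = 1,
               n_classes = n_classes, residual_depth = residual_depth)
}

conv_out_size <- function(size, kernel, stride, pad) {
  (size + 2L * pad - kernel) %/% stride + 1L
}

# He-style Gaussian initialization, deterministic given the RNG stream.
init_w <- function(nout, nin) matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)

#' Build a model from a specification
#'
#' Instantiates the network with He-initialized weights. Initialization is
#' deterministic given `seed`, and the parameter count is a pure function
#' of the specification.
#'
#' @param spec an `sfx_netspec`.
#' @param seed integer seed for weight initialization.
#' @return an `sfx_model` with ordered named layers (`conv1..conv5`,
#'   `fc1..fc3` for AlexNet style; `stage1..stageK`, `head` for resnet
#'   style) whose activations and gradients are accessible via
#'   [activations()] and [score_gradients()].
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sfx_netspec"))
  set.seed(seed)
  units <- list()
  size <- spec$input_size
  chan <- spec$in_channels
  if (spec$arch == "alexnet_style") {
    for (i in seq_along(spec$conv_blocks)) {
      b <- spec$conv_blocks[[i]]
      units[[length(units) + 1L]] <- list(
        type = "conv", name = paste0("conv", i),
        W = init_w(b$filters, b$kernel^2 * chan),
        b = numeric(b$filters),
        kh = b$kernel, kw = b$kernel, stride = b$stride, pad = b$pad,
        in_channels = chan)
      size <- conv_out_size(size, b$kernel, b$stride, b$pad)
      if (size < 1) stop("conv", i, " reduces spatial size below 1")
      chan <- b$filters
      if (b$pool > 0) {
        units[[length(units) + 1L]] <- list(type = "pool", name = paste0("pool", i),
                                            p = as.integer(b$pool))
        size <- size %/% b$pool
        if (size < 1) stop("pool after conv", i, " reduces spatial size below 1")
      }
    }
    units[[length(units) + 1L]] <- list(type = "flatten", name = "flatten")
    nin <- size^2 * chan
    for (i in 1:3) {
      nout <- spec$fc_sizes[i]
      units[[length(units) + 1L]] <- list(
        type = "fc", name = paste0("fc", i),
        W = init_w(nout, nin), b = numeric(nout), relu = (i < 3))
      nin <- nout
    }
  } else {
    for (s in seq_along(spec$residual_depth)) {
      blocks <- list()
      f <- spec$stage_filters[s]
      for (j in seq_len(spec$residual_depth[s])) {
        stride <- if (j == 1L && s > 1L) 2L else 1L
        proj <- if (chan != f || stride > 1L) init_w(f, chan) else NULL
        blocks[[j]] <- list(
          W1 = init_w(f, 9L * chan), b1 = numeric(f),
          W2 = init_w(f, 9L * f), b2 = numeric(f),
          proj = proj, proj_b = if (is.null(proj)) NULL else numeric(f),
          stride = stride, in_channels = chan)
        if (stride > 1L) size <- conv_out_size(size, 1L, 2L, 0L)
        if (size < 1) stop("stage ", s, " reduces spatial size below 1")
        chan <- f
      }
      units[[length(units) + 1L]] <- list(type = "res_stage",
                                          name = paste0("stage", s),
                                          blocks = blocks)
    }
    units[[length(units) + 1L]] <- list(type = "gap", name = "gap")
    units[[length(units) + 1L]] <- list(
      type = "fc", name = "head",
      W = init_w(spec$n_classes, chan), b = numeric(spec$n_classes),
      relu = FALSE)
  }
  structure(list(spec = spec, units = units,
                 layer_names = vapply(units, `[[`, "", "name")),
            class = "sfx_model")
}

#' @export
print.sfx_model <- function(x, ...) {
  np <- sum(vapply(get_params(x), length, 1L))
  cat(sprintf("<sfx_model %s input=%dx%dx%d classes=%d params=%d>\n",
              x$spec$arch, x$spec$input_size, x$spec$input_size,
              x$spec$in_channels, x$spec$n_classes, np))
  cat("  layers:", paste(x$layer_names, collapse = " "), "\n")
  invisible(x)
}

#' Names of the model's explanation-capable layers
#'
#' @param model an `sfx_model`.
#' @return character vector of convolutional layer / stage names.
#' @export
conv_layer_names <- function(model) {
  types <- vapply(model$units, `[[`, "", "type")
  model$layer_names[types %in% c("conv", "res_stage")]
}

# Default layer for explanations: last conv layer (AlexNet style) or last
# residual stage (resnet style).
default_explain_layer <- function(model) {
  nm <- conv_layer_names(model)
  nm[length(nm)]
}

#' Preprocess a frame for a model
#'
#' Per-frame normalization (subtract mean, divide by standard deviation
#' + 1e-8), bilinear resize to the model's input size if needed, and
#' replication of the grayscale frame to the model's channel count.
#'
#' @param model an `sfx_model`.
#' @param frame an `sfx_frame` or a plain H x W matrix.
#' @return H x W x C input array.
#' @export
preprocess_frame <- function(model, frame) {
  x <- if (inherits(frame, "sfx_frame")) frame$pixels else frame
  stopifnot(is.matrix(x))
  n <- model$spec$input_size
  if (nrow(x) != n || ncol(x) != n) x <- bilinear_resize(x, n, n)
  x <- (x - mean(x)) / (sd(x) + 1e-8)
  array(x, c(n, n, model$spec$in_channels))
}
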