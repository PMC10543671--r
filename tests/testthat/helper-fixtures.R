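# Shared fixtures: tiny networks with hand-settable weights, small datasets,
# and a memoized desk-scale training run shared by the slower study-level
# tests (training happens once per test session).

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

# 5-conv-block spec scaled down to a 16x16 input, few filters.
tiny_alexnet_spec <- function(n_classes = 3) {
  network_spec("alexnet_style", input_size = 16,
               conv_blocks = list(
                 list(filters = 3L, kernel = 3L, stride = 1L, pool = 2L),
                 list(filters = 4L, kernel = 3L, stride = 1L, pool = 0L),
                 list(filters = 4L, kernel = 3L, stride = 1L, pool = 0L),
                 list(filters = 4L, kernel = 3L, stride = 1L, pool = 2L),
                 list(filters = 3L, kernel = 3L, stride = 1L, pool = 0L)),
               fc_sizes = c(8L, 6L, n_classes), n_classes = n_classes)
}

tiny_model <- function(seed = 7, n_classes = 3) {
  build_model(tiny_alexnet_spec(n_classes), seed = seed)
}

# One conv block (no pool) + global average pooling + linear head: the
# architecture for which Grad-CAM coincides exactly with CAM computed from
# the head weights.
gap_toy_model <- function(seed = 5, n_classes = 2, filters = 4L,
                          input_size = 8L) {
  set.seed(seed)
  units <- list(
    list(type = "conv", name = "conv1",
         W = matrix(rnorm(filters * 9, 0, 0.5), filters, 9),
         b = numeric(filters), kh = 3L, kw = 3L, stride = 1L, pad = 1L,
         in_channels = 1L),
    list(type = "gap", name = "gap"),
    list(type = "fc", name = "head",
         W = matrix(rnorm(n_classes * filters, 0, 0.5), n_classes, filters),
         b = numeric(n_classes), relu = FALSE))
  spec <- network_spec("alexnet_style", input_size = input_size,
                       conv_blocks = list(
                         list(filters = 1L, kernel = 3L, stride = 1L, pool = 0L),
                         list(filters = 1L, kernel = 3L, stride = 1L, pool = 0L),
                         list(filters = 1L, kernel = 3L, stride = 1L, pool = 0L),
                         list(filters = 1L, kernel = 3L, stride = 1L, pool = 0L),
                         list(filters = 1L, kernel = 3L, stride = 1L, pool = 0L)),
                       fc_sizes = c(2L, 2L, n_classes), n_classes = n_classes)
  spec$input_size <- as.integer(input_size)
  structure(list(spec = spec, units = units,
                 layer_names = vapply(units, `[[`, "", "name")),
            class = "sfx_model")
}

# Fixed-weight 1-conv / 1-fc network on a 4x4 frame whose scores are easy
# to reproduce by hand (used for arithmetic oracles).
fixed_micro_model <- function() {
  kernel <- matrix(c(0, 1, 0,
                     1, -4, 1,
                     0, 1, 0), 3, 3, byrow = TRUE)  # Laplacian-like
  units <- list(
    list(type = "conv", name = "conv1",
         W = matrix(as.vector(kernel), 1, 9), b = 0.5,
         kh = 3L, kw = 3L, stride = 1L, pad = 0L, in_channels = 1L),
    list(type = "pool", name = "pool1", p = 2L),
    list(type = "flatten", name = "flatten"),
    list(type = "fc", name = "fc1", W = matrix(c(1, -1), 2, 1), b = c(0, 0.25),
         relu = FALSE))
  spec <- network_spec("alexnet_style", input_size = 4,
                       conv_blocks = list(
                         list(filters = 1L, kernel = 3L, stride = 1L, pool = 2L),
                         list(filters = 1L, kernel = 1L, stride = 1L, pool = 0L),
                         list(filters = 1L, kernel = 1L, stride = 1L, pool = 0L),
                         list(filters = 1L, kernel = 1L, stride = 1L, pool = 0L),
                         list(filters = 1L, kernel = 1L, stride = 1L, pool = 0L)),
                       fc_sizes = c(2L, 2L, 2L), n_classes = 2)
  spec$input_size <- 4L
  structure(list(spec = spec, units = units,
                 layer_names = vapply(units, `[[`, "", "name")),
            class = "sfx_model")
}

noise_free_scenes <- function(image_size = 32) {
  p <- default_scene_params(image_size, noise_sigma = 0)
  p
}

small_dataset <- function() {
  memoize("small_dataset", function() {
    ds <- generate_dataset(25, default_scene_params(), seed = 31,
                           test_fraction = 0.2)
    binarize_labels(ds)
  })
}

# Desk-scale study conditions: 500 train + 100 test frames per class,
# 64 x 64, 15-epoch training. Shared by the classification-accuracy and
# localization tests; trained once.
desk_dataset <- function() {
  memoize("desk_dataset", function() {
    ds <- generate_dataset(600, default_scene_params(), seed = 101,
                           test_fraction = 1 / 6)
    binarize_labels(ds)
  })
}

desk_fit_multiclass <- function() {
  memoize("desk_fit_multiclass", function() {
    ds <- desk_dataset()
    train(build_model(desk_alexnet_spec(5, 64), seed = 202), ds,
          train_config(epochs = 15, batch_size = 32, seed = 303),
          target = "multiclass")
  })
}

desk_fit_binary <- function() {
  memoize("desk_fit_binary", function() {
    ds <- desk_dataset()
    train(build_model(desk_alexnet_spec(2, 64), seed = 202), ds,
          train_config(epochs = 10, batch_size = 32, seed = 303),
          target = "binary")
  })
}

# Published five-class confusion-matrix counts of an AlexNet hit classifier
# on the DiffraNet test set (bundled as extdata); the worked example for
# the metric formulas.
published_confusion <- function() {
  path <- system.file("extdata", "diffranet_alexnet_confusion.csv",
                      package = "sfxsight")
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$true_class
  structure(m, class = c("sfx_confusion", "matrix", "array"))
}
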