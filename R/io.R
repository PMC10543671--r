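#' Write a dataset to disk
#'
#' Persists an `sfx_dataset` as a directory of 32-bit-sample TIFF frames
#' (`frame_00001.tif`, ...) plus a JSON sidecar `dataset.json` holding the
#' class-name map (Blank=0, NoCrystal=1, Weak=2, Good=3, Strong=4), labels,
#' split, optional binary labels, per-frame ground-truth peak tables and
#' the intensity scale used to map intensities into the TIFF `[0, 1]`
#' range. All writes are atomic (temp file + rename).
#'
#' @param dataset an `sfx_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sfx_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  peak_val <- max(1e-12, max(vapply(dataset$frames, function(f) max(f$pixels), 1)))
  # power-of-two scale so that rescaling is exact in binary floating point;
  # the TIFF carrier quantizes at 2^-32 of full scale
  scale <- 2^ceiling(log2(peak_val))
  for (i in seq_along(dataset$frames)) {
    path <- file.path(dir, sprintf("frame_%05d.tif", i))
    img <- dataset$frames[[i]]$pixels / scale
    atomic_write(function(tmp) tiff::writeTIFF(img, tmp, bits.per.sample = 32),
                 path)
  }
  meta <- list(
    class_names = sfx_classes,
    n_frames = length(dataset$frames),
    intensity_scale = scale,
    labels = as.integer(dataset$labels) - 1L,   # 0-based on disk
    split = as.character(dataset$split),
    binary = if (is.null(dataset$binary)) NULL
             else as.character(dataset$binary),
    peaks = lapply(dataset$frames, function(f) f$peaks)
  )
  atomic_write(function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null"),
    file.path(dir, "dataset.json"))
  invisible(dir)
}

#' Read a dataset written by [write_frames()]
#'
#' @param dir dataset directory.
#' @return an `sfx_dataset`.
#' @export
read_frames <- function(dir) {
  meta_path <- file.path(dir, "dataset.json")
  if (!file.exists(meta_path))
    stop("malformed dataset directory: missing ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("class_names", "n_frames", "labels", "split",
                  "intensity_scale"))
    if (is.null(meta[[field]]))
      stop("malformed dataset: missing '", field, "' in ", meta_path)
  frames <- vector("list", meta$n_frames)
  for (i in seq_len(meta$n_frames)) {
    path <- file.path(dir, sprintf("frame_%05d.tif", i))
    if (!file.exists(path)) stop("malformed dataset: missing ", path)
    px <- tiff::readTIFF(path) * meta$intensity_scale
    pk <- meta$peaks[[i]]
    peaks <- if (is.null(pk) || length(pk) == 0 || is.null(pk$row))
      data.frame(row = numeric(0), col = numeric(0), amplitude = numeric(0))
    else data.frame(row = as.numeric(pk$row), col = as.numeric(pk$col),
                    amplitude = as.numeric(pk$amplitude))
    frames[[i]] <- structure(
      list(pixels = px, peaks = peaks,
           label = meta$class_names[meta$labels[i] + 1L]),
      class = "sfx_frame")
  }
  structure(list(
    frames = frames,
    labels = factor(meta$class_names[meta$labels + 1L], levels = sfx_classes),
    split = factor(meta$split, levels = c("train", "test")),
    binary = if (is.null(meta$binary)) NULL
             else factor(meta$binary, levels = sfx_binary_classes)),
    class = "sfx_dataset")
}

#' Save a matrix or RGB array as PNG
#'
#' Grayscale matrices are min-max scaled to `[0, 1]`; H x W x 3 arrays are
#' written as-is (clipped to `[0, 1]`).
#'
#' @param x matrix or H x W x 3 array.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_png <- function(x, path) {
  if (is.matrix(x)) {
    rng <- range(x)
    x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  } else {
    x <- pmin(pmax(x, 0), 1)
  }
  atomic_write(function(tmp) png::writePNG(x, tmp), path)
  invisible(path)
}
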