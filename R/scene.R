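#' Scene parameters for one synthetic diffraction frame
#'
#' Describes the generative scene for a single detector frame of a given
#' class. Frames are composed of three additive terms, clipped at zero:
#' a Bragg-peak term (isotropic 2-D Gaussians at well-separated random
#' centres), an amorphous-ring term (smooth radially symmetric profile
#' around the beam centre), and detector noise (additive Gaussian, with
#' optional Poisson resampling of the photon signal).
#'
#' Class semantics follow the five-way diffraction labelling: `Blank`
#' carries neither peaks nor rings; `NoCrystal` carries rings but no peaks;
#' `Weak`, `Good` and `Strong` carry rings plus Bragg peaks whose count and
#' amplitude increase across the three classes.
#'
#' @param class_label one of [sfx_classes].
#' @param image_size frame side length in pixels (square frames; >= 16).
#' @param n_peaks_range integer interval `c(lo, hi)` for the number of
#'   Bragg peaks. Forced to `c(0, 0)` for `Blank`/`NoCrystal`.
#' @param peak_amplitude_range intensity interval for peak amplitudes
#'   (detector units).
#' @param peak_sigma Gaussian peak width in pixels.
#' @param ring_amplitude amplitude of the amorphous rings; 0 for `Blank`.
#' @param ring_radii ring centre radii in pixels.
#' @param ring_sigma radial width of each ring in pixels.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param poisson if `TRUE`, the noise-free photon signal is resampled
#'   Poisson before Gaussian noise is added.
#' @param min_sep_factor hard-core minimum peak separation, in units of
#'   `peak_sigma` (default 4, which keeps planted peak counts unambiguous;
#'   larger values give sparse scenes with fully isolated peaks).
#' @param seed optional integer seed; if given, [simulate_frame()] is a pure
#'   function of the parameters.
#' @return an object of class `sfx_scene` (a validated parameter list).
#' @seealso [default_scene_params()] for the per-class default table.
#' @export
scene_params <- function(class_label,
                         image_size = 64,
                         n_peaks_range = c(0L, 0L),
                         peak_amplitude_range = c(0, 0),
                         peak_sigma = 1.2,
                         ring_amplitude = 0,
                         ring_radii = c(10, 18, 26),
                         ring_sigma = 3,
                         noise_sigma = 0.3,
                         poisson = FALSE,
                         min_sep_factor = 4,
                         seed = NULL) {
  class_label <- match.arg(class_label, sfx_classes)
  stopifnot(image_size >= 16, length(n_peaks_range) == 2,
            n_peaks_range[1] <= n_peaks_range[2],
            length(peak_amplitude_range) == 2,
            peak_amplitude_range[1] <= peak_amplitude_range[2],
            peak_sigma > 0, ring_sigma > 0, noise_sigma >= 0,
            min_sep_factor >= 1)
  if (class_label %in% c("Blank", "NoCrystal")) n_peaks_range <- c(0L, 0L)
  if (class_label == "Blank") ring_amplitude <- 0
  if (class_label == "NoCrystal" && ring_amplitude <= 0)
    stop("NoCrystal frames need ring_amplitude > 0")
  p <- list(class_label = class_label, image_size = as.integer(image_size),
            n_peaks_range = as.integer(n_peaks_range),
            peak_amplitude_range = peak_amplitude_range,
            peak_sigma = peak_sigma, ring_amplitude = ring_amplitude,
            ring_radii = ring_radii, ring_sigma = ring_sigma,
            noise_sigma = noise_sigma, poisson = poisson,
            min_sep_factor = min_sep_factor, seed = seed)
  structure(p, class = "sfx_scene")
}

#' Default per-class scene parameters
#'
#' Returns a named list of [scene_params()] objects, one per class, scaled
#' to a given frame size. Peak counts and amplitudes increase across
#' `Weak < Good < Strong` (lower amplitude bounds 2 < 5 < 9), emulating
#' crystals of increasing diffraction strength; ring radii scale with the
#' frame so the amorphous background occupies the same relative area at
#' any resolution. Peak-count ranges are stated for 64 x 64 frames and
#' scale down with frame area below that (a small crop holds
#' proportionally fewer resolvable peaks); they do not grow above the
#' 64-pixel values, since the number of Bragg reflections is set by the
#' crystal, not the detector.
#'
#' @param image_size frame side length in pixels.
#' @param noise_sigma Gaussian read-noise level.
#' @param poisson enable Poisson photon noise.
#' @return named list of `sfx_scene` objects, names = [sfx_classes].
#' @export
default_scene_params <- function(image_size = 64, noise_sigma = 0.3,
                                 poisson = FALSE) {
  s <- image_size / 64
  radii <- c(10, 18, 26) * s
  area <- min(1, s^2)
  nrange <- function(lo, hi) as.integer(pmax(1, round(c(lo, hi) * area)))
  common <- list(image_size = image_size, ring_radii = radii,
                 ring_sigma = 3 * s, noise_sigma = noise_sigma,
                 poisson = poisson)
  mk <- function(label, ...) do.call(scene_params, c(list(label), common, list(...)))
  list(
    Blank     = mk("Blank"),
    NoCrystal = mk("NoCrystal", ring_amplitude = 1),
    Weak      = mk("Weak", ring_amplitude = 1, n_peaks_range = nrange(2, 6),
                   peak_amplitude_range = c(2, 4)),
    Good      = mk("Good", ring_amplitude = 1, n_peaks_range = nrange(8, 14),
                   peak_amplitude_range = c(5, 8)),
    Strong    = mk("Strong", ring_amplitude = 1, n_peaks_range = nrange(16, 26),
                   peak_amplitude_range = c(9, 14))
  )
}

# Sample peak centres uniformly on the pixel grid (so every ground-truth
# centre is an exact pixel location) with a hard-core minimum separation of
# 4 * peak_sigma, so that planted peaks are unambiguous local maxima.
# Gives up after 1000 candidate draws (overcrowded scene).
sample_peak_centres <- function(n, size, peak_sigma, sep_factor = 4) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  min_sep2 <- (sep_factor * peak_sigma)^2
  margin <- max(2, ceiling(3 * peak_sigma))
  lo <- 1 + margin; hi <- size - margin
  if (hi <= lo) stop("frame too small for the requested peak margin")
  centres <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L)
      stop("could not place ", n, " peaks with separation ",
           sep_factor * peak_sigma, " px in 1000 attempts (overcrowded scene)")
    cand <- sample(lo:hi, 2, replace = TRUE)  # pixel-centre positions
    if (placed > 0L) {
      d2 <- (centres[seq_len(placed), 1] - cand[1])^2 +
            (centres[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_sep2) next
    }
    placed <- placed + 1L
    centres[placed, ] <- cand
  }
  centres
}

#' Simulate one synthetic diffraction frame
#'
#' Renders the scene described by `params` into a non-negative intensity
#' array with ground-truth Bragg-peak coordinates. Peaks are isotropic 2-D
#' Gaussians at uniformly sampled centres with minimum pairwise separation
#' `4 * peak_sigma`; the ring term is a sum of Gaussian annuli centred on
#' the frame centre `((H+1)/2, (W+1)/2)` (1-based pixel coordinates).
#' Identical parameters and seed give a bit-identical frame.
#'
#' @param params an `sfx_scene` object from [scene_params()].
#' @return an `sfx_frame`: list with `pixels` (H x W matrix, >= 0),
#'   `peaks` (data.frame `row`, `col`, `amplitude`; empty for the two miss
#'   classes) and `label`.
#' @export
simulate_frame <- function(params) {
  stopifnot(inherits(params, "sfx_scene"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$image_size
  rng <- params$n_peaks_range
  n_peaks <- if (rng[2] > 0) {
    if (rng[1] == rng[2]) rng[1]
    else rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  } else 0L
  centres <- sample_peak_centres(n_peaks, n, params$peak_sigma,
                                 params$min_sep_factor)
  amps <- if (n_peaks > 0)
    runif(n_peaks, params$peak_amplitude_range[1], params$peak_amplitude_range[2])
  else numeric(0)

  img <- matrix(0, n, n)
  if (n_peaks > 0) {
    win <- ceiling(5 * params$peak_sigma)
    inv2s2 <- 1 / (2 * params$peak_sigma^2)
    for (k in seq_len(n_peaks)) {
      r0 <- centres[k, 1]; c0 <- centres[k, 2]
      rr <- max(1, floor(r0 - win)):min(n, ceiling(r0 + win))
      cc <- max(1, floor(c0 - win)):min(n, ceiling(c0 + win))
      g <- amps[k] * exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) * inv2s2)
      img[rr, cc] <- img[rr, cc] + g
    }
  }
  if (params$ring_amplitude > 0) {
    ctr <- (n + 1) / 2
    ax <- seq_len(n) - ctr
    r <- sqrt(outer(ax^2, ax^2, "+"))
    ring <- matrix(0, n, n)
    for (r0 in params$ring_radii)
      ring <- ring + exp(-(r - r0)^2 / (2 * params$ring_sigma^2))
    img <- img + params$ring_amplitude * ring
  }
  if (isTRUE(params$poisson))
    img <- matrix(rpois(n * n, pmax(img, 0)), n, n)
  if (params$noise_sigma > 0)
    img <- img + matrix(rnorm(n * n, 0, params$noise_sigma), n, n)
  img <- pmax(img, 0)

  peaks <- data.frame(row = centres[, 1], col = centres[, 2],
                      amplitude = amps)
  structure(list(pixels = img, peaks = peaks, label = params$class_label),
            class = "sfx_frame")
}

#' @export
print.sfx_frame <- function(x, ...) {
  cat(sprintf("<sfx_frame %dx%d class=%s peaks=%d mean=%.3f max=%.3f>\n",
              nrow(x$pixels), ncol(x$pixels), x$label, nrow(x$peaks),
              mean(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Generate a labelled synthetic dataset
#'
#' Simulates `n_per_class` frames for each of the five classes and attaches
#' a deterministic stratified train/test split. Per-frame ground truth
#' (peak lists) is retained on each frame.
#'
#' @param n_per_class frames per class (>= 1).
#' @param params_by_class named list of `sfx_scene` objects as produced by
#'   [default_scene_params()].
#' @param seed integer seed; together with `test_fraction` it fully
#'   determines frames and split.
#' @param test_fraction fraction of each class held out for testing
#'   (0 < f < 1).
#' @return an `sfx_dataset`: list with `frames` (list of `sfx_frame`),
#'   `labels` (factor over [sfx_classes]), `split` (factor train/test) and
#'   `binary` (`NULL` until [binarize_labels()] is applied).
#' @export
generate_dataset <- function(n_per_class,
                             params_by_class = default_scene_params(),
                             seed = 1L,
                             test_fraction = 0.2) {
  stopifnot(n_per_class >= 1, test_fraction > 0, test_fraction < 1,
            all(sfx_classes %in% names(params_by_class)))
  set.seed(seed)
  frames <- vector("list", 5L * n_per_class)
  labels <- character(length(frames))
  i <- 0L
  for (cl in sfx_classes) {
    p <- params_by_class[[cl]]
    p$seed <- NULL  # sequential RNG stream, seeded once above
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      frames[[i]] <- simulate_frame(p)
      labels[i] <- cl
    }
  }
  labels <- factor(labels, levels = sfx_classes)

  # stratified split, deterministic in (seed, test_fraction)
  set.seed(derive_seed(seed, 7919))
  split <- character(length(frames))
  n_test <- max(1L, round(test_fraction * n_per_class))
  for (cl in sfx_classes) {
    idx <- which(labels == cl)
    test_idx <- sample(idx, n_test)
    split[idx] <- "train"
    split[test_idx] <- "test"
  }
  structure(list(frames = frames, labels = labels,
                 split = factor(split, levels = c("train", "test")),
                 binary = NULL),
            class = "sfx_dataset")
}

#' @export
print.sfx_dataset <- function(x, ...) {
  cat(sprintf("<sfx_dataset %d frames (%s)>\n", length(x$frames),
              paste(levels(x$labels), table(x$labels), sep = "=", collapse = " ")))
  cat(sprintf("  split: train=%d test=%d; binary labels: %s\n",
              sum(x$split == "train"), sum(x$split == "test"),
              if (is.null(x$binary)) "absent" else "present"))
  invisible(x)
}

#' Attach hit/miss labels to a dataset
#'
#' Merges `Blank` and `NoCrystal` into `miss` and `Weak`, `Good`, `Strong`
#' into `hit`. The five-class labels are retained alongside.
#'
#' @param dataset an `sfx_dataset`.
#' @return the dataset with a `binary` factor over [sfx_binary_classes].
#' @export
binarize_labels <- function(dataset) {
  stopifnot(inherits(dataset, "sfx_dataset"))
  hit <- dataset$labels %in% c("Weak", "Good", "Strong")
  dataset$binary <- factor(ifelse(hit, "hit", "miss"),
                           levels = sfx_binary_classes)
  dataset
}

#' Ground-truth peak mask for a frame
#'
#' Binary mask that is `TRUE` within `dilation_radius` (Euclidean pixel
#' distance) of any planted Bragg-peak centre. Used to score how much of an
#' explanation heat map falls on true peak regions.
#'
#' @param frame an `sfx_frame` with at least one ground-truth peak.
#' @param dilation_radius disc radius in pixels (0 = centre pixels only).
#' @return logical H x W matrix.
#' @export
peak_mask <- function(frame, dilation_radius = 3) {
  stopifnot(inherits(frame, "sfx_frame"), dilation_radius >= 0)
  if (nrow(frame$peaks) == 0)
    stop("frame of class '", frame$label, "' has no ground-truth peaks to mask")
  h <- nrow(frame$pixels); w <- ncol(frame$pixels)
  mask <- matrix(FALSE, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (k in seq_len(nrow(frame$peaks))) {
    d2 <- (rows - frame$peaks$row[k])^2 + (cols - frame$peaks$col[k])^2
    mask <- mask | (d2 <= dilation_radius^2)
  }
  mask
}
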