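#' Spot-finder parameters
#'
#' Threshold-based Bragg-peak counting in the Peakfinder8 tradition: pixels
#' above a radially dependent threshold (robust background mean plus
#' `snr_min` background standard deviations for the pixel's annulus) are
#' grouped into connected components; components with more than `n_min`
#' but fewer than `n_max` pixels (strict inequalities) count as peaks, and
#' a frame is a hit when at least `n_peaks` peaks are found.
#'
#' @param n_min minimum connected size, exclusive.
#' @param n_max maximum connected size, exclusive.
#' @param n_peaks minimum number of peaks for a hit.
#' @param snr_min signal-to-noise threshold above the radial background.
#' @param n_radial_bins number of equal-width radial bins; `NULL` uses
#'   2-pixel-wide bins.
#' @param connectivity pixel connectivity, 4 or 8.
#' @return an `sfx_spotparams`.
#' @export
spot_params <- function(n_min = 2, n_max = 100, n_peaks = 3, snr_min = 3,
                        n_radial_bins = NULL, connectivity = 8) {
  stopifnot(n_min > 0, n_max > n_min, n_peaks >= 1, snr_min >= 0,
            connectivity %in% c(4, 8),
            is.null(n_radial_bins) || n_radial_bins >= 1)
  structure(list(n_min = n_min, n_max = n_max, n_peaks = n_peaks,
                 snr_min = snr_min, n_radial_bins = n_radial_bins,
                 connectivity = as.integer(connectivity)),
            class = "sfx_spotparams")
}

radius_map <- function(h, w) {
  ctr_r <- (h + 1) / 2; ctr_c <- (w + 1) / 2
  sqrt(outer((seq_len(h) - ctr_r)^2, (seq_len(w) - ctr_c)^2, "+"))
}

#' Radial background profile of a frame
#'
#' Splits the frame into equal-width annuli around the frame centre and
#' returns a robust location (median) and scale of the pixel intensities per
#' annulus. The scale is the upper-quartile estimator
#' `(q75 - median) / 0.6745` (equal to the standard deviation for Gaussian
#' data): unlike the MAD it does not collapse on zero-inflated annuli, which
#' arise wherever detector intensities are clipped at zero, and it stays
#' insensitive to bright Bragg-peak outliers. Empty annuli inherit the
#' nearest populated bin.
#'
#' @param frame an `sfx_frame` or H x W matrix.
#' @param n_bins number of bins; `NULL` for 2-pixel-wide bins.
#' @return data.frame with `r_lo`, `r_hi`, `mean`, `sd` per annulus.
#' @export
radial_background <- function(frame, n_bins = NULL) {
  x <- if (inherits(frame, "sfx_frame")) frame$pixels else frame
  stopifnot(is.matrix(x), length(x) > 0)
  r <- radius_map(nrow(x), ncol(x))
  rmax <- max(r)
  n_bins <- n_bins %||% max(1L, ceiling(rmax / 2))
  width <- rmax / n_bins
  bin <- pmin(pmax(floor(r / width), 0) + 1L, n_bins)
  mu <- rep(NA_real_, n_bins); s <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    v <- x[bin == b]
    if (length(v) > 0) {
      mu[b] <- median(v)
      s[b] <- (stats::quantile(v, 0.75, names = FALSE) - mu[b]) / 0.6745
    }
  }
  # empty annuli inherit the nearest populated bin
  pop <- which(!is.na(mu))
  if (length(pop) == 0) stop("no populated radial bins")
  for (b in seq_len(n_bins)) {
    if (is.na(mu[b])) {
      nb <- pop[which.min(abs(pop - b))]
      mu[b] <- mu[nb]; s[b] <- s[nb]
    }
  }
  data.frame(r_lo = (seq_len(n_bins) - 1) * width,
             r_hi = seq_len(n_bins) * width, mean = mu, sd = s)
}

#' Find Bragg peaks in a frame
#'
#' A pixel is a candidate iff its intensity exceeds
#' `mean(r) + snr_min * sd(r)` for its annulus of the radial background
#' profile. Candidates are grouped into connected components at the chosen
#' connectivity; components are kept iff `n_min < size < n_max`. Peaks are
#' reported with intensity-weighted centroids (weights are
#' background-subtracted intensities) and sorted by integrated intensity,
#' descending.
#'
#' @param frame an `sfx_frame` or H x W matrix.
#' @param params an `sfx_spotparams`.
#' @return data.frame with one row per peak: `row`, `col` (centroid),
#'   `size`, `intensity` (integrated, background-subtracted) and `snr`.
#' @export
find_peaks <- function(frame, params = spot_params()) {
  x <- if (inherits(frame, "sfx_frame")) frame$pixels else frame
  stopifnot(inherits(params, "sfx_spotparams"))
  prof <- radial_background(x, params$n_radial_bins)
  r <- radius_map(nrow(x), ncol(x))
  width <- prof$r_hi[1] - prof$r_lo[1]
  bin <- pmin(pmax(floor(r / width), 0) + 1L, nrow(prof))
  mu <- matrix(prof$mean[bin], nrow(x), ncol(x))
  sig <- matrix(prof$sd[bin], nrow(x), ncol(x))
  cand <- x > mu + params$snr_min * sig
  empty <- data.frame(row = numeric(0), col = numeric(0), size = integer(0),
                      intensity = numeric(0), snr = numeric(0))
  if (!any(cand)) return(empty)
  lab <- label_components_cpp(cand, params$connectivity)
  ids <- seq_len(max(lab))
  rows <- row(x); cols <- col(x)
  out <- lapply(ids, function(id) {
    sel <- lab == id
    size <- sum(sel)
    if (size <= params$n_min || size >= params$n_max) return(NULL)
    w <- pmax(x[sel] - mu[sel], 0)
    if (sum(w) == 0) w <- rep(1, size)
    integrated <- sum(x[sel] - mu[sel])
    noise <- sqrt(sum(sig[sel]^2))
    data.frame(row = sum(rows[sel] * w) / sum(w),
               col = sum(cols[sel] * w) / sum(w),
               size = size, intensity = integrated,
               snr = if (noise > 0) integrated / noise else Inf)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out[order(-out$intensity), , drop = FALSE]
}

#' Classify a frame as hit or miss by peak counting
#'
#' A frame is a hit iff [find_peaks()] returns at least `n_peaks` peaks.
#'
#' @param frame an `sfx_frame` or H x W matrix.
#' @param params an `sfx_spotparams`.
#' @return list with `label` (`"hit"`/`"miss"`) and `n_peaks` found.
#' @export
classify_hit <- function(frame, params = spot_params()) {
  peaks <- find_peaks(frame, params)
  n <- nrow(peaks)
  list(label = if (n >= params$n_peaks) "hit" else "miss", n_peaks = n)
}
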