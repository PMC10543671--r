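#' Round half away from zero
#'
#' Fixed-point rounding used for report tables: exact halves round up
#' (`95.75` -> `95.8`), unlike [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Bilinear resampling of a 2-D map
#'
#' Resizes `x` to `out_h` x `out_w` by bilinear interpolation with corner
#' alignment (the four corners of the output grid coincide with the corners
#' of the input grid). Used to project coarse feature-map-resolution heat
#' maps onto the detector frame.
#'
#' @param x numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return numeric `out_h` x `out_w` matrix.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  h <- nrow(x); w <- ncol(x)
  if (h == out_h && w == out_w) return(x)
  # map output pixel centres onto the input grid, corner-aligned
  ri <- if (out_h == 1) rep(1, out_h) else 1 + (seq_len(out_h) - 1) * (h - 1) / (out_h - 1)
  ci <- if (out_w == 1) rep(1, out_w) else 1 + (seq_len(out_w) - 1) * (w - 1) / (out_w - 1)
  r0 <- pmin(floor(ri), h - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), w - 1L); c0 <- pmax(c0, 1L)
  fr <- ri - r0
  fc <- ci - c0
  if (h == 1) { r0 <- rep(1L, out_h); fr <- rep(0, out_h) }
  if (w == 1) { c0 <- rep(1L, out_w); fc <- rep(0, out_w) }
  a <- x[r0, c0, drop = FALSE]
  b <- x[pmin(r0 + 1, h), c0, drop = FALSE]
  cc <- x[r0, pmin(c0 + 1, w), drop = FALSE]
  d <- x[pmin(r0 + 1, h), pmin(c0 + 1, w), drop = FALSE]
  FR <- matrix(fr, out_h, out_w)
  FC <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - FR) * (1 - FC) + b * FR * (1 - FC) + cc * (1 - FR) * FC + d * FR * FC
}

# Derive a stage seed from a global seed; keeps results independent across
# stages while staying within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1013 * offset) %% .Machine$integer.max)
}

# Atomic write: serialize to a temp file in the same directory, then rename.
atomic_write <- function(write_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
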