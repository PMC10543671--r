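# Brute-force local-maximum counter used as the independent oracle for
# planted-peak checks: strict 8-neighbourhood maxima above a floor.
count_local_maxima <- function(x, floor_value) {
  h <- nrow(x); w <- ncol(x)
  n <- 0L
  for (i in 2:(h - 1)) {
    for (j in 2:(w - 1)) {
      v <- x[i, j]
      if (v < floor_value) next
      nb <- x[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v > max(nb[-5])) n <- n + 1L
    }
  }
  n
}

test_that("blank scene with no noise renders an all-zero frame", {
  p <- scene_params("Blank", noise_sigma = 0, seed = 1)
  f <- simulate_frame(p)
  expect_true(all(f$pixels == 0))
  expect_equal(nrow(f$peaks), 0)
})

test_that("planted peaks are recovered exactly by a brute-force maxima scan", {
  p <- scene_params("Strong", n_peaks_range = c(5L, 5L),
                    peak_amplitude_range = c(9, 14), ring_amplitude = 0,
                    noise_sigma = 0, seed = 42)
  f <- simulate_frame(p)
  amp_floor <- min(f$peaks$amplitude) / 2
  expect_equal(count_local_maxima(f$pixels, amp_floor), 5L)
  # every planted centre is itself a local maximum of the noise-free frame
  for (k in seq_len(nrow(f$peaks))) {
    i <- f$peaks$row[k]; j <- f$peaks$col[k]
    nb <- f$pixels[(i - 1):(i + 1), (j - 1):(j + 1)]
    expect_gte(f$pixels[i, j], max(nb))
  }
})

test_that("identical scene parameters and seed give bit-identical frames", {
  p <- scene_params("Good", n_peaks_range = c(8L, 14L),
                    peak_amplitude_range = c(5, 8), ring_amplitude = 1,
                    seed = 9)
  f1 <- simulate_frame(p)
  f2 <- simulate_frame(p)
  expect_identical(f1$pixels, f2$pixels)
  expect_identical(f1$peaks, f2$peaks)
})

test_that("frames are non-negative and peak centres lie inside the frame", {
  for (s in 1:5) {
    p <- scene_params("Strong", n_peaks_range = c(16L, 26L),
                      peak_amplitude_range = c(9, 14), ring_amplitude = 1,
                      noise_sigma = 0.5, poisson = TRUE, seed = s)
    f <- simulate_frame(p)
    expect_true(all(f$pixels >= 0))
    expect_true(all(f$peaks$row >= 1 & f$peaks$row <= nrow(f$pixels)))
    expect_true(all(f$peaks$col >= 1 & f$peaks$col <= ncol(f$pixels)))
  }
})

test_that("overcrowded scenes are rejected with a clear error", {
  p <- scene_params("Strong", image_size = 16, n_peaks_range = c(60L, 60L),
                    peak_amplitude_range = c(9, 14), ring_amplitude = 1,
                    seed = 1)
  expect_error(simulate_frame(p), "overcrowded")
})

test_that("mean intensity increases Weak -> Good -> Strong at matched peak count", {
  # same peak count and seed per class; only the amplitude range differs
  means <- vapply(c("Weak", "Good", "Strong"), function(cl) {
    p <- scene_params(cl, n_peaks_range = c(8L, 8L),
                      peak_amplitude_range = switch(cl, Weak = c(2, 4),
                                                    Good = c(5, 8),
                                                    Strong = c(9, 14)),
                      ring_amplitude = 1, noise_sigma = 0, seed = 77)
    mean(simulate_frame(p)$pixels)
  }, numeric(1))
  expect_true(means["Weak"] < means["Good"])
  expect_true(means["Good"] < means["Strong"])
})

test_that("default class parameters have strictly ordered amplitude floors", {
  p <- default_scene_params()
  lows <- vapply(p[c("Weak", "Good", "Strong")],
                 function(q) q$peak_amplitude_range[1], numeric(1))
  expect_true(all(diff(lows) > 0))
  expect_equal(p$Blank$ring_amplitude, 0)
  expect_gt(p$NoCrystal$ring_amplitude, 0)
  expect_identical(p$Blank$n_peaks_range, c(0L, 0L))
  expect_identical(p$NoCrystal$n_peaks_range, c(0L, 0L))
})

test_that("generate_dataset produces stratified counts and a disjoint split", {
  ds <- generate_dataset(10, default_scene_params(), seed = 3,
                         test_fraction = 0.2)
  expect_length(ds$frames, 50)
  expect_true(all(table(ds$labels) == 10))
  expect_equal(sum(ds$split == "test"), 10)
  expect_true(all(table(ds$labels, ds$split)[, "test"] == 2))
  # peaks present exactly on the three hit classes
  has_peaks <- vapply(ds$frames, function(f) nrow(f$peaks) > 0, logical(1))
  expect_identical(has_peaks,
                   as.character(ds$labels) %in% c("Weak", "Good", "Strong"))
  # determinism of the split and frames
  ds2 <- generate_dataset(10, default_scene_params(), seed = 3,
                          test_fraction = 0.2)
  expect_identical(ds$split, ds2$split)
  expect_identical(ds$frames[[17]]$pixels, ds2$frames[[17]]$pixels)
  # a different seed changes pixel content but not the structure
  ds3 <- generate_dataset(10, default_scene_params(), seed = 4,
                          test_fraction = 0.2)
  expect_identical(ds$labels, ds3$labels)
  expect_false(identical(ds$frames[[17]]$pixels, ds3$frames[[17]]$pixels))
})

test_that("binarize_labels merges the two background classes into miss", {
  ds <- generate_dataset(4, default_scene_params(), seed = 8)
  ds <- binarize_labels(ds)
  expected <- ifelse(ds$labels %in% c("Blank", "NoCrystal"), "miss", "hit")
  expect_identical(as.character(ds$binary), expected)
  expect_equal(sum(ds$binary == "hit"),
               sum(ds$labels %in% c("Weak", "Good", "Strong")))
  # the five-class labels survive
  expect_identical(levels(ds$labels), sfx_classes)
})

test_that("peak masks are exact Euclidean discs around planted centres", {
  p <- scene_params("Weak", image_size = 24, n_peaks_range = c(1L, 1L),
                    peak_amplitude_range = c(2, 2), ring_amplitude = 1,
                    noise_sigma = 0, seed = 5)
  f <- simulate_frame(p)
  ctr <- c(f$peaks$row[1], f$peaks$col[1])
  m2 <- peak_mask(f, 2)
  for (i in seq_len(24)) for (j in seq_len(24)) {
    d <- sqrt((i - ctr[1])^2 + (j - ctr[2])^2)
    expect_identical(m2[i, j], d <= 2)
  }
  m0 <- peak_mask(f, 0)
  expect_equal(sum(m0), 1)
  expect_true(m0[ctr[1], ctr[2]])
  # k well-separated peaks cover k times the single-disc area
  p3 <- scene_params("Strong", image_size = 64, n_peaks_range = c(3L, 3L),
                     peak_amplitude_range = c(9, 14), ring_amplitude = 1,
                     noise_sigma = 0, min_sep_factor = 12, seed = 6)
  f3 <- simulate_frame(p3)
  expect_equal(sum(peak_mask(f3, 2)), 3 * sum(m2))
  # miss frames cannot be masked
  expect_error(peak_mask(simulate_frame(scene_params("Blank", seed = 1))),
               "no ground-truth peaks")
})

test_that("local-maxima thresholding separates hit from miss perfectly without noise", {
  scenes <- noise_free_scenes(48)
  set.seed(12)
  labels <- c(); counts <- c()
  for (cl in sfx_classes) {
    p <- scenes[[cl]]
    p$seed <- NULL
    for (r in 1:6) {
      f <- simulate_frame(p)
      labels <- c(labels, cl)
      counts <- c(counts, count_local_maxima(f$pixels, 1.8))
    }
  }
  is_hit <- labels %in% c("Weak", "Good", "Strong")
  expect_true(all(counts[is_hit] >= 1))
  expect_true(all(counts[!is_hit] == 0))
})
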