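test_that("score gradient through a GAP head is the constant 1/(h*w)", {
  m <- gap_toy_model(seed = 2, filters = 1L, input_size = 6L)
  m$units[[3]]$W <- matrix(c(1, -1), 2, 1)  # head reads the single map
  x <- array(abs(rnorm(36)), c(6, 6, 1))
  g <- score_gradients(m, x, 1, "conv1", preprocess = FALSE)
  expect_equal(as.numeric(g), rep(1 / 36, 36))
  # maps feeding only the other class get zero gradient under a
  # block-diagonal head
  m2 <- gap_toy_model(seed = 2, filters = 2L, input_size = 6L)
  m2$units[[3]]$W <- matrix(c(1, 0,
                              0, 1), 2, 2, byrow = TRUE)
  g2 <- score_gradients(m2, x, 1, "conv1", preprocess = FALSE)
  expect_true(all(g2[, , 2] == 0))
  expect_true(all(g2[, , 1] != 0))
})

test_that("neuron importance is the spatial mean of the gradients", {
  g <- array(0, c(2, 2, 1))
  g[, , 1] <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-wise
  expect_equal(neuron_importance(g), 2.5)
  expect_equal(neuron_importance(array(1, c(5, 7, 3))), rep(1, 3))
  set.seed(4)
  gr <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  brute <- vapply(1:6, function(k) sum(gr[, , k]) / 20, numeric(1))
  expect_equal(neuron_importance(gr), brute)
})

test_that("the weighted-map combination is ReLU-clipped and cancels correctly", {
  # direct check of the map algebra on constructed activations
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(1, 0, -1, 2), 2, 2)
  A[, , 2] <- A[, , 1]
  alpha <- c(1, -1)
  raw <- matrix(0, 2, 2)
  for (k in 1:2) raw <- raw + alpha[k] * A[, , k]
  expect_true(all(pmax(raw, 0) == 0))  # exact cancellation
  expect_equal(pmax(pmax(A[, , 1], 0) * 1, 0),
               pmax(matrix(c(1, 0, 0, 2), 2, 2), 0))
})

test_that("Grad-CAM equals CAM exactly on a GAP-head network", {
  m <- gap_toy_model(seed = 6, filters = 4L, input_size = 8L)
  set.seed(7)
  x <- array(rnorm(64), c(8, 8, 1))
  for (cls in 1:2) {
    g <- gradcam(m, x, class_index = cls, layer = "conv1",
                 preprocess = FALSE)
    # CAM from the head weights: sum_k w_ck A^k / (h*w), ReLU-clipped
    A <- activations(m, x, "conv1", preprocess = FALSE)
    cam <- matrix(0, 8, 8)
    for (k in 1:4) cam <- cam + m$units[[3]]$W[cls, k] * A[, , k] / 64
    cam <- pmax(cam, 0)
    expect_equal(g$raw_map, cam, tolerance = 1e-12)
  }
})

test_that("heat maps are non-negative, normalized, and zero-safe", {
  m <- tiny_model(seed = 9, n_classes = 3)
  set.seed(10)
  for (r in 1:100) {
    x <- matrix(rnorm(256, sd = runif(1, 0.1, 3)), 16, 16)
    g <- gradcam(m, x)
    expect_true(all(g$raw_map >= 0))
    expect_true(all(g$heatmap >= 0 & g$heatmap <= 1))
    expect_equal(dim(g$heatmap), c(16, 16))
  }
  # an identically zero raw map yields an identically zero heat map
  mz <- gap_toy_model(seed = 1, filters = 1L, input_size = 6L)
  mz$units[[3]]$W <- matrix(c(-1, 1), 2, 1)  # class 1 importance negative
  mz$units[[1]]$b <- 5  # keep activations positive
  g0 <- gradcam(mz, matrix(abs(rnorm(36)), 6, 6), class_index = 1,
                layer = "conv1")
  expect_true(all(g0$raw_map == 0))
  expect_true(all(g0$heatmap == 0))
})

test_that("guided backprop masks by forward sign and gradient sign", {
  # elementwise ReLU backward rule
  expect_equal(sfxsight:::relu_backward(5, -1, "guided"), 0)
  expect_equal(sfxsight:::relu_backward(-2, 1, "guided"), 0)
  expect_equal(sfxsight:::relu_backward(2, 1, "guided"), 2)
  expect_equal(sfxsight:::relu_backward(-2, 1, "normal"), -2)
  # through a 1-filter identity conv + ReLU with a fixed GAP head
  m <- gap_toy_model(seed = 1, filters = 1L, input_size = 2L)
  m$units[[1]]$W <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 1, 9)  # identity conv
  m$units[[3]]$W <- matrix(c(1, -1), 2, 1)
  # forward pre-activation negative everywhere -> guided gradient all zero
  xneg <- array(-1, c(2, 2, 1))
  gneg <- guided_backprop(m, xneg, class_index = 1, preprocess = FALSE)
  expect_true(all(gneg == 0))
  # positive activations but negative upstream gradient (class 2 head weight
  # is -1) -> masked to 0
  xpos <- array(1, c(2, 2, 1))
  g2 <- guided_backprop(m, xpos, class_index = 2, preprocess = FALSE)
  expect_true(all(g2 == 0))
  # positive activations and positive gradients -> equals the plain gradient
  g1 <- guided_backprop(m, xpos, class_index = 1, preprocess = FALSE)
  fp <- sfxsight:::forward_pass(m, xpos)
  bp <- sfxsight:::backward_pass(m, fp, c(1, 0))
  expect_equal(g1, apply(bp$dinput, c(1, 2), sum))
})

test_that("guided Grad-CAM is the elementwise product with shape checking", {
  m <- tiny_model(seed = 9, n_classes = 3)
  x <- matrix(runif(256), 16, 16)
  g <- gradcam(m, x)
  gb <- guided_backprop(m, x)
  gg <- guided_gradcam(g, gb)
  # loop-based oracle
  for (i in sample(256, 30)) expect_equal(gg[i], g$heatmap[i] * gb[i])
  g0 <- g
  g0$heatmap <- g$heatmap * 0
  expect_true(all(guided_gradcam(g0, gb) == 0))
  g1 <- g
  g1$heatmap <- g$heatmap * 0 + 1
  expect_equal(guided_gradcam(g1, gb), gb)
  expect_error(guided_gradcam(g, gb[1:8, 1:8]), "mismatch")
})

test_that("activation histograms conserve counts and match brute-force binning", {
  h <- activation_histogram(matrix(3.3, 5, 5), 10)
  expect_equal(sum(h$counts), 25)
  expect_equal(sum(h$counts > 0), 1)
  set.seed(5)
  v <- matrix(rnorm(400), 20, 20)
  h2 <- activation_histogram(v, 16)
  expect_equal(sum(h2$counts), 400)
  brute <- integer(16)
  for (x in as.numeric(v)) {
    b <- min(max(1L, findInterval(x, h2$edges, rightmost.closed = TRUE)), 16L)
    brute[b] <- brute[b] + 1L
  }
  expect_equal(h2$counts, brute)
})

test_that("localization score is the masked heat fraction", {
  heat <- matrix(0, 10, 10)
  mask <- matrix(FALSE, 10, 10)
  mask[3:5, 3:5] <- TRUE
  heat[4, 4] <- 2
  expect_equal(localization_score(heat, mask), 1)
  uniform <- matrix(1, 10, 10)
  expect_equal(localization_score(uniform, mask), mean(mask))
  set.seed(6)
  r <- matrix(runif(100), 10, 10)
  expect_equal(localization_score(r, mask), sum(r[mask]) / sum(r))
  expect_warning(z <- localization_score(matrix(0, 10, 10), mask), "undefined")
  expect_true(is.na(z))
})
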