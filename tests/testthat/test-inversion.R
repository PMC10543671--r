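test_that("alpha-norm prior matches its closed form", {
  expect_equal(alpha_norm_prior(matrix(7, 4, 4), 6), 0)
  expect_equal(alpha_norm_prior(c(1, -1), 6), 2)
  set.seed(1)
  x <- matrix(rnorm(30), 5, 6)
  a <- 6
  loop <- 0
  m <- mean(x)
  for (v in as.numeric(x)) loop <- loop + abs(v - m)^a
  expect_equal(alpha_norm_prior(x, a), loop)
})

test_that("total-variation prior matches hand evaluation and its beta=2 form", {
  expect_equal(tv_prior(matrix(5, 3, 3), 1), 0)
  # [[0,1],[0,1]]: two horizontal unit steps, no vertical steps
  x <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(tv_prior(x, 1), 2)
  set.seed(2)
  y <- matrix(rnorm(42), 6, 7)
  # beta = 2 reduces to the sum of squared forward differences
  loop <- 0
  for (i in 1:6) for (j in 1:7) {
    dh <- if (j < 7) y[i, j + 1] - y[i, j] else 0
    dv <- if (i < 6) y[i + 1, j] - y[i, j] else 0
    loop <- loop + dh^2 + dv^2
  }
  expect_equal(tv_prior(y, 2), loop)
  # generic beta against a loop oracle
  loop1 <- 0
  for (i in 1:6) for (j in 1:7) {
    dh <- if (j < 7) y[i, j + 1] - y[i, j] else 0
    dv <- if (i < 6) y[i + 1, j] - y[i, j] else 0
    loop1 <- loop1 + (dh^2 + dv^2)^(0.5)
  }
  expect_equal(tv_prior(y, 1), loop1)
})

test_that("prior gradients agree with finite differences", {
  set.seed(3)
  x <- matrix(rnorm(25), 5, 5)
  ga <- sfxsight:::alpha_norm_grad(x, 6)
  gt <- sfxsight:::tv_grad(x, 1)
  for (idx in sample(25, 10)) {
    h <- 1e-6
    xp <- x; xp[idx] <- xp[idx] + h
    xm <- x; xm[idx] <- xm[idx] - h
    expect_equal(ga[idx],
                 (alpha_norm_prior(xp, 6) - alpha_norm_prior(xm, 6)) / (2 * h),
                 tolerance = 1e-4)
    expect_equal(gt[idx], (tv_prior(xp, 1) - tv_prior(xm, 1)) / (2 * h),
                 tolerance = 1e-3)
  }
})

test_that("representation distance is normalized squared Euclidean", {
  m <- tiny_model(seed = 4)
  set.seed(5)
  x <- array(rnorm(256), c(16, 16, 1))
  phi0 <- activations(m, x, "conv2", preprocess = FALSE)
  expect_equal(rep_distance(m, x, phi0, "conv2"), 0)
  # identity layer: doubling the representation gives exactly 1
  expect_equal(rep_distance(m, 2 * x, x, "input"), 1)
  # random pair against a loop-based sum of squares
  y <- array(rnorm(256), c(16, 16, 1))
  phiy <- activations(m, y, "conv2", preprocess = FALSE)
  loop <- sum((as.numeric(phiy) - as.numeric(phi0))^2)
  expect_equal(rep_distance(m, y, phi0, "conv2"), loop / sum(phi0^2))
  expect_error(rep_distance(m, x, phi0[, , 1:2], "conv2"), "mismatch")
})

test_that("identity-layer inversion with zero priors recovers the original", {
  set.seed(6)
  x0 <- matrix(rnorm(64), 8, 8)
  cfg <- inversion_config("input", lambda_alpha = 0, lambda_tv = 0,
                          sigma = 1, iterations = 250, step_size = 0.3,
                          momentum = 0.9, seed = 11)
  r <- invert(NULL, x0, cfg)
  expect_lt(r$final_rep_distance, 1e-3)
  expect_lt(max(abs(r$x_star - x0)), 0.05 * diff(range(x0)))
  # determinism: identical config and seed reproduce the result exactly
  r2 <- invert(NULL, x0, cfg)
  expect_identical(r$x_star, r2$x_star)
  expect_identical(r$loss_trace, r2$loss_trace)
})

test_that("loss traces are finite, componentwise consistent, and bookkept", {
  m <- tiny_model(seed = 8)
  set.seed(9)
  x0 <- array(abs(rnorm(256)), c(16, 16, 1))
  phi0 <- activations(m, x0, "conv3", preprocess = FALSE)
  cfg <- inversion_config("conv3", lambda_alpha = 1e-4, lambda_tv = 1e-3,
                          sigma = 1, iterations = 40, step_size = 0.05,
                          optimizer = "adam", seed = 13)
  r <- invert(m, phi0, cfg)
  tr <- r$loss_trace
  expect_true(all(is.finite(tr$total)))
  expect_true(all(tr$rep >= 0 & tr$alpha >= 0 & tr$tv >= 0))
  expect_equal(tr$total, tr$rep + 1e-4 * tr$alpha + 1e-3 * tr$tv)
  # the returned iterate attains the best recorded total
  expect_lte(r$final_rep_distance, max(tr$rep))
  expect_true(all(diff(cummin(tr$total)) <= 0))
})

test_that("a heavier TV weight always ends with a smoother reconstruction", {
  m <- tiny_model(seed = 10)
  set.seed(14)
  x0 <- array(abs(rnorm(256)), c(16, 16, 1))
  phi0 <- activations(m, x0, "conv1", preprocess = FALSE)
  tvs <- vapply(c(0, 1e-3, 1e-1, 10), function(lam) {
    cfg <- inversion_config("conv1", lambda_alpha = 0, lambda_tv = lam,
                            sigma = 1, iterations = 80, step_size = 0.05,
                            optimizer = "adam", seed = 15)
    r <- invert(m, phi0, cfg)
    tv_prior(r$x_star[, , 1], 1)
  }, numeric(1))
  expect_true(all(diff(tvs) < 0))
})

test_that("early layers invert more faithfully than late layers", {
  m <- memoize("inv_model", function() build_model(desk_alexnet_spec(5, 32), seed = 16))
  scenes <- default_scene_params(32, noise_sigma = 0.3)
  scenes$Strong$n_peaks_range <- c(6L, 10L)  # fits the smaller frame
  set.seed(17)
  cors <- matrix(NA_real_, 10, 2, dimnames = list(NULL, c("conv1", "conv5")))
  for (f in 1:10) {
    p <- scenes$Strong
    frame <- simulate_frame(p)
    sig <- sqrt(sum(preprocess_frame(m, frame)[, , 1]^2))
    cfg <- inversion_config("input", sigma = sig, iterations = 60,
                            optimizer = "adam", step_size = 0.05,
                            seed = 100 + f)
    res <- invert_per_layer(m, frame, c("conv1", "conv5"), cfg)
    x0 <- preprocess_frame(m, frame)[, , 1]
    cors[f, ] <- vapply(res, function(r)
      cor(as.numeric(r$x_star[, , 1]), as.numeric(x0)), numeric(1))
  }
  expect_gt(mean(cors[, "conv1"]), mean(cors[, "conv5"]))
  # single-layer call returns a single result
  one <- invert_per_layer(m, simulate_frame(scenes$Strong), "conv2",
                          inversion_config("input", sigma = 30,
                                           iterations = 5, optimizer = "adam"))
  expect_length(one, 1)
  expect_s3_class(one$conv2, "sfx_inversion")
})
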