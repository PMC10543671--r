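#' Configuration for layer-representation inversion
#'
#' Settings for reconstructing an input-like image from a layer's
#' activations by minimizing
#' `||Phi(sigma * x) - Phi_0||^2 / ||Phi_0||^2
#'  + lambda_alpha * R_alpha(x) + lambda_tv * R_TV(x)`
#' over `x`, starting from seeded random noise. `R_alpha` is the alpha-norm
#' of the mean-subtracted image (narrow pixel spread); `R_TV` is the total
#' variation with exponent `beta` (neighbouring pixels alike; `beta = 1`
#' is the study setting). The scaling `sigma` is the average Euclidean norm
#' of training images, so the optimization variable stays in a natural
#' O(1) range while the network sees natural-intensity inputs.
#'
#' @param layer layer name whose representation is matched; the special
#'   value `"input"` makes `Phi` the identity (useful for closed-form
#'   checks).
#' @param lambda_alpha weight of the alpha-norm prior.
#' @param alpha_exponent exponent alpha (>= 1; default 6).
#' @param lambda_tv weight of the total-variation prior.
#' @param beta TV exponent (> 0; default 1).
#' @param sigma scaling; average Euclidean norm of training images
#'   (see [mean_image_norm()]).
#' @param iterations gradient steps.
#' @param step_size learning rate.
#' @param momentum momentum factor (gradient descent optimizer).
#' @param optimizer `"momentum"` (with step decay x0.5 every
#'   `ceil(iterations/3)`) or `"adam"`.
#' @param clip_mult if non-`NULL`, clip pixels each iteration to
#'   `clip_mult` times the RMS pixel value implied by `sigma`; `NULL`
#'   (default) leaves the reconstruction unconstrained, since sparse
#'   diffraction peaks legitimately exceed any small multiple of the RMS.
#' @param seed seed for the random-noise initialization.
#' @return an `sfx_invconfig`.
#' @export
inversion_config <- function(layer, lambda_alpha = 1e-5, alpha_exponent = 6,
                             lambda_tv = 1e-3, beta = 1, sigma = 1,
                             iterations = 200, step_size = 0.05,
                             momentum = 0.9,
                             optimizer = c("momentum", "adam"),
                             clip_mult = NULL, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(sigma > 0, iterations >= 1, beta > 0, alpha_exponent >= 1,
            lambda_alpha >= 0, lambda_tv >= 0, step_size > 0,
            momentum >= 0, momentum < 1)
  structure(list(layer = layer, lambda_alpha = lambda_alpha,
                 alpha_exponent = alpha_exponent, lambda_tv = lambda_tv,
                 beta = beta, sigma = sigma, iterations = as.integer(iterations),
                 step_size = step_size, momentum = momentum,
                 optimizer = optimizer, clip_mult = clip_mult,
                 seed = as.integer(seed)),
            class = "sfx_invconfig")
}

#' Average Euclidean norm of training images
#'
#' The `sigma` scaling of the inversion objective, computed over the
#' preprocessed train-split inputs of a dataset.
#'
#' @param model an `sfx_model` (for the preprocessing contract).
#' @param dataset an `sfx_dataset`.
#' @return positive scalar.
#' @export
mean_image_norm <- function(model, dataset) {
  tr <- which(dataset$split == "train")
  if (length(tr) == 0) tr <- seq_along(dataset$frames)
  mean(vapply(tr, function(i)
    sqrt(sum(preprocess_frame(model, dataset$frames[[i]])[, , 1]^2)),
    numeric(1)))
}

#' Normalized Euclidean representation distance
#'
#' `||Phi(x) - Phi_0||^2 / ||Phi_0||^2` over all feature-map entries of
#' the chosen layer.
#'
#' @param model an `sfx_model`.
#' @param x input array (already preprocessed / in network input space).
#' @param phi0 reference representation from the original image.
#' @param layer layer name (or `"input"` for the identity map).
#' @return non-negative scalar.
#' @export
rep_distance <- function(model, x, phi0, layer) {
  phi <- if (identical(layer, "input")) x
         else activations(model, x, layer, preprocess = FALSE)
  if (length(phi) != length(phi0))
    stop("representation shape mismatch at layer '", layer, "'")
  sum((phi - phi0)^2) / sum(phi0^2)
}

#' Alpha-norm image prior
#'
#' `R_alpha(x) = sum_i |x_i - mean(x)|^alpha` on the vectorized,
#' mean-subtracted image; favours a narrow spread of pixel values.
#'
#' @param x numeric array.
#' @param alpha_exponent exponent alpha.
#' @return non-negative scalar.
#' @export
alpha_norm_prior <- function(x, alpha_exponent = 6) {
  v <- as.numeric(x) - mean(x)
  sum(abs(v)^alpha_exponent)
}

alpha_norm_grad <- function(x, alpha_exponent) {
  v <- x - mean(x)
  g <- alpha_exponent * abs(v)^(alpha_exponent - 1) * sign(v)
  g - mean(g)  # chain rule through the subtracted mean
}

#' Total-variation image prior
#'
#' `R_TV(x) = sum_ij ((x[i, j+1] - x[i, j])^2 +
#' (x[i+1, j] - x[i, j])^2)^(beta/2)` with forward differences treated as
#' zero at the image boundary; favours images whose neighbouring pixels
#' have similar values.
#'
#' @param x numeric matrix.
#' @param beta exponent (the study uses `beta = 1`).
#' @return non-negative scalar.
#' @export
tv_prior <- function(x, beta = 1) {
  stopifnot(is.matrix(x))
  dh <- cbind(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE], 0)
  dv <- rbind(x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE], 0)
  sum((dh^2 + dv^2)^(beta / 2))
}

tv_grad <- function(x, beta, eps = 1e-8) {
  h <- nrow(x); w <- ncol(x)
  dh <- cbind(x[, -1, drop = FALSE] - x[, -w, drop = FALSE], 0)
  dv <- rbind(x[-1, , drop = FALSE] - x[-h, , drop = FALSE], 0)
  e <- beta * (dh^2 + dv^2 + eps)^(beta / 2 - 1)
  gh <- e * dh  # d/d(dh); dh[i,j] couples x[i,j+1] (+) and x[i,j] (-)
  gv <- e * dv
  g <- -gh - gv
  g[, -1] <- g[, -1] + gh[, -w]
  g[-1, ] <- g[-1, ] + gv[-h, ]
  g
}

#' Invert a layer representation
#'
#' Reconstructs an image from a reference representation `phi0` by
#' first-order minimization of the inversion objective, starting from
#' seeded Gaussian noise. Records the total objective and its three
#' components every iteration and returns the best-loss iterate.
#'
#' @param model an `sfx_model` (ignored when `cfg$layer == "input"`).
#' @param phi0 reference representation (from [activations()] on the
#'   original preprocessed frame, or the frame itself for `"input"`).
#' @param cfg an `sfx_invconfig`.
#' @return an `sfx_inversion`: list with `x_star` (reconstruction in
#'   network input space, i.e. `sigma * x`), `loss_trace` (data.frame of
#'   per-iteration `total`, `rep`, `alpha`, `tv`) and
#'   `final_rep_distance`.
#' @export
invert <- function(model, phi0, cfg) {
  stopifnot(inherits(cfg, "sfx_invconfig"))
  dims <- if (identical(cfg$layer, "input")) dim(phi0) %||% c(length(phi0), 1)
          else c(model$spec$input_size, model$spec$input_size,
                 model$spec$in_channels)
  if (identical(cfg$layer, "input") && is.null(dim(phi0)))
    phi0 <- matrix(phi0)
  set.seed(cfg$seed)
  x <- array(rnorm(prod(dims), 0, 0.1), dims)
  vel <- x * 0
  m_a <- x * 0; v_a <- x * 0  # adam state
  decay_every <- ceiling(cfg$iterations / 3)
  clip <- if (!is.null(cfg$clip_mult))
    cfg$clip_mult * cfg$sigma / sqrt(prod(dims[1:2])) else NULL

  objective <- function(x) {
    xin <- cfg$sigma * x
    if (identical(cfg$layer, "input")) {
      phi <- xin
      l_rep <- sum((phi - phi0)^2) / sum(phi0^2)
      g_rep <- 2 * cfg$sigma * (phi - phi0) / sum(phi0^2)
    } else {
      fp <- forward_pass(model, xin)
      phi <- fp$acts[[cfg$layer]]
      diffp <- phi - phi0
      l_rep <- sum(diffp^2) / sum(phi0^2)
      bp <- backward_pass(model, fp, 2 * diffp / sum(phi0^2),
                          from_layer = cfg$layer)
      g_rep <- cfg$sigma * bp$dinput
    }
    x2d <- if (length(dims) == 3) x[, , 1] else x
    l_a <- alpha_norm_prior(x, cfg$alpha_exponent)
    l_tv <- tv_prior(x2d, cfg$beta)
    g <- g_rep + cfg$lambda_alpha * alpha_norm_grad(x, cfg$alpha_exponent)
    gtv <- cfg$lambda_tv * tv_grad(x2d, cfg$beta)
    if (length(dims) == 3) {
      g[, , 1] <- g[, , 1] + gtv
    } else {
      g <- g + gtv
    }
    total <- l_rep + cfg$lambda_alpha * l_a + cfg$lambda_tv * l_tv
    if (!is.finite(total)) {
      comp <- c(rep = l_rep, alpha = l_a, tv = l_tv)
      stop("non-finite inversion objective (",
           paste(names(comp)[!is.finite(comp)], collapse = ", "),
           " component diverged)")
    }
    list(total = total, rep = l_rep, alpha = l_a, tv = l_tv, grad = g)
  }

  trace <- data.frame(iter = integer(0), total = numeric(0),
                      rep = numeric(0), alpha = numeric(0), tv = numeric(0))
  best <- NULL
  lr <- cfg$step_size
  for (it in seq_len(cfg$iterations)) {
    if (cfg$optimizer == "momentum" && it > 1 && (it - 1) %% decay_every == 0)
      lr <- lr * 0.5
    o <- objective(x)
    trace <- rbind(trace, data.frame(iter = it, total = o$total, rep = o$rep,
                                     alpha = o$alpha, tv = o$tv))
    if (is.null(best) || o$total < best$total)
      best <- list(total = o$total, rep = o$rep, x = x)
    if (cfg$optimizer == "momentum") {
      vel <- cfg$momentum * vel - lr * o$grad
      x <- x + vel
    } else {
      m_a <- 0.9 * m_a + 0.1 * o$grad
      v_a <- 0.999 * v_a + 0.001 * o$grad^2
      x <- x - lr * (m_a / (1 - 0.9^it)) /
        (sqrt(v_a / (1 - 0.999^it)) + 1e-8)
    }
    if (!is.null(clip)) x <- pmin(pmax(x, -clip), clip)
  }
  o <- objective(x)
  if (o$total < best$total) best <- list(total = o$total, rep = o$rep, x = x)
  structure(list(x_star = cfg$sigma * best$x, loss_trace = trace,
                 final_rep_distance = best$rep, config = cfg),
            class = "sfx_inversion")
}

#' Invert a frame's representation at several layers
#'
#' Runs [invert()] once per layer with a shared seed, matching each
#' layer's representation of the same (preprocessed) frame.
#'
#' @param model an `sfx_model`.
#' @param frame an `sfx_frame` or H x W matrix.
#' @param layers character vector of layer names.
#' @param cfg an `sfx_invconfig`; its `layer` and `sigma` fields are set
#'   per call (`sigma` is kept as given).
#' @return named list of `sfx_inversion` results, one per layer.
#' @export
invert_per_layer <- function(model, frame, layers = conv_layer_names(model),
                             cfg = inversion_config("input")) {
  input <- preprocess_frame(model, frame)
  out <- list()
  for (ly in layers) {
    phi0 <- activations(model, input, ly, preprocess = FALSE)
    cfg_l <- cfg
    cfg_l$layer <- ly
    out[[ly]] <- invert(model, phi0, cfg_l)
  }
  out
}
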