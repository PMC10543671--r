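#' Configuration for the full explainability study
#'
#' One document describing every stage: synthetic data generation, network
#' architecture, training, spot finding, Grad-CAM explanation and
#' representation inversion. Fully serializable to/from YAML with a stable
#' round trip ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' Stage seeds are derived from `seed` by fixed offsets (data +1, split,
#' model init +2, training +3, explanation sampling +4, inversion +5), so
#' one global seed reproduces the whole study.
#'
#' @param seed global seed.
#' @param n_per_class training-set frames per class.
#' @param image_size frame side length in pixels.
#' @param noise_sigma detector Gaussian noise level.
#' @param arch `"alexnet_style"` or `"resnet_style"`.
#' @param epochs,batch_size,lr_init,lr_decay training hyperparameters
#'   (see [train_config()]).
#' @param spot named list of [spot_params()] arguments.
#' @param explain_frames number of test frames per class used for
#'   Grad-CAM scoring.
#' @param mask_radius peak-mask dilation radius in pixels.
#' @param inversion_iterations gradient steps per layer inversion.
#' @param out_dir output directory for artifacts and the JSON report.
#' @return an `sfx_pipelineconfig` (nested list).
#' @export
pipeline_config <- function(seed = 1L, n_per_class = 500, image_size = 64,
                            noise_sigma = 0.3, arch = "alexnet_style",
                            epochs = 15, batch_size = 32, lr_init = 1e-3,
                            lr_decay = 0.95,
                            spot = list(n_min = 2, n_max = 400, n_peaks = 3,
                                        snr_min = 3),
                            explain_frames = 20, mask_radius = 3,
                            inversion_iterations = 150,
                            out_dir = "sfx_study") {
  structure(list(seed = as.integer(seed),
                 data = list(n_per_class = as.integer(n_per_class),
                             image_size = as.integer(image_size),
                             noise_sigma = noise_sigma,
                             test_fraction = 0.2),
                 network = list(arch = arch),
                 training = list(epochs = as.integer(epochs),
                                 batch_size = as.integer(batch_size),
                                 lr_init = lr_init, lr_decay = lr_decay),
                 spot = spot,
                 explain = list(frames_per_class = as.integer(explain_frames),
                                mask_radius = mask_radius),
                 inversion = list(iterations = as.integer(inversion_iterations)),
                 out_dir = out_dir),
            class = "sfx_pipelineconfig")
}

#' @rdname pipeline_config
#' @param cfg an `sfx_pipelineconfig`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- cfg
  class(x) <- NULL
  atomic_write(function(tmp) yaml::write_yaml(x, tmp), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "sfx_pipelineconfig")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full explainability study
#'
#' Executes the pipeline end to end: simulate a labelled synthetic dataset;
#' train a five-class classifier and a hit/miss classifier; evaluate both
#' (confusion matrix with per-class recall/precision, and a hit/miss
#' cross-tabulation of the CNN and the classical spot finder against
#' ground truth); score Grad-CAM explanations (localization on ground-truth
#' peak masks, activation totals per class, Blank-vs-Strong activation
#' histograms); and invert each convolutional layer's representation of a
#' sample frame. All artifacts plus a machine-readable JSON report are
#' written under `cfg$out_dir`; any stage failure halts with the stage
#' name after persisting partial results.
#'
#' @param cfg an `sfx_pipelineconfig`.
#' @param write_pngs also write heat-map / inversion PNG panels.
#' @param verbose print stage progress.
#' @return the report (nested list), invisibly; also written as
#'   `report.json`.
#' @export
run_study <- function(cfg = pipeline_config(), write_pngs = TRUE,
                      verbose = TRUE) {
  stopifnot(inherits(cfg, "sfx_pipelineconfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = unclass(cfg))
  persist <- function() {
    atomic_write(function(tmp)
      jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE),
      file.path(cfg$out_dir, "report.json"))
  }
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  persist()  # effective config is on disk even if the first stage fails

  # -- simulate ---------------------------------------------------------------
  say("stage simulate ...")
  ds <- run_stage("simulate", {
    scenes <- default_scene_params(cfg$data$image_size, cfg$data$noise_sigma)
    n_total <- round(cfg$data$n_per_class / (1 - cfg$data$test_fraction))
    generate_dataset(n_total, scenes, seed = derive_seed(cfg$seed, 1),
                     test_fraction = cfg$data$test_fraction)
  })
  ds <- binarize_labels(ds)
  report$simulate <- list(
    n_frames = length(ds$frames),
    n_train = sum(ds$split == "train"), n_test = sum(ds$split == "test"),
    class_counts = as.list(table(ds$labels)),
    mean_intensity_by_class = lapply(split(
      vapply(ds$frames, function(f) mean(f$pixels), 1), ds$labels), mean))
  persist()

  # -- train ------------------------------------------------------------------
  say("stage train (five-class) ...")
  tc <- train_config(epochs = cfg$training$epochs,
                     batch_size = cfg$training$batch_size,
                     lr_init = cfg$training$lr_init,
                     lr_decay = cfg$training$lr_decay,
                     seed = derive_seed(cfg$seed, 3))
  fit5 <- run_stage("train", {
    spec <- if (cfg$network$arch == "alexnet_style")
      desk_alexnet_spec(5, cfg$data$image_size)
    else desk_resnet_spec(5, cfg$data$image_size)
    train(build_model(spec, seed = derive_seed(cfg$seed, 2)), ds, tc,
          target = "multiclass", verbose = verbose)
  })
  say("stage train (hit/miss) ...")
  fit2 <- run_stage("train", {
    spec <- if (cfg$network$arch == "alexnet_style")
      desk_alexnet_spec(2, cfg$data$image_size)
    else desk_resnet_spec(2, cfg$data$image_size)
    train(build_model(spec, seed = derive_seed(cfg$seed, 2)), ds, tc,
          target = "binary", verbose = verbose)
  })
  utils::write.csv(fit5$history,
                   file.path(cfg$out_dir, "history_multiclass.csv"),
                   row.names = FALSE)
  utils::write.csv(fit2$history, file.path(cfg$out_dir, "history_binary.csv"),
                   row.names = FALSE)
  report$train <- list(multiclass = as.list(fit5$history[nrow(fit5$history), ]),
                       binary = as.list(fit2$history[nrow(fit2$history), ]))
  persist()

  # -- evaluate ---------------------------------------------------------------
  say("stage evaluate ...")
  ev <- run_stage("evaluate", {
    te <- which(ds$split == "test")
    pred5 <- predict_frames(fit5$model, ds$frames[te])
    cm <- confusion(as.integer(ds$labels[te]), pred5$labels, 5, sfx_classes)
    pred2 <- predict_frames(fit2$model, ds$frames[te])
    cnn_binary <- sfx_binary_classes[pred2$labels]
    sp <- do.call(spot_params, cfg$spot)
    spot_binary <- vapply(ds$frames[te],
                          function(f) classify_hit(f, sp)$label, "")
    truth <- as.character(ds$binary[te])
    list(cm = cm,
         cnn_table = hit_miss_table(truth, cnn_binary),
         spot_table = hit_miss_table(truth, spot_binary))
  })
  utils::write.csv(metric_table(ev$cm),
                   file.path(cfg$out_dir, "confusion_multiclass.csv"))
  report$evaluate <- list(
    confusion = unclass(unname(as.matrix(ev$cm))),
    accuracy_pct = accuracy(ev$cm),
    recall_pct = as.list(round_half_up(per_class_recall(ev$cm), 1)),
    precision_pct = as.list(round_half_up(per_class_precision(ev$cm), 1)),
    cnn_hit_miss_rows_pct = unclass(ev$cnn_table),
    spotfinder_hit_miss_rows_pct = unclass(ev$spot_table))
  persist()

  # -- explain ----------------------------------------------------------------
  say("stage explain ...")
  ex <- run_stage("explain", {
    set.seed(derive_seed(cfg$seed, 4))
    te <- which(ds$split == "test")
    per_class <- lapply(sfx_classes, function(cl) {
      idx <- te[ds$labels[te] == cl]
      idx[seq_len(min(cfg$explain$frames_per_class, length(idx)))]
    })
    names(per_class) <- sfx_classes
    loc <- c(); area <- c(); heat_total <- setNames(numeric(5), sfx_classes)
    hist_blank <- NULL; hist_strong <- NULL
    for (cl in sfx_classes) {
      tot <- 0
      for (i in per_class[[cl]]) {
        g <- gradcam(fit2$model, ds$frames[[i]])
        tot <- tot + sum(g$raw_map)
        if (cl %in% c("Weak", "Good", "Strong")) {
          m <- peak_mask(ds$frames[[i]], cfg$explain$mask_radius)
          m <- bilinear_resize(m * 1, nrow(g$heatmap), ncol(g$heatmap)) > 0.5
          s <- localization_score(g$heatmap, m)
          if (!is.na(s)) { loc <- c(loc, s); area <- c(area, mean(m)) }
        }
      }
      heat_total[cl] <- tot / max(1, length(per_class[[cl]]))
      if (cl == "Blank")
        hist_blank <- activation_histogram(
          gradcam(fit2$model, ds$frames[[per_class[[cl]][1]]])$heatmap, 32)
      if (cl == "Strong") {
        i1 <- per_class[[cl]][1]
        g1 <- gradcam(fit2$model, ds$frames[[i1]])
        hist_strong <- activation_histogram(g1$heatmap, 32)
        if (write_pngs) {
          save_png(g1$overlay, file.path(cfg$out_dir, "gradcam_strong.png"))
          gb <- guided_backprop(fit2$model, ds$frames[[i1]])
          save_png(guided_gradcam(g1, gb),
                   file.path(cfg$out_dir, "guided_gradcam_strong.png"))
        }
      }
    }
    list(mean_localization = mean(loc), mean_mask_area = mean(area),
         n_scored = length(loc), heat_total_by_class = as.list(heat_total),
         histogram_blank = hist_blank, histogram_strong = hist_strong)
  })
  report$explain <- ex
  persist()

  # -- invert -----------------------------------------------------------------
  say("stage invert ...")
  inv <- run_stage("invert", {
    te <- which(ds$split == "test")
    strong_i <- te[ds$labels[te] == "Strong"][1]
    sigma <- mean_image_norm(fit5$model, ds)
    icfg <- inversion_config("input", sigma = sigma,
                             iterations = cfg$inversion$iterations,
                             optimizer = "adam", step_size = 0.05,
                             seed = derive_seed(cfg$seed, 5))
    res <- invert_per_layer(fit5$model, ds$frames[[strong_i]],
                            conv_layer_names(fit5$model), icfg)
    x0 <- preprocess_frame(fit5$model, ds$frames[[strong_i]])[, , 1]
    cors <- vapply(res, function(r)
      cor(as.numeric(r$x_star[, , 1]), as.numeric(x0)), 1)
    if (write_pngs) {
      panel <- do.call(cbind, c(list(x0), lapply(res, function(r) r$x_star[, , 1])))
      save_png(panel, file.path(cfg$out_dir, "inversion_panel.png"))
    }
    list(layers = names(res),
         pixel_correlation = as.list(cors),
         final_rep_distance = lapply(res, function(r) r$final_rep_distance))
  })
  report$invert <- inv
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  persist()
  say(sprintf("study complete in %.1f s; report at %s", report$wall_time_s,
              file.path(cfg$out_dir, "report.json")))
  invisible(report)
}
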