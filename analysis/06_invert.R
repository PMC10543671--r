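#!/usr/bin/env Rscript
# Stage 6: reconstruct frames from each convolutional layer's representation.
#
# Inverts conv1..conv5 of the trained five-class model for one Strong and
# one NoCrystal test frame (shared seed per frame), writes the panel of
# reconstructions next to the original, and tabulates the pixel correlation
# of each reconstruction with its input — the faithfulness-versus-depth
# trend.

library(sfxsight)

out <- "results"
dir.create(file.path(out, "invert"), showWarnings = FALSE)
ds <- read_frames(file.path(out, "data"))
fit5 <- load_model(file.path(out, "model_multiclass.ckpt"))
te <- which(ds$split == "test")
sigma <- mean_image_norm(fit5, ds)

rows <- list()
for (cl in c("Strong", "NoCrystal")) {
  i <- te[ds$labels[te] == cl][1]
  frame <- ds$frames[[i]]
  cfg <- inversion_config("input", sigma = sigma, iterations = 150,
                          optimizer = "adam", step_size = 0.05, seed = 7)
  res <- invert_per_layer(fit5, frame, conv_layer_names(fit5), cfg)
  x0 <- preprocess_frame(fit5, frame)[, , 1]
  panel <- do.call(cbind, c(list(x0),
                            lapply(res, function(r) r$x_star[, , 1])))
  save_png(panel, file.path(out, "invert",
                            sprintf("inversion_panel_%s.png", tolower(cl))))
  for (ly in names(res)) {
    rows[[length(rows) + 1]] <- data.frame(
      class = cl, layer = ly,
      pixel_correlation = cor(as.numeric(res[[ly]]$x_star[, , 1]),
                              as.numeric(x0)),
      final_rep_distance = res[[ly]]$final_rep_distance)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "invert", "inversion_summary.csv"),
          row.names = FALSE)
print(tab, row.names = FALSE)
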