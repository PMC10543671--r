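#!/usr/bin/env Rscript
# Stage 5: Grad-CAM and guided Grad-CAM explanations of the hit/miss CNN.
#
# For each class: heat-map overlays for an example test frame, activation
# histograms (Blank vs Strong), per-frame localization scores against the
# ground-truth Bragg-peak masks, and the mean total heat per class. The
# localization score is the fraction of heat-map mass inside the dilated
# peak mask; a peak-blind map would score at the mask area fraction.

library(sfxsight)

out <- "results"
dir.create(file.path(out, "explain"), showWarnings = FALSE)
ds <- read_frames(file.path(out, "data"))
fit2 <- load_model(file.path(out, "model_binary.ckpt"))
te <- which(ds$split == "test")

loc_rows <- list()
heat_by_class <- setNames(numeric(5), sfx_classes)
for (cl in sfx_classes) {
  idx <- head(te[ds$labels[te] == cl], 20)
  tot <- 0
  for (i in idx) {
    g <- gradcam(fit2, ds$frames[[i]])
    tot <- tot + sum(g$raw_map)
    if (cl %in% c("Weak", "Good", "Strong")) {
      m <- peak_mask(ds$frames[[i]], 3)
      loc_rows[[length(loc_rows) + 1]] <-
        data.frame(frame = i, class = cl,
                   localization = localization_score(g$heatmap, m),
                   mask_area = mean(m))
    }
  }
  heat_by_class[cl] <- tot / length(idx)
  # example overlay + guided Grad-CAM for the first test frame of the class
  i1 <- idx[1]
  g1 <- gradcam(fit2, ds$frames[[i1]])
  save_png(g1$overlay, file.path(out, "explain",
                                 sprintf("gradcam_%s.png", tolower(cl))))
  gb <- guided_backprop(fit2, ds$frames[[i1]])
  save_png(guided_gradcam(g1, gb),
           file.path(out, "explain",
                     sprintf("guided_gradcam_%s.png", tolower(cl))))
  h <- activation_histogram(g1$heatmap, 32)
  write.csv(data.frame(edge_lo = head(h$edges, -1), count = h$counts),
            file.path(out, "explain",
                      sprintf("activation_histogram_%s.csv", tolower(cl))),
            row.names = FALSE)
}

loc <- do.call(rbind, loc_rows)
write.csv(loc, file.path(out, "explain", "localization_scores.csv"),
          row.names = FALSE)
write.csv(data.frame(class = names(heat_by_class),
                     mean_total_heat = heat_by_class),
          file.path(out, "explain", "heat_by_class.csv"), row.names = FALSE)

message(sprintf("mean localization %.3f vs mask area %.3f over %d hit frames",
                mean(loc$localization), mean(loc$mask_area), nrow(loc)))
message("mean total heat per class:")
print(round(heat_by_class, 3))
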