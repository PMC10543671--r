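#!/usr/bin/env Rscript
# Stage 3: evaluate both classifiers on the held-out test split.
#
# Produces the five-class confusion matrix with per-class recall and
# precision (the standard published layout), and row-normalized 2x2 hit/miss
# cross-tabulations for the binary CNN and for the classical spot-finder
# baseline, against ground truth.

library(sfxsight)

out <- "results"
ds <- read_frames(file.path(out, "data"))
fit5 <- load_model(file.path(out, "model_multiclass.ckpt"))
fit2 <- load_model(file.path(out, "model_binary.ckpt"))
te <- which(ds$split == "test")

pred5 <- predict_frames(fit5, ds$frames[te])
cm <- confusion(ds$labels[te], factor(sfx_classes[pred5$labels],
                                      levels = sfx_classes))
tab <- metric_table(cm)
write.csv(tab, file.path(out, "confusion_multiclass.csv"))
message(sprintf("five-class accuracy: %.1f%%", accuracy(cm)))
print(tab)

pred2 <- predict_frames(fit2, ds$frames[te])
cnn_tab <- hit_miss_table(as.character(ds$binary[te]),
                          sfx_binary_classes[pred2$labels])
sp <- spot_params(n_min = 2, n_max = 400, n_peaks = 3, snr_min = 3)
spot_tab <- hit_miss_table(as.character(ds$binary[te]),
                           vapply(ds$frames[te],
                                  function(f) classify_hit(f, sp)$label, ""))
message("CNN hit/miss row percentages:")
print(round(cnn_tab, 1))
message("spot-finder hit/miss row percentages:")
print(round(spot_tab, 1))
write.csv(rbind(data.frame(method = "cnn", true = rownames(cnn_tab), cnn_tab),
                data.frame(method = "spotfinder", true = rownames(spot_tab),
                           spot_tab)),
          file.path(out, "hit_miss_tables.csv"), row.names = FALSE)
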