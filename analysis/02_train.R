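#!/usr/bin/env Rscript
# Stage 2: train the two CNN hit finders on the simulated dataset.
#
# Fits (a) a five-class classifier over Blank/NoCrystal/Weak/Good/Strong and
# (b) a binary hit/miss classifier after merging the labels, both with the
# desk-scale AlexNet-style architecture and the Adam recipe (15 epochs for
# five classes, 10 for the easier binary problem). Saves checkpoints and
# per-epoch histories.

library(sfxsight)

seed <- 1L
out <- "results"
ds <- read_frames(file.path(out, "data"))

message("training five-class model ...")
fit5 <- train(build_model(desk_alexnet_spec(5, 64), seed = seed + 1), ds,
              train_config(epochs = 15, batch_size = 32, seed = seed + 2),
              target = "multiclass", verbose = TRUE)
save_model(fit5$model, file.path(out, "model_multiclass.ckpt"))
write.csv(fit5$history, file.path(out, "history_multiclass.csv"),
          row.names = FALSE)

message("training hit/miss model ...")
fit2 <- train(build_model(desk_alexnet_spec(2, 64), seed = seed + 1), ds,
              train_config(epochs = 10, batch_size = 32, seed = seed + 2),
              target = "binary", verbose = TRUE)
save_model(fit2$model, file.path(out, "model_binary.ckpt"))
write.csv(fit2$history, file.path(out, "history_binary.csv"),
          row.names = FALSE)

message(sprintf("final test accuracy: five-class %.1f%%, hit/miss %.1f%%",
                100 * tail(fit5$history$test_acc, 1),
                100 * tail(fit2$history$test_acc, 1)))
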