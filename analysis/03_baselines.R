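#!/usr/bin/env Rscript

# Stage 3 — train the two local baselines on the development corpus.
#
# Boosted trees on TF-IDF unigrams (grid search over trees x depth x
# learning rate with 5-fold cross-validated F1) and the attention network
# (embedding -> convolution -> bidirectional recurrence -> additive
# attention -> sigmoid).

suppressPackageStartupMessages(library(cognote))

out <- "results/analysis"
dev <- read_corpus(file.path(out, "dev.jsonl"))

trees <- train_boosted_trees(dev, seed = 301L)
write.csv(trees$grid, file.path(out, "tree_grid_cv.csv"),
          row.names = FALSE)
cat("boosted-trees grid (5-fold CV F1):\n")
print(trees$grid, row.names = FALSE)
cat(sprintf("selected: nrounds=%d, depth=%d, eta=%.2f\n",
            trees$best_params$nrounds, trees$best_params$max_depth,
            trees$best_params$eta))

net <- train_attention_net(dev,
                           attention_hyper(epochs = 3L, max_tokens = 128L),
                           seed = 302L)
cat(sprintf("attention net trained: vocabulary %d, %d epochs\n",
            length(net$vocabulary), net$hyper$epochs))

saveRDS(trees, file.path(out, "model_trees.rds"))
saveRDS(net, file.path(out, "model_net.rds"))
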