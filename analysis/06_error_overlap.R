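#!/usr/bin/env Rscript

# Stage 6 — error-profile diversity: per-model error sets on the test
# corpus, the three-set Venn decomposition with inclusion-exclusion
# accounting, and the mutual-error fraction.

suppressPackageStartupMessages(library(cognote))

out <- "results/analysis"
test <- read_corpus(file.path(out, "test.jsonl"))
preds <- lapply(c("llm", "boosted_trees", "attention_net"), function(nm) {
  read_predictions(file.path(out, paste0("pred_", nm, ".csv")), name = nm)
})

sets <- error_sets(preds, test)
counts <- overlap_counts(sets)
print(counts)
cat(sprintf("mutual-error fraction: %.1f%% of the %d mispredicted sections\n",
            mutual_error_fraction(counts), counts$union))
write_overlap_json(counts, file.path(out, "overlap.json"))

png(file.path(out, "error_venn.png"), width = 720, height = 640)
plot_error_venn(counts)
dev.off()
cat("wrote", file.path(out, "error_venn.png"), "\n")
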