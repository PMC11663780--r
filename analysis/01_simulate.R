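#!/usr/bin/env Rscript

# Stage 1 — simulate the study corpora.
#
# The patient data behind this kind of study cannot be shared, so every
# downstream stage runs on synthetic analogues with the same statistical
# shape: a keyword-filtered development corpus (4949 sections, 29.4%
# positive, mean length 850 characters, every negative carrying a
# cognition keyword) and an unfiltered test corpus (1996 sections, 3.5%
# positive, mean length 464 characters). The development corpus is split
# into an example pool and a 200-section selection subset.

suppressPackageStartupMessages(library(cognote))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
lexicon <- read_lexicon()
bank <- default_phrase_bank(lexicon)

dev <- generate_corpus(dev_corpus_config(seed = 101L), bank, name = "dev")
test <- generate_corpus(test_corpus_config(seed = 102L), bank,
                        name = "test")
set.seed(103L)
sel_idx <- sample.int(nrow(dev), 200L)
dev_s <- note_corpus(dev[sel_idx, ], name = "dev-selection")
dev_a <- note_corpus(dev[-sel_idx, ], name = "dev-pool")

write_corpus(dev, file.path(out, "dev.jsonl"))
write_corpus(dev_a, file.path(out, "dev_pool.jsonl"))
write_corpus(dev_s, file.path(out, "dev_selection.jsonl"))
write_corpus(test, file.path(out, "test.jsonl"))

characteristics <- do.call(rbind, lapply(
  list(dev, dev_a, dev_s, test), function(corpus) {
    n <- nchar(corpus$text)
    data.frame(corpus = corpus_name(corpus), sections = nrow(corpus),
               patients = length(unique(corpus$patient_id)),
               mean_chars = round(mean(n), 1), min_chars = min(n),
               max_chars = max(n),
               positive_rate_pct = round(100 * positive_rate(corpus), 1))
  }))
write.csv(characteristics, file.path(out, "dataset_characteristics.csv"),
          row.names = FALSE)
print(characteristics, row.names = FALSE)

kept <- keyword_filter(dev, lexicon)
cat(sprintf("\nexpert keyword screen retains %d / %d development sections\n",
            attr(kept, "retained"), nrow(dev)))
cat(sprintf("test-corpus sections matching a screening keyword: %d / %d\n",
            sum(lexicon_matches(test, lexicon)), nrow(test)))
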