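#!/usr/bin/env Rscript

# Stage 5 — keyword-importance interpretation, merging the three model
# channels (LLM citation counts, attention concentration, split gain) with
# the expert lexicon via the mean-plus-two-standard-deviations rule.

suppressPackageStartupMessages(library(cognote))

out <- "results/analysis"
lexicon <- read_lexicon()
trees <- readRDS(file.path(out, "model_trees.rds"))
net <- readRDS(file.path(out, "model_net.rds"))
dev_s <- read_corpus(file.path(out, "dev_selection.jsonl"))
llm_log <- read_verdict_log(file.path(out, "llm_verdicts.jsonl"))

tables <- list(llm_keywords(llm_log),
               attention_keywords(net, dev_s),
               gain_keywords(trees))
report <- merge_keyword_report(tables, lexicon)
write_keyword_report(report, file.path(out, "keyword_report.tsv"))
cat(format_keyword_table(report), sep = "\n")
cat(sprintf("\n%d model-derived keywords selected alongside %d expert terms\n",
            sum(report$selected & report$source != "expert"),
            sum(report$source == "expert")))
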