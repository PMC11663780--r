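#!/usr/bin/env Rscript

# Stage 4 — classify the test corpus with all three models, combine them by
# majority vote, and evaluate with bootstrap confidence intervals and
# paired comparisons.

suppressPackageStartupMessages(library(cognote))

out <- "results/analysis"
lexicon <- read_lexicon()
bank <- default_phrase_bank(lexicon)
test <- read_corpus(file.path(out, "test.jsonl"))
trees <- readRDS(file.path(out, "model_trees.rds"))
net <- readRDS(file.path(out, "model_net.rds"))
instructions <- paste(readLines(file.path(out, "error_instructions.txt")),
                      collapse = "\n")

backend <- scripted_backend(lexicon, bank, flip_rate_overall = 0.02,
                            per_category_flip = list(negated = 0.5,
                                                     uncertain = 0.3),
                            seed = 201L, name = "llm")
llm_run <- classify_sections(backend, default_template_registry()$t1, test,
                             error_instructions = instructions,
                             model_name = "llm")
write_verdict_log(llm_run$log, file.path(out, "llm_verdicts.jsonl"))

preds <- list(llm = llm_run$predictions,
              boosted_trees = predict_labels(trees, test),
              attention_net = predict_labels(net, test))
ens <- majority_vote(unname(preds))
all_preds <- c(preds, list(ensemble = ens))
for (nm in names(all_preds)) {
  write_predictions(all_preds[[nm]],
                    file.path(out, paste0("pred_", nm, ".csv")))
}

reports <- lapply(all_preds, bootstrap_cis, gold = test, B = 1000L,
                  seed = 401L)
for (nm in names(reports)) {
  write_metrics_json(reports[[nm]],
                     file.path(out, paste0("metrics_", nm, ".json")))
}
table_lines <- format_metrics_table(reports)
writeLines(table_lines, file.path(out, "metrics_table.txt"))
cat(table_lines, sep = "\n")

tests <- do.call(rbind, lapply(names(preds), function(nm) {
  cbind(comparison = paste0("ensemble_vs_", nm),
        as.data.frame(paired_metric_test(ens, preds[[nm]], test,
                                         B = 1000L, seed = 402L)))
}))
write.csv(tests, file.path(out, "paired_tests.csv"), row.names = FALSE)
cat("\npaired bootstrap comparisons (ensemble minus model):\n")
print(tests[tests$metric %in% c("accuracy", "f1"), ], row.names = FALSE)
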