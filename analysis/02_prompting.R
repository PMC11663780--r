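#!/usr/bin/env Rscript

# Stage 2 — prompt engineering against the scripted LLM backends.
#
# Two deterministic scripted backends stand in for a strong and a weak
# remote LLM. For each, every template in the registry is scored by its
# effective response rate on 10 tuning sections and by accuracy on the
# 200-section selection subset; the best backend/template pair is kept.
# The four five-shot strategies are then compared, and finally a paragraph
# of error-analysis-based instructions (built from the backend's own
# mistakes on the selection subset) is added to the prompt.

suppressPackageStartupMessages(library(cognote))

out <- "results/analysis"
lexicon <- read_lexicon()
bank <- default_phrase_bank(lexicon)
dev <- read_corpus(file.path(out, "dev.jsonl"))
dev_a <- read_corpus(file.path(out, "dev_pool.jsonl"))
dev_s <- read_corpus(file.path(out, "dev_selection.jsonl"))
templates <- default_template_registry()

backends <- list(
  strong = scripted_backend(lexicon, bank, flip_rate_overall = 0.02,
                            per_category_flip = list(negated = 0.5,
                                                     uncertain = 0.3),
                            seed = 201L, name = "strong-llm"),
  weak = scripted_backend(lexicon, bank, flip_rate_overall = 0.3,
                          format_break_rate = 0.15, mute_rate = 0.1,
                          seed = 202L, name = "weak-llm"))

set.seed(203L)
tuning <- note_corpus(dev[sample.int(nrow(dev), 10L), ], name = "tuning")
ranking <- do.call(rbind, lapply(names(backends), function(nm) {
  cbind(backend = nm,
        as.data.frame(rank_templates(templates, backends[[nm]], tuning,
                                     dev_s)))
}))
write.csv(ranking, file.path(out, "template_selection.csv"),
          row.names = FALSE)
print(ranking, row.names = FALSE)

best <- ranking[order(-ranking$effective_response_rate,
                      -ranking$accuracy), ][1, ]
backend <- backends[[best$backend]]
template <- templates[[best$template_id]]
cat(sprintf("\nselected backend '%s' with template '%s' (accuracy %.3f)\n",
            best$backend, best$template_id, best$accuracy))

# four five-shot example-selection strategies
prior <- classify_sections(backend, template,
                           note_corpus(dev_a[1:200, ], "prior"))
strategies <- list(
  random = fewshot_strategy("random", dev_a, 5L, seed = 204L),
  targeted = fewshot_strategy("targeted", note_corpus(dev_a[1:200, ], "p"),
                              5L, seed = 205L,
                              prior_predictions = prior$predictions),
  kmeans = fewshot_strategy("kmeans", note_corpus(dev_a[1:500, ], "k"),
                            5L, seed = 206L),
  knn = fewshot_strategy("knn", note_corpus(dev_a[1:500, ], "n")))
fewshot <- data.frame(
  strategy = names(strategies),
  accuracy = vapply(strategies, function(st) {
    run <- classify_sections(backend, template, dev_s,
                             fewshot_strategy = st)
    selection_accuracy(run$predictions, dev_s)
  }, numeric(1)))
write.csv(fewshot, file.path(out, "fewshot_comparison.csv"),
          row.names = FALSE)
cat("\nfive-shot strategy accuracies on the selection subset\n")
print(fewshot, row.names = FALSE)
cat("(the scripted backend judges the target section only, so example\n",
    "selection cannot move its accuracy; the comparison exercises the\n",
    "machinery that a live backend would benefit from)\n")

# error-analysis-based instructions
base_run <- classify_sections(backend, template, dev_s)
acc_before <- selection_accuracy(base_run$predictions, dev_s)
a <- align_predictions(base_run$predictions, dev_s)
wrong <- which(a$pred != a$gold)
cases <- dev_s[wrong, ]
cases$gold <- a$gold[wrong]
cases$predicted <- a$pred[wrong]
cases$category <- detect_hard_negative_category(cases$text, bank)
instructions <- build_error_instructions(cases)
writeLines(instructions, file.path(out, "error_instructions.txt"))
after <- classify_sections(backend, template, dev_s,
                           error_instructions = instructions)
cat(sprintf("\nerror-analysis-based instructions: accuracy %.3f -> %.3f\n",
            acc_before, selection_accuracy(after$predictions, dev_s)))
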