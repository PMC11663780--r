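#' Configuration for an end-to-end experiment
#'
#' Bundles everything [run_experiment()] needs: generator configs for the
#' development corpus (split into an example pool and a selection subset)
#' and the unfiltered test corpus, the template registry, the scripted
#' backend error profiles for the LLM analogue and for template selection,
#' few-shot settings, baseline hyperparameters, bootstrap settings and a
#' global seed from which every stage seed is derived.
#'
#' @param dev_config Generator config for the keyword-filtered development
#'   corpus.
#' @param test_config Generator config for the unfiltered test corpus.
#' @param selection_size Size of the selection subset held out of the
#'   development corpus for template/strategy scoring.
#' @param templates Named list of `prompt_template` objects.
#' @param llm_profile Named list of [scripted_backend()] arguments for the
#'   primary LLM analogue.
#' @param weak_llm_profile Scripted-backend arguments for the weaker LLM
#'   analogue used in backend selection.
#' @param fewshot_k Examples per prompt (default 5).
#' @param tree_grid Boosted-trees hyperparameter grid.
#' @param net_hyper Attention-net hyperparameters.
#' @param bootstrap_B Bootstrap replicates.
#' @param patient_split Keep patient ids disjoint between development and
#'   test corpora? Default `FALSE`, mirroring a section-level split in which
#'   the same patient may appear on both sides.
#' @param seed Global integer seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(dev_config = dev_corpus_config(),
                              test_config = test_corpus_config(),
                              selection_size = 200L,
                              templates = default_template_registry(),
                              llm_profile = list(
                                flip_rate_overall = 0.02,
                                per_category_flip = list(negated = 0.5,
                                                         uncertain = 0.3)),
                              weak_llm_profile = list(
                                flip_rate_overall = 0.3,
                                format_break_rate = 0.15,
                                mute_rate = 0.1),
                              fewshot_k = 5L,
                              tree_grid = default_tree_grid(),
                              net_hyper = attention_hyper(epochs = 3L,
                                                          max_tokens = 128L),
                              bootstrap_B = 1000L,
                              patient_split = FALSE,
                              seed = 1L) {
  structure(list(dev_config = dev_config, test_config = test_config,
                 selection_size = as.integer(selection_size),
                 templates = templates, llm_profile = llm_profile,
                 weak_llm_profile = weak_llm_profile,
                 fewshot_k = as.integer(fewshot_k),
                 tree_grid = tree_grid, net_hyper = net_hyper,
                 bootstrap_B = as.integer(bootstrap_B),
                 patient_split = isTRUE(patient_split),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

stage_seed <- function(config, offset) {
  (config$seed * 7919L + offset) %% 2147483647L
}

config_hash <- function(config) {
  hash_string(paste(utils::capture.output(utils::str(config)),
                    collapse = "\n"))
}

relabel_patients <- function(corpus, prefix) {
  corpus$patient_id <- paste0(prefix, corpus$patient_id)
  corpus
}

#' Run the four-part experiment end to end
#'
#' Executes, in order: corpus generation (development and test analogues,
#' with the development corpus split into an example pool and a selection
#' subset), keyword screening, template and backend selection (effective
#' response rate on a small tuning sample, then accuracy on the selection
#' subset), the four five-shot strategy comparison, error-analysis-based
#' instruction augmentation, baseline training, classification of the test
#' corpus by all three models, majority-vote ensembling, bootstrap metrics
#' with paired comparisons, the merged keyword report, and the error-overlap
#' report. Every artefact is written under `out_dir` together with a run
#' manifest (config hash, stage seeds, package version). A stage failure
#' aborts with the stage name; artefacts written so far persist.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, paste("FAILED:", conditionMessage(e)))
      stop("experiment stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  lexicon <- read_lexicon()
  bank <- default_phrase_bank(lexicon)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("cognote")),
                   config_hash = config_hash(config),
                   global_seed = config$seed, stage_seeds = list())
  seed_for <- function(name, offset) {
    s <- stage_seed(config, offset)
    manifest$stage_seeds[[name]] <<- s
    s
  }

  # -- stage 1: generate ----------------------------------------------------
  corpora <- run_stage("generate", {
    dev_cfg <- config$dev_config
    dev_cfg$seed <- seed_for("dev_corpus", 1L)
    test_cfg <- config$test_config
    test_cfg$seed <- seed_for("test_corpus", 2L)
    dev <- generate_corpus(dev_cfg, bank, name = "dev")
    test <- generate_corpus(test_cfg, bank, name = "test")
    if (config$patient_split) {
      dev <- relabel_patients(dev, "DEV-")
      test <- relabel_patients(test, "TEST-")
    }
    sel_idx <- with_seed(seed_for("selection_split", 3L),
                         sample.int(nrow(dev), config$selection_size))
    dev_s <- note_corpus(dev[sel_idx, ], name = "dev-selection")
    dev_a <- note_corpus(dev[-sel_idx, ], name = "dev-pool")
    write_corpus(dev, file.path(out_dir, "dev.jsonl"))
    write_corpus(test, file.path(out_dir, "test.jsonl"))
    write_corpus(dev_s, file.path(out_dir, "dev_selection.jsonl"))
    note("generate", sprintf(
      "dev n=%d (pos %.3f), pool n=%d, selection n=%d, test n=%d (pos %.3f)",
      nrow(dev), positive_rate(dev), nrow(dev_a), nrow(dev_s), nrow(test),
      positive_rate(test)))
    list(dev = dev, dev_a = dev_a, dev_s = dev_s, test = test)
  })

  # -- stage 2: keyword screening -------------------------------------------
  run_stage("filter", {
    filtered <- keyword_filter(corpora$dev, lexicon)
    note("filter", sprintf("expert keyword screen retains %d / %d sections",
                           attr(filtered, "retained"), nrow(corpora$dev)))
  })

  # -- stage 3: template and backend selection ------------------------------
  selection <- run_stage("select_template", {
    tune_idx <- with_seed(seed_for("template_tuning", 4L),
                          sample.int(nrow(corpora$dev), 10L))
    tuning <- note_corpus(corpora$dev[tune_idx, ], name = "tuning")
    backends <- list(
      strong = do.call(scripted_backend,
                       c(list(lexicon = lexicon, bank = bank,
                              seed = seed_for("strong_backend", 5L),
                              name = "strong-llm"), config$llm_profile)),
      weak = do.call(scripted_backend,
                     c(list(lexicon = lexicon, bank = bank,
                            seed = seed_for("weak_backend", 6L),
                            name = "weak-llm"), config$weak_llm_profile)))
    reports <- lapply(backends, function(be) {
      rank_templates(config$templates, be, tuning, corpora$dev_s)
    })
    best <- lapply(reports, function(r) r[1, ])
    chosen_backend <- names(which.max(vapply(best, function(r) r$accuracy,
                                             numeric(1))))
    report_df <- do.call(rbind, lapply(names(reports), function(nm) {
      cbind(backend = nm, as.data.frame(reports[[nm]]))
    }))
    utils::write.csv(report_df,
                     file.path(out_dir, "template_selection.csv"),
                     row.names = FALSE)
    note("select_template", sprintf(
      "selected backend '%s' with template '%s' (accuracy %.3f)",
      chosen_backend, best[[chosen_backend]]$template_id,
      best[[chosen_backend]]$accuracy))
    list(backend = backends[[chosen_backend]],
         template = config$templates[[best[[chosen_backend]]$template_id]])
  })

  # -- stage 4: few-shot strategy comparison --------------------------------
  run_stage("fewshot", {
    pool <- corpora$dev_a
    prior <- classify_sections(selection$backend, selection$template,
                               pool[seq_len(min(200L, nrow(pool))), ])
    strategies <- list(
      random = fewshot_strategy("random", pool, config$fewshot_k,
                                seed = seed_for("fs_random", 7L)),
      targeted = fewshot_strategy(
        "targeted", pool[seq_len(min(200L, nrow(pool))), ],
        config$fewshot_k, seed = seed_for("fs_targeted", 8L),
        prior_predictions = prior$predictions),
      kmeans = fewshot_strategy("kmeans",
                                pool[seq_len(min(500L, nrow(pool))), ],
                                config$fewshot_k,
                                seed = seed_for("fs_kmeans", 9L)),
      knn = fewshot_strategy("knn", pool[seq_len(min(500L, nrow(pool))), ],
                             config$fewshot_k))
    accs <- vapply(names(strategies), function(nm) {
      res <- classify_sections(selection$backend, selection$template,
                               corpora$dev_s,
                               fewshot_strategy = strategies[[nm]])
      selection_accuracy(res$predictions, corpora$dev_s)
    }, numeric(1))
    utils::write.csv(data.frame(strategy = names(accs), accuracy = accs),
                     file.path(out_dir, "fewshot_comparison.csv"),
                     row.names = FALSE)
    note("fewshot", paste(sprintf("%s=%.3f", names(accs), accs),
                          collapse = ", "))
  })

  # -- stage 5: error-analysis-based instructions ---------------------------
  instructions <- run_stage("error_instructions", {
    base_run <- classify_sections(selection$backend, selection$template,
                                  corpora$dev_s)
    a <- align_predictions(base_run$predictions, corpora$dev_s)
    wrong <- which(a$pred != a$gold)
    if (length(wrong) == 0L) {
      note("error_instructions", "no errors on selection subset; skipped")
      NULL
    } else {
      cases <- corpora$dev_s[wrong, ]
      cases$gold <- a$gold[wrong]
      cases$predicted <- a$pred[wrong]
      cases$category <- detect_hard_negative_category(cases$text, bank)
      txt <- build_error_instructions(cases)
      writeLines(txt, file.path(out_dir, "error_instructions.txt"))
      after <- classify_sections(selection$backend, selection$template,
                                 corpora$dev_s, error_instructions = txt)
      note("error_instructions", sprintf(
        "selection accuracy %.3f -> %.3f after instructions",
        selection_accuracy(base_run$predictions, corpora$dev_s),
        selection_accuracy(after$predictions, corpora$dev_s)))
      txt
    }
  })

  # -- stage 6: baseline training -------------------------------------------
  trees <- run_stage("train_trees", {
    m <- train_boosted_trees(corpora$dev, grid = config$tree_grid,
                             seed = seed_for("trees", 10L))
    note("train_trees", sprintf(
      "best grid point: nrounds=%d depth=%d eta=%.2f (CV F1 %.3f)",
      m$best_params$nrounds, m$best_params$max_depth, m$best_params$eta,
      max(m$grid$cv_f1)))
    m
  })
  net <- run_stage("train_net", {
    m <- train_attention_net(corpora$dev, hyper = config$net_hyper,
                             seed = seed_for("net", 11L))
    note("train_net", sprintf("trained on %d sections, vocabulary %d",
                              nrow(corpora$dev), length(m$vocabulary)))
    m
  })

  # -- stage 7: classify the test corpus ------------------------------------
  preds <- run_stage("classify_test", {
    llm_run <- classify_sections(selection$backend, selection$template,
                                 corpora$test,
                                 error_instructions = instructions,
                                 model_name = "llm")
    write_verdict_log(llm_run$log, file.path(out_dir, "llm_verdicts.jsonl"))
    p <- list(llm = llm_run$predictions,
              boosted_trees = predict_labels(trees, corpora$test),
              attention_net = predict_labels(net, corpora$test))
    for (nm in names(p)) {
      write_predictions(p[[nm]], file.path(out_dir,
                                           paste0("pred_", nm, ".csv")))
    }
    note("classify_test", sprintf("%d flagged LLM fallbacks",
                                  sum(llm_run$log$flagged)))
    list(models = p, llm_log = llm_run$log)
  })

  # -- stage 8: ensemble ----------------------------------------------------
  ens <- run_stage("ensemble", {
    e <- majority_vote(unname(preds$models))
    write_predictions(e, file.path(out_dir, "pred_ensemble.csv"))
    e
  })

  # -- stage 9: evaluation --------------------------------------------------
  run_stage("evaluate", {
    all_preds <- c(preds$models, list(ensemble = ens))
    reports <- lapply(all_preds, function(p) {
      bootstrap_cis(p, corpora$test, B = config$bootstrap_B,
                    seed = seed_for("bootstrap", 12L))
    })
    for (nm in names(reports)) {
      write_metrics_json(reports[[nm]],
                         file.path(out_dir, paste0("metrics_", nm, ".json")))
    }
    tests <- do.call(rbind, lapply(names(preds$models), function(nm) {
      cbind(comparison = paste0("ensemble_vs_", nm),
            as.data.frame(paired_metric_test(ens, preds$models[[nm]],
                                             corpora$test,
                                             B = config$bootstrap_B,
                                             seed = seed_for("paired",
                                                             13L))))
    }))
    utils::write.csv(tests, file.path(out_dir, "paired_tests.csv"),
                     row.names = FALSE)
    writeLines(format_metrics_table(reports),
               file.path(out_dir, "metrics_table.txt"))
    note("evaluate", sprintf("ensemble F1 %.3f", reports$ensemble$f1))
  })

  # -- stage 10: interpretation ---------------------------------------------
  run_stage("interpret", {
    tables <- list(llm_keywords(preds$llm_log),
                   attention_keywords(net, corpora$dev_s),
                   gain_keywords(trees))
    report <- merge_keyword_report(tables, lexicon)
    write_keyword_report(report, file.path(out_dir, "keyword_report.tsv"))
    note("interpret", sprintf("%d selected model keywords",
                              sum(report$selected &
                                    report$source != "expert")))
  })

  # -- stage 11: error overlap ----------------------------------------------
  run_stage("overlap", {
    counts <- overlap_counts(error_sets(unname(preds$models),
                                        corpora$test))
    write_overlap_json(counts, file.path(out_dir, "overlap.json"))
    note("overlap", sprintf("union %d, triple %d", counts$union,
                            counts$abc))
  })

  manifest$stages <- log_lines
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a human-readable report from a run directory
#'
#' Assembles the dataset-characteristics, metric, keyword and error-overlap
#' tables from a completed [run_experiment()] directory. Missing artefacts
#' are listed by name.
#'
#' @param run_dir A run directory.
#' @return Character vector of report lines (also written to
#'   `report.txt` in the run directory).
#' @export
render_report <- function(run_dir) {
  needed <- c("dev.jsonl", "test.jsonl", "metrics_table.txt",
              "keyword_report.tsv", "overlap.json", "manifest.json")
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  if (length(missing) > 0L) {
    stop("run directory is missing artefact(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dev <- read_corpus(file.path(run_dir, "dev.jsonl"))
  test <- read_corpus(file.path(run_dir, "test.jsonl"))
  char_row <- function(corpus) {
    n <- nchar(corpus$text)
    sprintf("%-6s %8d sections %10.1f (%d-%d) chars %8.1f%% positive",
            corpus_name(corpus), nrow(corpus), mean(n), min(n), max(n),
            100 * positive_rate(corpus))
  }
  overlap <- jsonlite::read_json(file.path(run_dir, "overlap.json"))
  lines <- c(
    "== Dataset characteristics ==",
    char_row(dev), char_row(test), "",
    "== Model evaluation ==",
    readLines(file.path(run_dir, "metrics_table.txt")), "",
    "== Keywords ==",
    format_keyword_table(
      read_keyword_report(file.path(run_dir, "keyword_report.tsv"))), "",
    "== Error overlap ==",
    sprintf("per-model errors: %s", paste(unlist(overlap[c("a", "b", "c")]),
                                          collapse = ", ")),
    sprintf("pairwise (incl. triple): %s; triple: %s",
            paste(unlist(overlap[c("ab", "ac", "bc")]), collapse = ", "),
            overlap$abc),
    sprintf("union: %s; mutual-error fraction: %s%%", overlap$union,
            overlap$mutual_error_pct))
  writeLines(lines, file.path(run_dir, "report.txt"))
  lines
}
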