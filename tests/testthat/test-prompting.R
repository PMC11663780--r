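section_for <- function(text = "Memory loss noted.", id = "s001") {
  list(section_id = id, text = text)
}

test_that("prompt assembly renders blocks in fixed order and is pure", {
  tpl <- prompt_template("t", "Judge the section.",
                         additional_guidance = "Be careful.",
                         few_shot_slot = TRUE)
  ex <- tibble::tibble(text = sprintf("ex %d", 1:5),
                       label = c(1L, 0L, 1L, 0L, 0L))
  p1 <- assemble_prompt(tpl, section_for(), examples = ex,
                        error_instructions = "Watch negations.")
  p2 <- assemble_prompt(tpl, section_for(), examples = ex,
                        error_instructions = "Watch negations.")
  expect_identical(p1, p2)
  heads <- c("## Task", "## Guidance", "## Examples",
             "## Error instructions", "## Response format", "## Section")
  pos <- vapply(heads, function(h) regexpr(h, p1, fixed = TRUE)[1],
                numeric(1))
  expect_true(all(diff(pos) > 0))
  expect_equal(lengths(regmatches(p1, gregexpr("Example \\d", p1))), 5)
  # JSON and both questions always requested
  expect_match(p1, "JSON")
  expect_match(p1, "cognitive_decline")
  expect_match(p1, "keywords")
  # minimal template: task and section only
  tpl0 <- prompt_template("t0", "Judge.")
  p0 <- assemble_prompt(tpl0, section_for())
  expect_false(grepl("## Guidance|## Examples|## Error instructions", p0))
  expect_error(assemble_prompt(tpl0, section_for(), examples = ex),
               "few-shot")
  expect_error(prompt_template("bad", ""), "non-empty")
})

test_that("response parsing partitions all inputs into three categories", {
  v <- parse_response('{"cognitive_decline":"yes","keywords":["memory loss"]}')
  expect_identical(v$category, "effective_parseable")
  expect_identical(v$label, 1L)
  expect_identical(v$keywords, "memory loss")
  v2 <- parse_response("Decline present. Keywords: memory, MoCA")
  expect_identical(v2$category, "effective_unparseable")
  expect_true(is.na(v2$label))
  expect_identical(parse_response("I am unable to help with that.")$category,
                   "not_effective")
  # judgment normalisation
  for (val in c("YES", "true", 1)) {
    r <- parse_response(jsonlite::toJSON(list(label = val,
                                              keywords = "x"),
                                         auto_unbox = TRUE))
    expect_identical(r$label, 1L)
  }
  for (val in c("No", "false", 0)) {
    r <- parse_response(jsonlite::toJSON(list(decision = val,
                                              keywords = list()),
                                         auto_unbox = TRUE))
    expect_identical(r$label, 0L)
  }
  # fuzz: parsing never throws and always assigns a category
  set.seed(42)
  alphabet <- c(letters, " ", "{", "}", '"', ":", ",", "[", "]", "\n")
  for (i in 1:200) {
    raw <- paste(sample(alphabet, sample(0:60, 1), replace = TRUE),
                 collapse = "")
    out <- parse_response(raw)
    expect_true(out$category %in% c("effective_parseable",
                                    "effective_unparseable",
                                    "not_effective"))
    expect_identical(!is.na(out$label),
                     out$category == "effective_parseable")
  }
})

test_that("effective response rate counts both effective categories", {
  vs <- c(replicate(5, parse_response('{"label":"yes","keywords":["a"]}'),
                    simplify = FALSE),
          replicate(3, parse_response("Yes. Keywords: a"), simplify = FALSE),
          replicate(2, parse_response("cannot"), simplify = FALSE))
  expect_equal(effective_response_rate(vs), 0.8)
  expect_equal(effective_response_rate(vs, count_unparseable = FALSE), 0.5)
  expect_equal(effective_response_rate(vs[1:5]), 1.0)
  expect_equal(effective_response_rate(vs[9:10]), 0.0)
  expect_error(effective_response_rate(list()), "no verdicts")
})

test_that("the scripted backend is deterministic and heuristic-exact", {
  lex <- fixture_lexicon()
  be <- scripted_backend(lex, fixture_bank(), seed = 5)
  tpl <- default_template_registry()$t2
  prompt <- assemble_prompt(tpl, section_for("Early dementia discussed."))
  r1 <- llm_complete(be, prompt)
  r2 <- llm_complete(be, prompt)
  expect_identical(r1, r2)
  v <- parse_response(r1)
  expect_identical(v$label, 1L)
  expect_true("dementia" %in% v$keywords)
  # keyword-free section -> negative
  v0 <- parse_response(llm_complete(be, assemble_prompt(
    tpl, section_for("knee pain improved", "s002"))))
  expect_identical(v0$label, 0L)
  # hard-negative cue overrides keyword presence
  vh <- parse_response(llm_complete(be, assemble_prompt(
    tpl, section_for("Temporary forgetfulness due to codeine, expected to resolve.",
                     "s003"))))
  expect_identical(vh$label, 0L)
  expect_error(llm_complete(be, "no target here"), "target-section")
  expect_error(scripted_backend(lex, fixture_bank(), mute_rate = 2),
               "rates")
  expect_error(scripted_backend(lex, fixture_bank(),
                                per_category_flip = list(bogus = 0.5)),
               "bogus")
})

test_that("classification handles fallbacks and exact heuristics", {
  lex <- fixture_lexicon()
  bank <- fixture_bank()
  tpl <- default_template_registry()$t1
  corpus <- generate_corpus(generator_config(60, 0.4,
                                             hard_negative_share = 0,
                                             seed = 31), bank)
  res <- classify_sections(scripted_backend(lex, bank, seed = 7), tpl,
                           corpus)
  expect_equal(selection_accuracy(res$predictions, corpus), 1.0)
  # mute backend: all default-negative and flagged
  mute <- classify_sections(scripted_backend(lex, bank, seed = 7,
                                             mute_rate = 1), tpl,
                            corpus[1:10, ])
  expect_true(all(mute$predictions$label == 0L))
  expect_true(all(mute$log$flagged))
  # format-breaking backend: effective but unparseable, also fallback
  fb <- classify_sections(scripted_backend(lex, bank, seed = 7,
                                           format_break_rate = 1), tpl,
                          corpus[1:10, ])
  expect_true(all(fb$log$category == "effective_unparseable"))
  expect_equal(effective_response_rate(fb$log), 1.0)
})

test_that("selection accuracy matches its definition and alignment rules", {
  gold <- tiny_corpus(rep("x y", 200), rep(c(1L, 0L), 100))
  pred_labels <- gold$label
  pred_labels[1:28] <- 1L - pred_labels[1:28]
  pred <- prediction_set(gold$section_id, pred_labels)
  expect_equal(selection_accuracy(pred, gold), 0.86)
  expect_equal(selection_accuracy(prediction_set(gold$section_id,
                                                 gold$label), gold), 1.0)
  expect_equal(selection_accuracy(prediction_set(gold$section_id,
                                                 1L - gold$label), gold),
               0.0)
  expect_error(selection_accuracy(prediction_set("zz", 1L), gold),
               "different section ids")
})

test_that("error instructions enumerate categories deterministically", {
  cases <- tibble::tibble(
    text = c("No evidence of memory loss.", "Improved cognition.",
             "Temporary forgetfulness due to codeine."),
    gold = c(0L, 0L, 0L), predicted = c(1L, 1L, 1L),
    category = c("negated", "improvement", "transient"))
  txt <- build_error_instructions(cases)
  expect_identical(txt, build_error_instructions(cases))
  expect_match(txt, "negated")
  expect_equal(lengths(regmatches(txt, gregexpr("\n- ", txt))), 3)
  expect_error(build_error_instructions(cases[0, ]), "error case")
})

test_that("targeted error instructions strictly raise accuracy", {
  lex <- fixture_lexicon()
  bank <- fixture_bank()
  tpl <- default_template_registry()$t1
  corpus <- generate_corpus(generator_config(150, 0.3,
                                             hard_negative_share = 0.6,
                                             seed = 17), bank)
  be <- scripted_backend(lex, bank, seed = 23,
                         per_category_flip = list(negated = 1,
                                                  transient = 1))
  before <- classify_sections(be, tpl, corpus)
  acc_before <- selection_accuracy(before$predictions, corpus)
  a <- align_predictions(before$predictions, corpus)
  wrong <- which(a$pred != a$gold)
  cases <- corpus[wrong, ]
  cases$gold <- a$gold[wrong]
  cases$predicted <- a$pred[wrong]
  cases$category <- detect_hard_negative_category(cases$text, bank)
  instr <- build_error_instructions(cases)
  after <- classify_sections(be, tpl, corpus, error_instructions = instr)
  acc_after <- selection_accuracy(after$predictions, corpus)
  expect_lt(acc_before, 1.0)
  expect_gt(acc_after, acc_before)
  expect_equal(acc_after, 1.0)
})

test_that("template ranking orders by response rate then accuracy", {
  lex <- fixture_lexicon()
  bank <- fixture_bank()
  corpus <- generate_corpus(generator_config(30, 0.4, seed = 51,
                                             hard_negative_share = 0.3),
                            bank)
  report <- rank_templates(default_template_registry(),
                           scripted_backend(lex, bank, seed = 3),
                           corpus[1:10, ], corpus[11:30, ])
  expect_identical(names(report),
                   c("template_id", "effective_response_rate", "accuracy"))
  expect_true(!is.unsorted(rev(report$effective_response_rate)))
})

test_that("verdict logs and templates round-trip through their formats", {
  lex <- fixture_lexicon()
  bank <- fixture_bank()
  corpus <- generate_corpus(generator_config(10, 0.4, seed = 77), bank)
  res <- classify_sections(scripted_backend(lex, bank, seed = 7),
                           default_template_registry()$t2, corpus)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_verdict_log(res$log, path)
  back <- read_verdict_log(path)
  expect_identical(back$section_id, res$log$section_id)
  expect_identical(back$label, res$log$label)
  expect_identical(back$keywords, res$log$keywords)
  tpath <- withr::local_tempfile(fileext = ".yaml")
  write_templates(default_template_registry(), tpath)
  back_t <- read_templates(tpath)
  expect_identical(lapply(back_t, unclass),
                   lapply(default_template_registry(), unclass))
})
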