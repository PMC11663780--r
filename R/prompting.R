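#' Construct a prompt template
#'
#' A template has a required task description and optional blocks: additional
#' task guidance, a five-shot examples slot, and error-analysis-based
#' instructions. Whatever the blocks say, every rendered prompt also carries a
#' fixed response-format block asking for (a) the cognitive-decline judgment,
#' (b) the supporting keywords and (c) JSON output — so the template invariant
#' holds by construction.
#'
#' @param template_id Short identifier.
#' @param task_description Required task text.
#' @param additional_guidance Optional guidance text.
#' @param few_shot_slot Enable the examples block?
#' @param error_instructions Optional error-analysis-based instruction text.
#' @return A `prompt_template`.
#' @export
prompt_template <- function(template_id, task_description,
                            additional_guidance = NULL,
                            few_shot_slot = FALSE,
                            error_instructions = NULL) {
  if (!nzchar(task_description)) {
    stop("task_description must be non-empty", call. = FALSE)
  }
  structure(list(template_id = template_id,
                 task_description = task_description,
                 additional_guidance = additional_guidance,
                 few_shot_slot = isTRUE(few_shot_slot),
                 error_instructions = error_instructions),
            class = "prompt_template")
}

#' The default template registry
#'
#' A small registry of candidate templates differing in which optional blocks
#' they carry, used by the template-selection stage.
#'
#' @return Named list of `prompt_template` objects.
#' @export
default_template_registry <- function() {
  task <- paste("Read the clinical note section below and judge whether it",
                "documents signs of progressive cognitive decline (from",
                "subjective cognitive decline through mild cognitive",
                "impairment to dementia).")
  guidance <- paste("Count concerns, symptoms, diagnoses, cognitive",
                    "assessments and cognition-directed therapies as",
                    "evidence. Do not count mentions that are improving,",
                    "transient, reversible, negated or uncertain. Briefly",
                    "reason before answering.")
  list(
    t1 = prompt_template("t1", task, additional_guidance = guidance,
                         few_shot_slot = TRUE),
    t2 = prompt_template("t2", task, few_shot_slot = TRUE),
    t3 = prompt_template("t3", task,
                         additional_guidance = "Answer strictly from the text.",
                         few_shot_slot = TRUE))
}

#' Render a prompt from a template and a target section
#'
#' Blocks are rendered in fixed order — task description, guidance, examples,
#' error instructions, response format, target section — each introduced by a
#' labelled header line. Rendering is a pure function of its inputs.
#'
#' @param template A `prompt_template`.
#' @param section A one-row corpus slice or a list with `section_id` and
#'   `text`.
#' @param examples A data frame with columns `text` and `label`, or `NULL`.
#' @param error_instructions Optional override for the template's
#'   error-instruction block.
#' @return A single prompt string.
#' @export
assemble_prompt <- function(template, section, examples = NULL,
                            error_instructions = NULL) {
  if (!is.null(examples) && nrow(examples) > 0L && !template$few_shot_slot) {
    stop("template '", template$template_id,
         "' has no few-shot slot but examples were supplied", call. = FALSE)
  }
  blocks <- c(paste0("## Task\n", template$task_description))
  if (!is.null(template$additional_guidance)) {
    blocks <- c(blocks, paste0("## Guidance\n", template$additional_guidance))
  }
  if (!is.null(examples) && nrow(examples) > 0L) {
    ex_lines <- vapply(seq_len(nrow(examples)), function(i) {
      sprintf("Example %d (cognitive decline: %s): %s", i,
              if (examples$label[i] == 1) "yes" else "no", examples$text[i])
    }, character(1))
    blocks <- c(blocks, paste0("## Examples\n",
                               paste(ex_lines, collapse = "\n")))
  }
  err <- if (!is.null(error_instructions)) error_instructions else
    template$error_instructions
  if (!is.null(err)) {
    blocks <- c(blocks, paste0("## Error instructions\n", err))
  }
  blocks <- c(blocks, paste0(
    "## Response format\n",
    "Respond in JSON with two fields: \"cognitive_decline\" (\"yes\" or ",
    "\"no\") and \"keywords\" (the keywords in the section that informed ",
    "the judgment)."))
  blocks <- c(blocks, sprintf("## Section\nSection ID: %s\nText: %s",
                              section$section_id, section$text))
  paste(blocks, collapse = "\n\n")
}

# ---- response parsing ------------------------------------------------------

first_balanced_json <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  start <- which(chars == "{")
  if (length(start) == 0L) return(NULL)
  depth <- 0L
  for (i in start[1L]:length(chars)) {
    if (chars[i] == "{") depth <- depth + 1L
    if (chars[i] == "}") {
      depth <- depth - 1L
      if (depth == 0L) {
        return(substr(raw, start[1L], i))
      }
    }
  }
  NULL
}

normalize_judgment <- function(value) {
  v <- tolower(trimws(as.character(value)[1]))
  if (v %in% c("yes", "true", "1", "y")) return(1L)
  if (v %in% c("no", "false", "0", "n")) return(0L)
  NA_integer_
}

#' Parse an LLM response into a verdict
#'
#' Every response is classified into one of three effectiveness categories:
#' `effective_parseable` when the first balanced JSON object carries a
#' recognisable judgment field and keyword list; `effective_unparseable` when
#' the free text still answers both questions (a judgment phrase and a
#' keyword enumeration are detected); `not_effective` otherwise. Parsing
#' never throws.
#'
#' @param raw Raw response text.
#' @return A `parsed_verdict`: list with `category`, `label` (binary or
#'   `NA`), `keywords` (character or `NULL`) and `raw`.
#' @export
parse_response <- function(raw) {
  raw <- if (is.null(raw) || length(raw) == 0L) "" else as.character(raw)[1]
  verdict <- function(category, label = NA_integer_, keywords = NULL) {
    structure(list(category = category, label = label, keywords = keywords,
                   raw = raw), class = "parsed_verdict")
  }
  blob <- first_balanced_json(raw)
  if (!is.null(blob)) {
    obj <- tryCatch(jsonlite::fromJSON(blob), error = function(e) NULL)
    if (is.list(obj)) {
      jfield <- grep("cogn|decline|label|judg|answer|decision|verdict",
                     names(obj), ignore.case = TRUE, value = TRUE)
      kfield <- grep("keyword", names(obj), ignore.case = TRUE, value = TRUE)
      if (length(jfield) > 0L && length(kfield) > 0L) {
        label <- normalize_judgment(obj[[jfield[1]]])
        if (!is.na(label)) {
          kw <- as.character(unlist(obj[[kfield[1]]]))
          kw <- kw[nzchar(kw) & tolower(kw) != "none"]
          return(verdict("effective_parseable", label, kw))
        }
      }
    }
  }
  low <- tolower(raw)
  affirmative <- grepl(
    "\\byes\\b|decline (is )?(present|detected|identified)|positive for cognitive",
    low)
  negative <- grepl(
    "\\bno\\b|\\babsent\\b|not (present|detected|identified)|\\bnegative\\b",
    low)
  keywords_answered <- grepl("keywords?\\s*[:=-]", low)
  if ((affirmative || negative) && keywords_answered) {
    return(verdict("effective_unparseable"))
  }
  verdict("not_effective")
}

#' Effective response rate of a verdict collection
#'
#' The fraction of responses that answered both the judgment and the keyword
#' question. By default both the parseable and the unparseable-but-effective
#' categories count as effective; set `count_unparseable = FALSE` to count
#' only parseable responses.
#'
#' @param verdicts List of `parsed_verdict` objects (or a verdict-log tibble
#'   with a `category` column).
#' @param count_unparseable Count `effective_unparseable` as effective?
#' @return Fraction in \[0, 1\].
#' @export
effective_response_rate <- function(verdicts, count_unparseable = TRUE) {
  cats <- if (is.data.frame(verdicts)) verdicts$category else
    vapply(verdicts, function(v) v$category, character(1))
  if (length(cats) == 0L) stop("no verdicts supplied", call. = FALSE)
  ok <- c("effective_parseable", if (count_unparseable) "effective_unparseable")
  mean(cats %in% ok)
}

# ---- scripted backend ------------------------------------------------------

#' A deterministic scripted LLM backend
#'
#' A test double standing in for a remote LLM. Its base judgment is a cue
#' heuristic: positive when the section text matches any screening keyword,
#' overridden to negative when a hard-negative cue from the phrase bank is
#' detected — exact, by construction, on corpora from [generate_corpus()].
#' Seeded flips then impose configurable error profiles: `flip_rate_overall`
#' applies everywhere, and `per_category_flip` overrides it on sections
#' carrying specific hard-negative cue categories. If the prompt's
#' error-instructions block names a category, that category's flip is
#' disabled — emulating an LLM that stops making an error it was warned
#' about. With probability `format_break_rate` the response carries the same
#' answers without JSON; with probability `mute_rate` it is a refusal. All
#' draws are keyed by (seed, section id), so identical prompts always yield
#' identical responses.
#'
#' @param lexicon Screening lexicon (default shipped lexicon).
#' @param bank Phrase bank used to detect hard-negative cues.
#' @param flip_rate_overall Baseline label-flip probability.
#' @param per_category_flip Named list: hard-negative category -> flip
#'   probability.
#' @param seed Integer seed.
#' @param format_break_rate Probability of a non-JSON but answer-bearing
#'   response.
#' @param mute_rate Probability of a refusal.
#' @param name Backend name used in logs.
#' @return A `scripted_backend`.
#' @export
scripted_backend <- function(lexicon = read_lexicon(),
                             bank = default_phrase_bank(lexicon),
                             flip_rate_overall = 0,
                             per_category_flip = list(),
                             seed = 1L,
                             format_break_rate = 0,
                             mute_rate = 0,
                             name = "scripted-llm") {
  rates <- c(flip_rate_overall, unlist(per_category_flip),
             format_break_rate, mute_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all scripted-backend rates must lie in [0, 1]", call. = FALSE)
  }
  bad_cat <- setdiff(names(per_category_flip),
                     names(bank$hard_negative_cues))
  if (length(bad_cat) > 0L) {
    stop("unknown hard-negative category in per_category_flip: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  lex <- lexicon[lexicon$source == "expert", ]
  pat_toks <- tokenize_text(lex$pattern)
  matcher <- list(pattern = lex$pattern,
                  stripped = sub("-$", "", lex$pattern),
                  is_stem = lex$is_stem,
                  single = tolower(ifelse(!lex$is_stem &
                                            lengths(pat_toks) == 1L,
                                          lex$pattern, NA_character_)),
                  stem = ifelse(lex$is_stem,
                                sub("-$", "", tolower(lex$pattern)),
                                NA_character_))
  structure(list(lexicon = lexicon, bank = bank, matcher = matcher,
                 flip_rate_overall = flip_rate_overall,
                 per_category_flip = per_category_flip,
                 seed = as.integer(seed),
                 format_break_rate = format_break_rate,
                 mute_rate = mute_rate, name = name),
            class = "scripted_backend")
}

#' Complete a prompt against a backend
#'
#' The backend contract: `llm_complete(backend, prompt, temperature)` returns
#' a response string, and at temperature 0 identical prompts yield identical
#' responses.
#'
#' @param backend A backend object.
#' @param prompt Prompt text.
#' @param temperature Sampling temperature (the pipeline always uses 0).
#' @return Response text.
#' @export
llm_complete <- function(backend, prompt, temperature = 0) {
  UseMethod("llm_complete")
}

hash_string <- function(x) {
  # FNV-1a over UTF-8 bytes, folded into a positive 31-bit integer
  bytes <- utf8ToInt(x)
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(h, b %% 256)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' @export
llm_complete.scripted_backend <- function(backend, prompt, temperature = 0) {
  m <- regmatches(prompt, regexec(
    "## Section\nSection ID: (\\S+)\nText: ", prompt))[[1]]
  if (length(m) < 2L) {
    stop("scripted backend: prompt has no recognisable target-section block",
         call. = FALSE)
  }
  section_id <- m[2]
  text <- sub("(?s).*## Section\nSection ID: \\S+\nText: ", "", prompt,
              perl = TRUE)

  # deterministic draws keyed by (seed, section_id); caller RNG untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed((backend$seed * 48271 + hash_string(section_id)) %% 2147483647)
  u <- stats::runif(3L)

  mt <- backend$matcher
  toks <- tokenize_text(text)[[1]]
  hits <- vapply(seq_along(mt$pattern), function(i) {
    if (!is.na(mt$single[i])) return(mt$single[i] %in% toks)
    if (!is.na(mt$stem[i])) return(any(startsWith(toks, mt$stem[i])))
    match_tokens(mt$pattern[i], FALSE, toks)
  }, logical(1))
  keywords <- mt$stripped[hits]
  base_label <- as.integer(any(hits))
  hn_cat <- detect_hard_negative_category(text, backend$bank)
  if (!is.na(hn_cat)) base_label <- 0L

  flip_p <- backend$flip_rate_overall
  if (!is.na(hn_cat) && hn_cat %in% names(backend$per_category_flip)) {
    flip_p <- backend$per_category_flip[[hn_cat]]
    instr <- regmatches(prompt, regexec(
      "(?s)## Error instructions\n(.*?)\n\n## ", prompt, perl = TRUE))[[1]]
    if (length(instr) >= 2L &&
        grepl(paste0("\\b", hn_cat, "\\b"), tolower(instr[2]))) {
      flip_p <- 0
    }
  }
  label <- if (u[3] < flip_p) 1L - base_label else base_label

  if (u[1] < backend$mute_rate) {
    return("I am unable to help with that.")
  }
  ans <- if (label == 1L) "yes" else "no"
  if (u[2] < backend$format_break_rate) {
    kw_txt <- if (length(keywords) > 0L)
      paste(keywords, collapse = ", ") else "none"
    return(sprintf("Judgment: %s. Keywords: %s", ans, kw_txt))
  }
  as.character(jsonlite::toJSON(
    list(cognitive_decline = ans, keywords = keywords), auto_unbox = TRUE))
}

# ---- classification over a corpus -----------------------------------------

#' Classify every section of a corpus with an LLM backend
#'
#' One prediction per section at temperature 0. Non-effective or unparseable
#' verdicts are retried once verbatim; if still not parseable the section is
#' predicted negative and flagged in the verdict log.
#'
#' @param backend A backend (e.g. [scripted_backend()]).
#' @param template A `prompt_template`.
#' @param corpus A `note_corpus`.
#' @param fewshot_strategy Optional [fewshot_strategy()] supplying examples.
#' @param error_instructions Optional error-instruction text.
#' @param model_name Name recorded on the prediction set.
#' @return List with `predictions` (a `prediction_set`) and `log` (a tibble:
#'   section_id, category, label, keywords, flagged, raw).
#' @export
classify_sections <- function(backend, template, corpus,
                              fewshot_strategy = NULL,
                              error_instructions = NULL,
                              model_name = NULL) {
  if (is.null(model_name)) {
    model_name <- if (!is.null(backend$name)) backend$name else "llm"
  }
  n <- nrow(corpus)
  labels <- integer(n)
  cats <- character(n)
  kw <- vector("list", n)
  raws <- character(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    section <- corpus[i, ]
    examples <- if (!is.null(fewshot_strategy)) {
      resolve_examples(fewshot_strategy, section)
    } else NULL
    prompt <- assemble_prompt(template, section, examples = examples,
                              error_instructions = error_instructions)
    v <- tryCatch(
      parse_response(llm_complete(backend, prompt, temperature = 0)),
      error = function(e) {
        stop("backend failed on section ", section$section_id, ": ",
             conditionMessage(e), call. = FALSE)
      })
    if (v$category != "effective_parseable") {
      v <- parse_response(llm_complete(backend, prompt, temperature = 0))
    }
    cats[i] <- v$category
    raws[i] <- v$raw
    if (v$category == "effective_parseable") {
      labels[i] <- v$label
      kw[[i]] <- v$keywords
    } else {
      labels[i] <- 0L
      kw[[i]] <- character(0)
      flagged[i] <- TRUE
    }
  }
  log <- tibble::tibble(section_id = corpus$section_id, category = cats,
                        label = labels, keywords = kw, flagged = flagged,
                        raw = raws)
  list(predictions = prediction_set(corpus$section_id, labels,
                                    model_name = model_name),
       log = log)
}

#' Accuracy of a prediction set against gold labels
#'
#' The template/backend selection criterion: (TP + TN) / N.
#'
#' @param pred A `prediction_set`.
#' @param gold A `note_corpus` with gold labels.
#' @return Fraction of sections predicted correctly.
#' @export
selection_accuracy <- function(pred, gold) {
  aligned <- align_predictions(pred, gold)
  mean(aligned$pred == aligned$gold)
}

#' Build an error-analysis-based instruction block
#'
#' Produces a paragraph enumerating each error category observed in a set of
#' misclassified sections, with one exemplar cue per category, for inclusion
#' in a prompt. Deterministic given input order.
#'
#' @param error_cases A data frame of misclassified sections with columns
#'   `text`, `gold`, `predicted` and `category` (hard-negative cue category
#'   or `NA`; see [detect_hard_negative_category()]).
#' @param category_notes Optional named list overriding the built-in caution
#'   text per category.
#' @return A single text block.
#' @export
build_error_instructions <- function(error_cases, category_notes = list()) {
  if (is.null(error_cases) || nrow(error_cases) == 0L) {
    stop("at least one error case is required", call. = FALSE)
  }
  default_notes <- list(
    improvement = paste("statements that cognition is improving do not",
                        "indicate progressive decline"),
    transient = paste("transient symptoms, such as temporary forgetfulness",
                      "due to medication, are negative"),
    reversible = paste("reversible episodes, such as confusion shortly after",
                       "surgery, are negative"),
    negated = paste("negated mentions, such as denial or absence of memory",
                    "problems, are negative"),
    uncertain = paste("vague or uncertain mentions without corroboration",
                      "are negative"),
    general = "do not infer decline from unrelated clinical conditions")
  cat_col <- as.character(error_cases$category)
  cat_col[is.na(cat_col)] <- "general"
  cats <- unique(cat_col)
  lines <- vapply(cats, function(cat) {
    exemplar <- error_cases$text[cat_col == cat][1]
    exemplar <- substr(exemplar, 1L, 80L)
    note <- if (!is.null(category_notes[[cat]])) category_notes[[cat]] else
      default_notes[[cat]]
    if (is.null(note)) note <- default_notes$general
    sprintf("- %s errors (e.g., \"%s\"): %s.", cat, exemplar, note)
  }, character(1))
  paste0("In previous runs you made the following kinds of errors; pay ",
         "attention to them when judging:\n", paste(lines, collapse = "\n"))
}

#' Rank prompt templates for a backend
#'
#' Computes each template's effective response rate on a small tuning sample
#' and its accuracy on a selection corpus, and ranks by effective response
#' rate then accuracy — the selection report of the template-engineering
#' loop.
#'
#' @param templates Named list of `prompt_template` objects.
#' @param backend A backend.
#' @param tuning_corpus Small corpus for the effective-response-rate check.
#' @param selection_corpus Corpus for the accuracy criterion.
#' @return A tibble (template_id, effective_response_rate, accuracy), ranked.
#' @export
rank_templates <- function(templates, backend, tuning_corpus,
                           selection_corpus) {
  rows <- lapply(templates, function(tpl) {
    tune <- classify_sections(backend, tpl, tuning_corpus)
    sel <- classify_sections(backend, tpl, selection_corpus)
    tibble::tibble(template_id = tpl$template_id,
                   effective_response_rate =
                     effective_response_rate(tune$log),
                   accuracy = selection_accuracy(sel$predictions,
                                                 selection_corpus))
  })
  out <- do.call(rbind, rows)
  out[order(-out$effective_response_rate, -out$accuracy,
            out$template_id), ]
}

#' Write or read a verdict log as JSONL
#'
#' @param log A verdict-log tibble from [classify_sections()].
#' @param path Output path.
#' @return `path` invisibly; `read_verdict_log()` returns the tibble.
#' @export
write_verdict_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(list(section_id = log$section_id[i],
                          category = log$category[i],
                          label = log$label[i],
                          keywords = log$keywords[[i]],
                          flagged = log$flagged[i],
                          raw = log$raw[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_verdict_log
#' @export
read_verdict_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    section_id = vapply(rows, `[[`, character(1), "section_id"),
    category = vapply(rows, `[[`, character(1), "category"),
    label = vapply(rows, function(r) as.integer(r$label), integer(1)),
    keywords = lapply(rows, function(r) as.character(r$keywords)),
    flagged = vapply(rows, function(r) isTRUE(r$flagged), logical(1)),
    raw = vapply(rows, `[[`, character(1), "raw"))
}

#' Write or read prompt templates as YAML
#'
#' @param templates Named list of `prompt_template` objects.
#' @param path YAML path.
#' @return `path` invisibly; `read_templates()` returns the named list.
#' @export
write_templates <- function(templates, path) {
  yaml::write_yaml(lapply(templates, unclass), path)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  lapply(yaml::read_yaml(path), function(x) do.call(prompt_template, x))
}
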