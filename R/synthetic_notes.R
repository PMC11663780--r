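#' Generator configuration for synthetic note corpora
#'
#' Character lengths follow a log-normal target clamped to
#' `[length_min, length_max]`; the log-normal is chosen for the strong right
#' skew real section lengths show (ranges far exceeding the mean). Patients
#' receive geometrically distributed numbers of consecutive sections with the
#' requested mean. `label_flip_rate` optionally emulates annotation noise by
#' flipping labels after composition (default 0: labels are generated, not
#' annotated).
#'
#' @param n_sections Number of sections to generate.
#' @param positive_rate Fraction of positive (cognitive-decline) sections.
#' @param hard_negative_share Fraction of negatives carrying a hard-negative
#'   cue; the remaining negatives are keyword-free filler.
#' @param length_log_mean,length_log_sd Log-normal parameters of the target
#'   character length.
#' @param length_min,length_max Character-length bounds (code points).
#' @param sections_per_patient_mean Mean sections per patient.
#' @param label_flip_rate Probability of flipping each label after
#'   composition.
#' @param seed Integer seed; a fixed seed makes generation byte-identical.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_sections,
                             positive_rate,
                             hard_negative_share = 0.3,
                             length_log_mean = log(850) - 0.5,
                             length_log_sd = 1.0,
                             length_min = 26,
                             length_max = 9323,
                             sections_per_patient_mean = 2.5,
                             label_flip_rate = 0,
                             seed = 1L) {
  cfg <- list(n_sections = n_sections, positive_rate = positive_rate,
              hard_negative_share = hard_negative_share,
              length_log_mean = length_log_mean,
              length_log_sd = length_log_sd,
              length_min = length_min, length_max = length_max,
              sections_per_patient_mean = sections_per_patient_mean,
              label_flip_rate = label_flip_rate, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid generator config: field '", field, "' ", why, call. = FALSE)
  }
  if (!is.numeric(cfg$n_sections) || cfg$n_sections < 1) {
    bad("n_sections", "must be a positive integer")
  }
  if (!is.numeric(cfg$positive_rate) || cfg$positive_rate <= 0 ||
      cfg$positive_rate >= 1) {
    bad("positive_rate", "must lie in (0, 1)")
  }
  if (cfg$hard_negative_share < 0 || cfg$hard_negative_share > 1) {
    bad("hard_negative_share", "must lie in [0, 1]")
  }
  if (cfg$length_min < 1) bad("length_min", "must be >= 1")
  if (cfg$length_min >= cfg$length_max) {
    bad("length_min", "must be smaller than length_max")
  }
  if (cfg$sections_per_patient_mean < 1) {
    bad("sections_per_patient_mean", "must be >= 1")
  }
  if (cfg$label_flip_rate < 0 || cfg$label_flip_rate > 1) {
    bad("label_flip_rate", "must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Preset configs emulating the development and test corpora
#'
#' `dev_corpus_config()` emulates a keyword-filtered development corpus:
#' 4949 sections, 29.4% positive, mean length 850 characters in
#' \[26, 9323\], and every negative carrying a hard-negative cue (a section
#' that survived keyword screening necessarily contains a screening
#' keyword). `test_corpus_config()` emulates an unfiltered test corpus:
#' 1996 sections, 3.5% positive, mean length 464 characters in
#' \[26, 14740\], with only a small share of hard negatives.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
dev_corpus_config <- function(seed = 1L, ...) {
  args <- list(n_sections = 4949L, positive_rate = 0.294,
               hard_negative_share = 1.0,
               length_log_mean = log(850) - 0.5, length_log_sd = 1.0,
               length_min = 26, length_max = 9323, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}

#' @rdname dev_corpus_config
#' @export
test_corpus_config <- function(seed = 2L, ...) {
  args <- list(n_sections = 1996L, positive_rate = 0.035,
               hard_negative_share = 0.05,
               length_log_mean = log(464) - 0.5, length_log_sd = 1.0,
               length_min = 26, length_max = 14740, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}

build_filler <- function(bank, n_chars) {
  if (n_chars <= 0) return("")
  parts <- character(0)
  total <- 0L
  while (total < n_chars) {
    s <- sample(bank$filler_sentences, 1L)
    parts <- c(parts, s)
    total <- total + nchar(s) + 1L
  }
  substr(paste(parts, collapse = " "), 1L, n_chars)
}

#' Compose one synthetic section text
#'
#' Positive sections embed one or more positive cue phrases; hard-negative
#' sections embed exactly one hard-negative cue; plain negatives are filler
#' only (and therefore keyword-free). Filler is added around the cue to hit
#' the target length; the result is trimmed to the target but never below the
#' embedded cue, then clamped to the configured bounds. Draws come from the
#' current RNG state.
#'
#' @param label 0 or 1.
#' @param bank A `phrase_bank`.
#' @param target_length Target length in characters.
#' @param hard_negative For `label = 0`, embed a hard-negative cue?
#' @param hn_category Hard-negative category, or `NULL` to draw one.
#' @param length_min,length_max Clamping bounds.
#' @return A single text string.
#' @export
compose_section_text <- function(label, bank, target_length,
                                 hard_negative = FALSE, hn_category = NULL,
                                 length_min = 26, length_max = 9323) {
  target <- max(length_min, min(round(target_length), length_max))
  cue <- NULL
  if (label == 1) {
    n_cues <- 1L + stats::rbinom(1L, 2L, 0.3)
    cats <- sample(names(bank$positive_cues), n_cues, replace = TRUE)
    cue <- paste(vapply(cats, function(cat) {
      sample(bank$positive_cues[[cat]], 1L)
    }, character(1)), collapse = " ")
  } else if (hard_negative) {
    if (is.null(hn_category)) {
      hn_category <- sample(names(bank$hard_negative_cues), 1L)
    }
    cue <- sample(bank$hard_negative_cues[[hn_category]], 1L)
  }
  if (is.null(cue)) {
    return(build_filler(bank, target))
  }
  if (nchar(cue) >= target) {
    return(substr(cue, 1L, max(nchar(cue), length_min)))
  }
  budget <- target - nchar(cue)
  pre_len <- sample.int(budget + 1L, 1L) - 1L
  post_len <- budget - pre_len
  pre <- build_filler(bank, pre_len - 1L)   # -1 for the joining space
  post <- build_filler(bank, post_len - 1L)
  parts <- c(pre, cue, post)
  text <- paste(parts[nzchar(parts)], collapse = " ")
  cue_end <- if (nzchar(pre)) nchar(pre) + 1L + nchar(cue) else nchar(cue)
  substr(text, 1L, max(target, cue_end))
}

#' Generate a labelled synthetic note corpus
#'
#' Draws labels as independent Bernoulli(`positive_rate`) trials, assigns a
#' hard-negative cue to the configured share of negatives, composes each
#' section from the phrase bank at a clamped log-normal target length, and
#' deals consecutive sections to patients with geometric sizes. Generation is
#' byte-identical for a fixed seed.
#'
#' @param config A [generator_config()].
#' @param bank A `phrase_bank` (default [default_phrase_bank()]).
#' @param name Corpus name.
#' @return A `note_corpus`.
#' @export
generate_corpus <- function(config, bank = default_phrase_bank(),
                            name = "synthetic") {
  validate_generator_config(config)
  if (!inherits(bank, "phrase_bank")) {
    stop("bank must be a phrase_bank", call. = FALSE)
  }
  n <- as.integer(config$n_sections)
  set.seed(config$seed)
  labels <- stats::rbinom(n, 1L, config$positive_rate)
  hard <- labels == 0L &
    stats::runif(n) < config$hard_negative_share
  targets <- stats::rlnorm(n, config$length_log_mean, config$length_log_sd)
  texts <- character(n)
  for (i in seq_len(n)) {
    texts[i] <- compose_section_text(labels[i], bank, targets[i],
                                     hard_negative = hard[i],
                                     length_min = config$length_min,
                                     length_max = config$length_max)
  }
  if (config$label_flip_rate > 0) {
    flip <- stats::runif(n) < config$label_flip_rate
    labels[flip] <- 1L - labels[flip]
  }
  # deal sections to patients with geometric sizes, mean sections_per_patient
  p_geom <- 1 / config$sections_per_patient_mean
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, 1L + stats::rgeom(max(16L, ceiling(n * p_geom)), p_geom))
  }
  patient_idx <- rep(seq_along(sizes), sizes)[seq_len(n)]
  note_corpus(
    tibble::tibble(
      section_id = sprintf("S%06d", seq_len(n)),
      patient_id = sprintf("P%05d", patient_idx),
      text = texts,
      label = labels),
    name = name)
}

#' A linearly separable diagnostic corpus
#'
#' Generates short sections of neutral tokens in which a single planted
#' keyword appears in every positive section and in no negative section, so
#' the planted keyword predicts the label perfectly. A few other screening
#' keywords are sprinkled rarely and label-independently as distractors.
#' Used to verify that the classifiers can learn a clean signal and that
#' every interpretation channel recovers the planted keyword.
#'
#' @param n Number of sections.
#' @param positive_rate Fraction of positives.
#' @param seed Integer seed.
#' @param keyword The planted keyword (default `"dementia"`, a screening
#'   keyword, so the scripted backend cites it).
#' @param distractors Other keywords sprinkled rarely in either class.
#' @return A `note_corpus`.
#' @export
separable_corpus <- function(n = 500L, positive_rate = 0.3, seed = 1L,
                             keyword = "dementia",
                             distractors = c("sleep", "mood", "exam",
                                             "score", "drive", "question",
                                             "montreal")) {
  neutral <- c("patient", "visit", "clinic", "stable", "routine", "plan",
               "followup", "medication", "review", "blood", "pressure",
               "normal", "daily", "reports", "today", "continues",
               "tolerated", "well", "without", "issues")
  set.seed(seed)
  labels <- stats::rbinom(n, 1L, positive_rate)
  texts <- vapply(seq_len(n), function(i) {
    words <- sample(neutral, 8L + sample.int(6L, 1L), replace = TRUE)
    if (labels[i] == 1L) {
      pos <- sample.int(length(words), 1L)
      words <- append(words, keyword, after = pos)
    }
    if (stats::runif(1) < 0.03) {
      words <- append(words, sample(distractors, 1L),
                      after = sample.int(length(words), 1L))
    }
    paste(words, collapse = " ")
  }, character(1))
  note_corpus(
    tibble::tibble(section_id = sprintf("X%05d", seq_len(n)),
                   patient_id = sprintf("P%05d", seq_len(n)),
                   text = texts, label = labels),
    name = "separable")
}

#' Read or write a generator config as YAML
#'
#' @param config A `generator_config`.
#' @param path YAML file path.
#' @return `read_generator_config()` returns a `generator_config`;
#'   `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  do.call(generator_config, yaml::read_yaml(path))
}
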