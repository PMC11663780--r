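#' Construct a note corpus
#'
#' A corpus is an ordered collection of labelled clinical-note sections. It is
#' represented as a tibble with columns `section_id`, `patient_id`, `text` and
#' `label` (1 = cognitive decline, 0 = no cognitive decline), carrying a
#' `corpus_name` attribute and class `note_corpus`.
#'
#' @param sections A data frame with columns `section_id`, `patient_id`,
#'   `text`, `label`.
#' @param name Corpus name (a short string used in reports).
#' @return A `note_corpus` tibble.
#' @export
note_corpus <- function(sections, name = "corpus") {
  required <- c("section_id", "patient_id", "text", "label")
  missing_cols <- setdiff(required, names(sections))
  if (length(missing_cols) > 0L) {
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(sections[required])
  out$section_id <- as.character(out$section_id)
  out$patient_id <- as.character(out$patient_id)
  out$text <- as.character(out$text)
  out$label <- as.integer(out$label)
  if (anyDuplicated(out$section_id)) {
    dup <- out$section_id[duplicated(out$section_id)][1L]
    stop("duplicate section_id in corpus: ", dup, call. = FALSE)
  }
  if (any(is.na(out$label)) || !all(out$label %in% c(0L, 1L))) {
    bad <- which(is.na(out$label) | !(out$label %in% c(0L, 1L)))[1L]
    stop("label outside {0,1} at row ", bad, call. = FALSE)
  }
  if (any(!nzchar(out$text))) {
    stop("empty text at row ", which(!nzchar(out$text))[1L], call. = FALSE)
  }
  attr(out, "corpus_name") <- name
  class(out) <- c("note_corpus", class(out))
  out
}

#' @export
print.note_corpus <- function(x, ...) {
  cat(sprintf("<note_corpus '%s'> %d sections, %d patients, positive rate %.3f\n",
              corpus_name(x), nrow(x), length(unique(x$patient_id)),
              positive_rate(x)))
  NextMethod()
}

#' Corpus name
#' @param corpus A `note_corpus`.
#' @return The corpus name string.
#' @export
corpus_name <- function(corpus) {
  nm <- attr(corpus, "corpus_name")
  if (is.null(nm)) "corpus" else nm
}

#' Fraction of positive sections in a corpus
#' @param corpus A `note_corpus`.
#' @return Mean of the binary labels.
#' @export
positive_rate <- function(corpus) mean(corpus$label)

#' Read a corpus from JSONL or CSV
#'
#' JSONL files hold one object per line with fields `section_id`,
#' `patient_id`, `text`, `label`; CSV files hold the same columns. Validation
#' failures report the offending line.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; defaults from the file extension.
#' @param name Corpus name; defaults to the file base name.
#' @return A `note_corpus`.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv"), name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (missing(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) NULL)
      if (is.null(obj)) stop("malformed JSON at line ", i, call. = FALSE)
      miss <- setdiff(c("section_id", "patient_id", "text", "label"), names(obj))
      if (length(miss) > 0L) {
        stop("line ", i, ": missing field(s) ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      if (!(as.character(obj$label) %in% c("0", "1"))) {
        stop("line ", i, ": label outside {0,1}", call. = FALSE)
      }
      rows[[i]] <- tibble::tibble(section_id = as.character(obj$section_id),
                                  patient_id = as.character(obj$patient_id),
                                  text = as.character(obj$text),
                                  label = as.integer(obj$label))
    }
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          encoding = "UTF-8", stringsAsFactors = FALSE)
    miss <- setdiff(c("section_id", "patient_id", "text", "label"), names(df))
    if (length(miss) > 0L) {
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    bad <- which(!(df$label %in% c("0", "1")))
    if (length(bad) > 0L) {
      # +1 for the header line
      stop("line ", bad[1L] + 1L, ": label outside {0,1}", call. = FALSE)
    }
    df$label <- as.integer(df$label)
  }
  dup <- which(duplicated(df$section_id))
  if (length(dup) > 0L) {
    stop("duplicate section_id at line ", dup[1L] + (format == "csv"),
         ": ", df$section_id[dup[1L]], call. = FALSE)
  }
  note_corpus(df, name = name)
}

#' Write a corpus to JSONL or CSV
#'
#' JSONL output round-trips byte-identically through [read_corpus()].
#'
#' @param corpus A `note_corpus`.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  if (missing(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(list(section_id = corpus$section_id[i],
                            patient_id = corpus$patient_id[i],
                            text = corpus$text[i],
                            label = corpus$label[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(as.data.frame(corpus), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

# ---- keyword lexicon -------------------------------------------------------

#' Read a keyword lexicon
#'
#' A lexicon is a two-column TSV (`pattern`, `source`). Patterns ending in a
#' hyphen are word-prefix stems (e.g. `cognit-` matches "cognitive" and
#' "cognition"); all other patterns match whole word tokens, case
#' insensitively. Multiword patterns match consecutive token runs. Sources
#' identify where each entry came from: `expert`, `boosted_trees`,
#' `attention_net` or `llm`.
#'
#' @param path TSV path; defaults to the lexicon shipped with the package.
#' @return A `keyword_lexicon` tibble with columns `pattern`, `is_stem`,
#'   `source`.
#' @export
read_lexicon <- function(path = system.file("extdata", "keyword_lexicon.tsv",
                                            package = "cognote")) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("pattern", "source") %in% names(df))) {
    stop("lexicon must have columns 'pattern' and 'source'", call. = FALSE)
  }
  keyword_lexicon(df$pattern, df$source)
}

#' Construct a keyword lexicon
#'
#' @param pattern Character vector of patterns (trailing `-` marks a stem).
#' @param source Character vector of sources, recycled if length 1.
#' @return A `keyword_lexicon` tibble.
#' @export
keyword_lexicon <- function(pattern, source = "expert") {
  if (length(source) == 1L) source <- rep(source, length(pattern))
  is_stem <- grepl("-$", pattern)
  stripped <- sub("-$", "", pattern)
  if (any(!nzchar(stripped))) stop("empty pattern after stripping hyphen",
                                   call. = FALSE)
  if (anyDuplicated(paste(pattern, source, sep = "\r"))) {
    stop("duplicate (pattern, source) pair in lexicon", call. = FALSE)
  }
  out <- tibble::tibble(pattern = pattern, is_stem = is_stem, source = source)
  class(out) <- c("keyword_lexicon", class(out))
  out
}

#' Tokenize text for keyword matching
#'
#' Lower-cases and splits on any non-alphanumeric character. Character
#' positions are Unicode code points.
#'
#' @param text Character vector.
#' @return A list of token character vectors.
#' @export
tokenize_text <- function(text) {
  toks <- strsplit(tolower(text), "[^[:alnum:]]+")
  lapply(toks, function(t) t[nzchar(t)])
}

match_tokens <- function(pattern, is_stem, tokens) {
  pat <- tolower(pattern)
  if (is_stem) {
    pat <- sub("-$", "", pat)
    return(any(startsWith(tokens, pat)))
  }
  parts <- tokenize_text(pat)[[1]]
  if (length(parts) <= 1L) return(parts %in% tokens)
  if (length(tokens) < length(parts)) return(FALSE)
  joined <- paste0(" ", paste(tokens, collapse = " "), " ")
  grepl(paste0(" ", paste(parts, collapse = " "), " "), joined, fixed = TRUE)
}

#' Test whether a lexicon entry matches a text
#'
#' Matching is case-insensitive over word tokens: stems (patterns with a
#' trailing hyphen) match any token with that prefix; plain patterns match
#' whole tokens only, so `memory` does not match "memorial".
#'
#' @param pattern A single lexicon pattern (trailing `-` marks a stem).
#' @param text A single text string.
#' @return `TRUE` if the entry matches.
#' @export
match_keyword <- function(pattern, text) {
  match_tokens(pattern, grepl("-$", pattern), tokenize_text(text)[[1]])
}

#' Which sections of a corpus match a lexicon slice
#'
#' @param corpus A `note_corpus` (or character vector of texts).
#' @param lexicon A `keyword_lexicon`.
#' @param source Lexicon source to use, or `NULL` for all entries.
#' @return Logical vector, one element per section.
#' @export
lexicon_matches <- function(corpus, lexicon, source = "expert") {
  texts <- if (is.character(corpus)) corpus else corpus$text
  lex <- if (is.null(source)) lexicon else lexicon[lexicon$source %in% source, ]
  if (nrow(lex) == 0L) {
    stop("lexicon has no entries for source: ",
         paste(source, collapse = ", "), call. = FALSE)
  }
  toks <- tokenize_text(texts)
  pat_toks <- tokenize_text(lex$pattern)
  single <- !lex$is_stem & lengths(pat_toks) == 1L
  words <- unlist(pat_toks[single])
  stems <- sub("-$", "", tolower(lex$pattern[lex$is_stem]))
  other <- lex[!single & !lex$is_stem, , drop = FALSE]
  vapply(toks, function(t) {
    if (length(t) == 0L) return(FALSE)
    if (length(words) > 0L && any(words %in% t)) return(TRUE)
    for (s in stems) if (any(startsWith(t, s))) return(TRUE)
    for (i in seq_len(nrow(other))) {
      if (match_tokens(other$pattern[i], FALSE, t)) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Keyword screening of a corpus
#'
#' Retains exactly the sections where at least one lexicon entry of the
#' requested source matches, preserving order, text and labels. The number of
#' retained sections is recorded in the `retained` attribute.
#'
#' @param corpus A `note_corpus`.
#' @param lexicon A `keyword_lexicon`.
#' @param source Lexicon source to filter with (default `"expert"`).
#' @return The filtered `note_corpus`.
#' @export
keyword_filter <- function(corpus, lexicon, source = "expert") {
  keep <- lexicon_matches(corpus, lexicon, source = source)
  out <- corpus[keep, , drop = FALSE]
  attr(out, "corpus_name") <- corpus_name(corpus)
  attr(out, "retained") <- sum(keep)
  class(out) <- unique(c("note_corpus", class(out)))
  out
}
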