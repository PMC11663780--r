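#' Mean-plus-two-standard-deviations selection
#'
#' Selects the indices whose value strictly exceeds the mean plus twice the
#' sample (n-1) standard deviation of the whole vector. With a constant
#' vector the standard deviation is 0 and nothing is selected.
#'
#' @param values Numeric vector of at least two values.
#' @return Integer vector of selected indices.
#' @export
mean2sd_select <- function(values) {
  if (length(values) < 2L) {
    stop("mean2sd_select needs at least two values", call. = FALSE)
  }
  which(values > mean(values) + 2 * stats::sd(values))
}

keyword_rows <- function(keyword, source, value, selected) {
  tibble::tibble(keyword = as.character(keyword), source = source,
                 value = as.numeric(value), selected = selected)
}

#' Keywords the LLM relied on, by citation frequency
#'
#' Counts case-folded, whitespace-trimmed keyword citations across all
#' parseable verdicts (multiword keywords kept intact) and flags those whose
#' count exceeds the mean citation count plus two standard deviations.
#'
#' @param verdict_log Verdict-log tibble from [classify_sections()].
#' @return Keyword-importance rows (keyword, source, value, selected).
#' @export
llm_keywords <- function(verdict_log) {
  ok <- verdict_log$category == "effective_parseable"
  if (!any(ok)) {
    warning("no parseable verdicts; empty LLM keyword table")
    return(keyword_rows(character(0), character(0), numeric(0), logical(0)))
  }
  kw <- tolower(trimws(unlist(verdict_log$keywords[ok])))
  kw <- kw[nzchar(kw)]
  if (length(kw) == 0L) {
    return(keyword_rows(character(0), character(0), numeric(0), logical(0)))
  }
  counts <- sort(table(kw), decreasing = TRUE)
  values <- as.numeric(counts)
  selected <- rep(FALSE, length(values))
  if (length(values) >= 2L) selected[mean2sd_select(values)] <- TRUE
  keyword_rows(names(counts), "llm", values, selected)
}

#' Keywords the attention network concentrates on
#'
#' Within each section, selects the tokens whose attention weight exceeds
#' that section's mean weight plus two within-section standard deviations,
#' then aggregates across the corpus by counting the sections in which each
#' token was selected. Tokens selected in at least `floor` sections are
#' flagged.
#'
#' @param model A fitted `attention_net_model`.
#' @param corpus A `note_corpus`.
#' @param floor Minimum section count for the aggregate flag (default 2).
#' @return Keyword-importance rows (keyword, source, value = section count,
#'   selected).
#' @export
attention_keywords <- function(model, corpus, floor = 2L) {
  if (!inherits(model, "attention_net_model")) {
    stop("attention_keywords requires a fitted attention_net_model",
         call. = FALSE)
  }
  hits <- list()
  for (i in seq_len(nrow(corpus))) {
    w <- attention_trace(model, corpus$text[i])
    if (length(w) < 2L) next
    sel <- mean2sd_select(as.numeric(w))
    if (length(sel) > 0L) hits[[length(hits) + 1L]] <- unique(names(w)[sel])
  }
  if (length(hits) == 0L) {
    return(keyword_rows(character(0), character(0), numeric(0), logical(0)))
  }
  counts <- sort(table(unlist(hits)), decreasing = TRUE)
  keyword_rows(names(counts), "attention_net", as.numeric(counts),
               as.numeric(counts) >= floor)
}

#' Keywords the boosted-trees model splits on, by information gain
#'
#' Applies the mean-plus-two-standard-deviations rule to the per-feature
#' total split gain over the full vocabulary (features never split on count
#' as zero gain), and maps selected features back to their terms. Rows are
#' returned for features with non-zero gain.
#'
#' @param model A `boosted_trees_model` with its recorded gain table.
#' @return Keyword-importance rows (keyword, source, value = gain,
#'   selected).
#' @export
gain_keywords <- function(model) {
  if (!inherits(model, "boosted_trees_model") || is.null(model$gain)) {
    stop("gain_keywords requires a boosted_trees_model with a gain table",
         call. = FALSE)
  }
  gain <- model$gain
  selected_idx <- if (length(gain) >= 2L) mean2sd_select(as.numeric(gain))
    else integer(0)
  keep <- which(gain > 0)
  ord <- keep[order(-gain[keep], names(gain)[keep])]
  keyword_rows(names(gain)[ord], "boosted_trees", gain[ord],
               ord %in% selected_idx)
}

#' Merge model keyword tables with the expert lexicon
#'
#' Builds the combined keyword-importance report: one row per (keyword,
#' source), expert entries always included (selected, no value), model rows
#' restricted to their selected keywords, stably sorted by source then
#' keyword.
#'
#' @param tables List of keyword-importance row tibbles.
#' @param expert_lexicon A `keyword_lexicon`; its `expert` entries are
#'   added.
#' @param selected_only Keep only selected model rows (default `TRUE`).
#' @return A keyword-importance tibble.
#' @export
merge_keyword_report <- function(tables, expert_lexicon = read_lexicon(),
                                 selected_only = TRUE) {
  model_rows <- if (length(tables) > 0L) do.call(rbind, tables) else
    keyword_rows(character(0), character(0), numeric(0), logical(0))
  if (selected_only && nrow(model_rows) > 0L) {
    model_rows <- model_rows[model_rows$selected, , drop = FALSE]
  }
  expert <- expert_lexicon[expert_lexicon$source == "expert", ]
  expert_rows <- keyword_rows(expert$pattern, "expert",
                              rep(NA_real_, nrow(expert)),
                              rep(TRUE, nrow(expert)))
  out <- rbind(expert_rows, model_rows)
  src_order <- match(out$source, c("expert", "boosted_trees",
                                   "attention_net", "llm"))
  out[order(src_order, out$keyword, method = "radix"), ]
}

#' Write or read a keyword-importance report as TSV
#'
#' @param report Keyword-importance tibble.
#' @param path TSV path.
#' @return `path` invisibly; the reader returns the tibble.
#' @export
write_keyword_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = TRUE, qmethod = "double")
  invisible(path)
}

#' @rdname write_keyword_report
#' @export
read_keyword_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(keyword = "character",
                                         source = "character",
                                         value = "numeric",
                                         selected = "logical"))
  tibble::as_tibble(df)
}

#' Render the keyword report as a four-row text table
#'
#' One row per source, keywords comma-joined — the layout of a combined
#' expert/model keyword table.
#'
#' @param report Keyword-importance tibble.
#' @return Character vector of table lines.
#' @export
format_keyword_table <- function(report) {
  sources <- c(expert = "Expert curated", boosted_trees = "Boosted trees",
               attention_net = "Attention net", llm = "LLM")
  vapply(names(sources), function(src) {
    kws <- report$keyword[report$source == src & report$selected]
    sprintf("%-15s | %s", sources[[src]],
            if (length(kws)) paste(kws, collapse = ", ") else "(none)")
  }, character(1))
}
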