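# Shared fixtures: small corpora, banks and independent brute-force oracles.

fixture_lexicon <- function() read_lexicon()

fixture_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- default_phrase_bank(fixture_lexicon())
    bank
  }
})

tiny_corpus <- function(texts, labels, patients = NULL) {
  n <- length(texts)
  note_corpus(tibble::tibble(
    section_id = sprintf("t%03d", seq_len(n)),
    patient_id = if (is.null(patients)) sprintf("p%03d", seq_len(n)) else
      patients,
    text = texts, label = labels), name = "tiny")
}

# brute-force keyword matcher used as the filtering oracle: regex scan over
# word boundaries, independent of the tokenizing implementation
oracle_lexicon_match <- function(lexicon, text, source = "expert") {
  lex <- lexicon[lexicon$source == source, ]
  low <- tolower(text)
  for (i in seq_len(nrow(lex))) {
    pat <- tolower(lex$pattern[i])
    rx <- if (lex$is_stem[i]) {
      paste0("(^|[^[:alnum:]])", sub("-$", "", pat))
    } else {
      parts <- strsplit(pat, "[^[:alnum:]]+")[[1]]
      parts <- parts[nzchar(parts)]
      paste0("(^|[^[:alnum:]])", paste(parts, collapse = "[^[:alnum:]]+"),
             "($|[^[:alnum:]])")
    }
    if (grepl(rx, low)) return(TRUE)
  }
  FALSE
}

# independent confusion-metric oracle: direct formula transcription
oracle_metrics <- function(tp, fp, fn, tn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_ else
    if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       specificity = div(tn, tn + fp), npv = div(tn, tn + fn),
       accuracy = div(tp + tn, tp + fp + fn + tn))
}

# independent three-set overlap oracle via a full membership table
oracle_overlap <- function(a, b, c) {
  elems <- unique(c(a, b, c))
  ina <- elems %in% a; inb <- elems %in% b; inc <- elems %in% c
  list(a = sum(ina), b = sum(inb), c = sum(inc),
       ab = sum(ina & inb), ac = sum(ina & inc), bc = sum(inb & inc),
       abc = sum(ina & inb & inc), union = length(elems))
}

# independent mean + 2 sd oracle
oracle_mean2sd <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  which(v > m + 2 * s)
}

# independent cosine kNN oracle: exhaustive similarity sort with stable ties
oracle_knn <- function(q, x, k) {
  sims <- vapply(seq_len(nrow(x)), function(i) {
    nx <- sqrt(sum(x[i, ]^2)); nq <- sqrt(sum(q^2))
    if (nx == 0 || nq == 0) 0 else sum(x[i, ] * q) / (nx * nq)
  }, numeric(1))
  order(-sims)[seq_len(k)]
}

small_net_hyper <- function(epochs = 5L) {
  attention_hyper(d_embed = 16L, d_conv = 16L, d_hidden = 8L, d_attn = 8L,
                  max_tokens = 32L, epochs = epochs)
}

# default-size net, short truncation: used where attention interpretability
# matters (the larger conv/hidden stages localise attention more reliably)
fixture_net_hyper <- function(epochs = 5L) {
  attention_hyper(max_tokens = 32L, epochs = epochs)
}
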