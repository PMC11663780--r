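#' Construct a prediction set
#'
#' One model's binary predictions over a corpus, aligned by section id.
#'
#' @param section_id Character vector of unique section ids.
#' @param label Integer vector of predicted labels in \{0, 1\}.
#' @param score Optional numeric scores in \[0, 1\].
#' @param model_name Model name recorded on the set.
#' @return A `prediction_set` tibble with attribute `model_name`.
#' @export
prediction_set <- function(section_id, label, score = NULL,
                           model_name = "model") {
  if (anyDuplicated(section_id)) {
    stop("duplicate section_id in prediction set", call. = FALSE)
  }
  label <- as.integer(label)
  if (any(is.na(label)) || !all(label %in% c(0L, 1L))) {
    stop("prediction labels must lie in {0,1}", call. = FALSE)
  }
  out <- tibble::tibble(section_id = as.character(section_id), label = label)
  if (!is.null(score)) {
    if (any(score < 0 | score > 1, na.rm = TRUE)) {
      stop("scores must lie in [0,1]", call. = FALSE)
    }
    out$score <- as.numeric(score)
  }
  attr(out, "model_name") <- model_name
  class(out) <- c("prediction_set", class(out))
  out
}

#' Name of the model behind a prediction set
#' @param pred A `prediction_set`.
#' @return The model name string.
#' @export
model_name <- function(pred) {
  nm <- attr(pred, "model_name")
  if (is.null(nm)) "model" else nm
}

#' Align a prediction set with a gold-labelled corpus
#'
#' @param pred A `prediction_set`.
#' @param gold A `note_corpus`.
#' @return List with `section_id`, `pred` and `gold` label vectors in gold
#'   order; errors when the id sets differ.
#' @export
align_predictions <- function(pred, gold) {
  if (!setequal(pred$section_id, gold$section_id)) {
    stop("prediction set '", model_name(pred),
         "' and gold corpus cover different section ids", call. = FALSE)
  }
  idx <- match(gold$section_id, pred$section_id)
  list(section_id = gold$section_id, pred = pred$label[idx],
       gold = gold$label)
}

#' Write or read a prediction set as CSV
#'
#' Columns: section_id, score (may be empty), label.
#'
#' @param pred A `prediction_set`.
#' @param path CSV path.
#' @param name Model name to record when reading.
#' @return `path` invisibly; `read_predictions()` returns a
#'   `prediction_set`.
#' @export
write_predictions <- function(pred, path) {
  df <- as.data.frame(pred)
  if (is.null(df$score)) df$score <- NA_real_
  utils::write.csv(df[c("section_id", "score", "label")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(section_id = "character"))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  score <- if (all(is.na(df$score))) NULL else df$score
  prediction_set(df$section_id, df$label, score = score, model_name = name)
}
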