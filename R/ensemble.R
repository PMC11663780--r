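#' Majority-vote ensemble of prediction sets
#'
#' Assigns the positive label when at least half-plus-one of the models
#' predict positive — with three models, cognitive decline is the final
#' label iff two or more models identify it. Generalised to any odd number
#' of models (three or more); an even count is rejected because no tie rule
#' is defined.
#'
#' @param pred_sets List of `prediction_set` objects over identical ids.
#' @return A `prediction_set` named `"ensemble"`.
#' @export
majority_vote <- function(pred_sets) {
  n_models <- length(pred_sets)
  if (n_models < 3L) {
    stop("majority vote requires at least three prediction sets",
         call. = FALSE)
  }
  if (n_models %% 2L == 0L) {
    stop("majority vote requires an odd number of prediction sets, got ",
         n_models, " (", paste(vapply(pred_sets, model_name, character(1)),
                               collapse = ", "), ")", call. = FALSE)
  }
  ids <- pred_sets[[1]]$section_id
  for (ps in pred_sets[-1]) {
    if (!setequal(ps$section_id, ids)) {
      stop("prediction sets '", model_name(pred_sets[[1]]), "' and '",
           model_name(ps), "' cover different section ids", call. = FALSE)
    }
  }
  votes <- vapply(pred_sets, function(ps) {
    ps$label[match(ids, ps$section_id)]
  }, integer(length(ids)))
  total <- rowSums(matrix(votes, nrow = length(ids)))
  label <- as.integer(total >= (n_models + 1L) / 2L)
  prediction_set(ids, label, model_name = "ensemble")
}
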