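#' Build a document-term feature space
#'
#' Vocabulary is every term with document frequency at or above the floor,
#' sorted lexicographically; rows align with corpus order. Weighting is raw
#' counts or smoothed TF-IDF (`tf * (log((1+N)/(1+df)) + 1)`, rows
#' L2-normalised).
#'
#' @param corpus A `note_corpus`.
#' @param weighting `"tfidf"` (default) or `"counts"`.
#' @param df_floor Minimum document frequency (default 2).
#' @return A `feature_space`: list with `vocabulary`, `weighting`,
#'   `df_floor`, `idf` and the sparse `matrix` (sections x terms).
#' @export
featurize <- function(corpus, weighting = c("tfidf", "counts"),
                      df_floor = 2L) {
  weighting <- match.arg(weighting)
  if (nrow(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  toks <- tokenize_text(corpus$text)
  df_tab <- table(unlist(lapply(toks, unique)))
  vocab <- sort(names(df_tab)[df_tab >= df_floor], method = "radix")
  if (length(vocab) == 0L) {
    stop("vocabulary is empty after applying the document-frequency floor (",
         df_floor, ")", call. = FALSE)
  }
  n <- nrow(corpus)
  idf <- log((1 + n) / (1 + as.numeric(df_tab[vocab]))) + 1
  names(idf) <- vocab
  space <- structure(list(vocabulary = vocab, weighting = weighting,
                          df_floor = df_floor, idf = idf),
                     class = "feature_space")
  space$matrix <- dtm_matrix(space, toks, corpus$section_id)
  space
}

dtm_matrix <- function(space, toks, section_ids) {
  vocab <- space$vocabulary
  ij <- lapply(seq_along(toks), function(i) {
    idx <- match(toks[[i]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NULL)
    tab <- tabulate(idx, length(vocab))
    j <- which(tab > 0L)
    cbind(i = i, j = j, x = tab[j])
  })
  ij <- do.call(rbind, ij)
  m <- Matrix::sparseMatrix(
    i = if (is.null(ij)) integer(0) else ij[, "i"],
    j = if (is.null(ij)) integer(0) else ij[, "j"],
    x = if (is.null(ij)) numeric(0) else ij[, "x"],
    dims = c(length(toks), length(vocab)),
    dimnames = list(section_ids, vocab))
  if (space$weighting == "tfidf") {
    m <- m %*% Matrix::Diagonal(x = space$idf)
    nrm <- sqrt(Matrix::rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- Matrix::Diagonal(x = 1 / nrm) %*% m
    dimnames(m) <- list(section_ids, vocab)
  }
  m
}

#' Apply an existing feature space to a new corpus
#'
#' @param space A `feature_space` from [featurize()].
#' @param corpus A `note_corpus`.
#' @return Sparse matrix with the space's vocabulary as columns.
#' @export
featurize_apply <- function(space, corpus) {
  dtm_matrix(space, tokenize_text(corpus$text), corpus$section_id)
}

#' Default hyperparameter grid for the boosted-trees model
#'
#' Trees \{50, 200\} x depth \{3, 6\} x learning rate \{0.1, 0.3\}: a small,
#' representative, fast grid.
#'
#' @return A data frame of grid points.
#' @export
default_tree_grid <- function() {
  expand.grid(nrounds = c(50L, 200L), max_depth = c(3L, 6L),
              eta = c(0.1, 0.3), KEEP.OUT.ATTRS = FALSE)
}

xgb_fit <- function(x, y, params, nrounds, seed) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = params$max_depth,
                  eta = params$eta, nthread = 1, seed = seed,
                  verbosity = 0),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = nrounds)
}

#' Train the boosted-trees baseline with grid-search 5-fold CV
#'
#' Selects the grid point maximising mean cross-validated F1 (at the 0.5
#' cutoff), refits on the full corpus, and records the per-feature total
#' split gain over the whole vocabulary (0 for unused features) for the
#' keyword-interpretation stage. Fully seed-reproducible.
#'
#' @param corpus A `note_corpus` containing both classes.
#' @param grid Data frame with columns `nrounds`, `max_depth`, `eta`.
#' @param folds Number of CV folds (>= 2).
#' @param seed Integer seed.
#' @param weighting,df_floor Featurisation settings, see [featurize()].
#' @return A `boosted_trees_model`.
#' @export
train_boosted_trees <- function(corpus, grid = default_tree_grid(),
                                folds = 5L, seed = 1L,
                                weighting = "tfidf", df_floor = 2L) {
  if (length(unique(corpus$label)) < 2L) {
    stop("corpus contains a single class; cannot train", call. = FALSE)
  }
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  space <- featurize(corpus, weighting = weighting, df_floor = df_floor)
  x <- space$matrix
  y <- corpus$label
  n <- nrow(corpus)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  cv_f1 <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    f1s <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- xgb_fit(x[tr, , drop = FALSE], y[tr], grid[g, ],
                     grid$nrounds[g], seed)
      p <- stats::predict(fit, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
      m <- metrics_from_counts(sum(p > 0.5 & y[!tr] == 1L),
                               sum(p > 0.5 & y[!tr] == 0L),
                               sum(p <= 0.5 & y[!tr] == 1L),
                               sum(p <= 0.5 & y[!tr] == 0L))
      if (is.na(m$f1)) 0 else m$f1
    }, numeric(1))
    cv_f1[g] <- mean(f1s)
  }
  best <- which.max(cv_f1)
  booster <- xgb_fit(x, y, grid[best, ], grid$nrounds[best], seed)
  imp <- xgboost::xgb.importance(model = booster)
  gain <- stats::setNames(numeric(length(space$vocabulary)),
                          space$vocabulary)
  if (!is.null(imp) && nrow(imp) > 0L) {
    gain[imp$Feature] <- imp$Gain
  }
  structure(list(booster = booster, space = space,
                 grid = cbind(grid, cv_f1 = cv_f1),
                 best_params = grid[best, , drop = FALSE],
                 gain = gain, seed = seed),
            class = "boosted_trees_model")
}

#' Predict positive-class scores for a corpus
#'
#' @param model A fitted classifier (`boosted_trees_model` or
#'   `attention_net_model`).
#' @param corpus A `note_corpus`.
#' @return Numeric scores in \[0, 1\], one per section.
#' @export
predict_score <- function(model, corpus) UseMethod("predict_score")

#' @export
predict_score.boosted_trees_model <- function(model, corpus) {
  x <- featurize_apply(model$space, corpus)
  stats::predict(model$booster, xgboost::xgb.DMatrix(x))
}

#' Turn model scores into a labelled prediction set
#'
#' The label is 1 iff the score strictly exceeds the cutoff; a score of
#' exactly 0.5 is negative.
#'
#' @param model A fitted classifier.
#' @param corpus A `note_corpus`.
#' @param cutoff Decision cutoff (default 0.5).
#' @param name Model name; defaults from the model class.
#' @return A `prediction_set` with scores.
#' @export
predict_labels <- function(model, corpus, cutoff = 0.5, name = NULL) {
  if (is.null(name)) {
    name <- switch(class(model)[1],
                   boosted_trees_model = "boosted_trees",
                   attention_net_model = "attention_net",
                   class(model)[1])
  }
  score <- predict_score(model, corpus)
  prediction_set(corpus$section_id, as.integer(score > cutoff),
                 score = score, model_name = name)
}

#' Cross-validated F1 of an arbitrary classifier trainer
#'
#' Utility for model assessment: seeded fold assignment, train on the
#' held-in folds with `fit_fun`, score the held-out fold, F1 at the 0.5
#' cutoff, averaged over folds (undefined fold F1 counts as 0).
#'
#' @param corpus A `note_corpus`.
#' @param fit_fun Function(corpus) returning a model with a
#'   [predict_score()] method.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Mean cross-validated F1.
#' @export
cross_validated_f1 <- function(corpus, fit_fun, folds = 5L, seed = 1L) {
  n <- nrow(corpus)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  f1s <- vapply(seq_len(folds), function(f) {
    train <- corpus[fold_id != f, ]
    attr(train, "corpus_name") <- corpus_name(corpus)
    class(train) <- unique(c("note_corpus", class(train)))
    test <- corpus[fold_id == f, ]
    model <- fit_fun(train)
    p <- predict_score(model, test)
    y <- test$label
    m <- metrics_from_counts(sum(p > 0.5 & y == 1L), sum(p > 0.5 & y == 0L),
                             sum(p <= 0.5 & y == 1L), sum(p <= 0.5 & y == 0L))
    if (is.na(m$f1)) 0 else m$f1
  }, numeric(1))
  mean(f1s)
}
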