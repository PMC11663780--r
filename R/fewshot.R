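#' A deterministic TF-IDF embedding provider
#'
#' The default local embedding space for example selection: L2-normalised
#' TF-IDF unigram vectors fitted on the pool. Deterministic, networkless,
#' and preserving the lexical-similarity geometry the selection strategies
#' rely on. Out-of-vocabulary tokens in later queries are ignored.
#'
#' @param pool_texts Character vector of pool texts to fit the vocabulary on.
#' @return An `embedding_provider`: a list with `embed(texts)` returning a
#'   matrix with one row per text, and `dim`, the embedding dimension.
#' @export
tfidf_provider <- function(pool_texts) {
  toks <- tokenize_text(pool_texts)
  vocab <- sort(unique(unlist(toks)), method = "radix")
  if (length(vocab) == 0L) stop("pool has an empty vocabulary", call. = FALSE)
  n <- length(pool_texts)
  df <- table(factor(unlist(lapply(toks, unique)), levels = vocab))
  idf <- log((1 + n) / (1 + as.numeric(df))) + 1
  embed <- function(texts) {
    tt <- tokenize_text(texts)
    out <- matrix(0, nrow = length(texts), ncol = length(vocab))
    for (i in seq_along(tt)) {
      counts <- table(factor(tt[[i]], levels = vocab))
      v <- as.numeric(counts) * idf
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) v <- v / nrm
      out[i, ] <- v
    }
    out
  }
  structure(list(embed = embed, dim = length(vocab), vocabulary = vocab),
            class = "embedding_provider")
}

#' Embed a pool corpus, caching by section id
#'
#' @param provider An `embedding_provider`.
#' @param pool A `note_corpus`.
#' @return Matrix of embeddings with section ids as row names.
#' @export
embed_pool <- function(provider, pool) {
  m <- provider$embed(pool$text)
  rownames(m) <- pool$section_id
  m
}

#' Write or read an embedding cache
#'
#' The cache is a plain TSV matrix whose first column is the section-id
#' index.
#'
#' @param embeddings Matrix with section-id row names.
#' @param path TSV path.
#' @return `path` invisibly; `read_embedding_cache()` returns the matrix.
#' @export
write_embedding_cache <- function(embeddings, path) {
  m <- embeddings
  colnames(m) <- paste0("d", seq_len(ncol(m)))
  df <- data.frame(section_id = rownames(embeddings), m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embedding_cache
#' @export
read_embedding_cache <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(section_id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$section_id, NULL)
  m
}

# ---- the four five-shot selection strategies -------------------------------

check_pool_size <- function(pool, k) {
  if (nrow(pool) < k) {
    stop("pool has ", nrow(pool), " sections but k = ", k, call. = FALSE)
  }
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random five-shot selection
#'
#' Uniform selection of `k` distinct pool sections without replacement.
#'
#' @param pool A `note_corpus` of candidate examples.
#' @param k Number of examples (default 5).
#' @param seed Integer seed.
#' @return A `note_corpus` slice of `k` sections.
#' @export
select_random <- function(pool, k = 5L, seed = 1L) {
  check_pool_size(pool, k)
  idx <- with_seed(seed, sample.int(nrow(pool), k))
  pool[idx, ]
}

#' Targeted five-shot selection
#'
#' Prefers sections the model previously misclassified: returns
#' `min(k, misclassified)` of them (a seeded subsample if more), padded with
#' seeded random correctly classified sections if fewer.
#'
#' @param pool A `note_corpus` of candidate examples with gold labels.
#' @param prior_predictions A `prediction_set` over the pool.
#' @param k Number of examples.
#' @param seed Integer seed.
#' @return A `note_corpus` slice of `k` sections.
#' @export
select_targeted <- function(pool, prior_predictions, k = 5L, seed = 1L) {
  check_pool_size(pool, k)
  aligned <- align_predictions(prior_predictions, pool)
  wrong <- which(aligned$pred != aligned$gold)
  idx <- with_seed(seed, {
    if (length(wrong) >= k) {
      sample(wrong, k)
    } else {
      right <- setdiff(seq_len(nrow(pool)), wrong)
      c(wrong, sample(right, k - length(wrong)))
    }
  })
  pool[idx, ]
}

#' K-means-cluster-center five-shot selection
#'
#' Runs seeded k-means (Euclidean, 10 restarts, 300-iteration cap) on the
#' pool embeddings and returns, for each cluster, the member nearest its
#' centroid (ties to the lowest index) — a diverse, representative example
#' set.
#'
#' @param pool A `note_corpus`.
#' @param k Number of clusters/examples.
#' @param provider An `embedding_provider` (default TF-IDF on the pool).
#' @param seed Integer seed.
#' @return A `note_corpus` slice of `k` sections.
#' @export
select_kmeans_centers <- function(pool, k = 5L,
                                  provider = tfidf_provider(pool$text),
                                  seed = 1L) {
  check_pool_size(pool, k)
  if (k == nrow(pool)) return(pool)     # every member is its own center
  x <- provider$embed(pool$text)
  if (nrow(unique(x)) < k) {
    warning("fewer than k distinct embedding vectors; ",
            "degenerate clustering, returning the first k pool members")
    return(pool[seq_len(k), ])
  }
  km <- with_seed(seed,
                  stats::kmeans(x, centers = k, nstart = 10, iter.max = 300))
  idx <- vapply(seq_len(k), function(j) {
    members <- which(km$cluster == j)
    d2 <- rowSums((x[members, , drop = FALSE] -
                     matrix(km$centers[j, ], length(members),
                            ncol(x), byrow = TRUE))^2)
    members[which.min(d2)]
  }, integer(1))
  pool[sort(idx), ]
}

#' Dynamic kNN five-shot selection
#'
#' For one query section, returns the `k` pool members with the highest
#' cosine similarity to the query embedding (ties to the lowest pool index),
#' recomputed per query. A pool member sharing the query's section id is
#' excluded. Zero-vector embeddings get similarity 0 with a warning.
#'
#' @param query_section A one-row corpus slice (or list with `section_id`,
#'   `text`).
#' @param pool A `note_corpus`.
#' @param k Number of neighbours.
#' @param provider An `embedding_provider`.
#' @param pool_embeddings Optional precomputed [embed_pool()] matrix.
#' @return A `note_corpus` slice of `k` sections, most similar first.
#' @export
select_knn_dynamic <- function(query_section, pool, k = 5L,
                               provider = tfidf_provider(pool$text),
                               pool_embeddings = NULL) {
  check_pool_size(pool, k)
  if (!nzchar(query_section$text)) stop("empty query text", call. = FALSE)
  q <- provider$embed(query_section$text)[1, ]
  x <- if (is.null(pool_embeddings)) provider$embed(pool$text) else
    pool_embeddings
  qn <- sqrt(sum(q^2))
  xn <- sqrt(rowSums(x^2))
  sims <- numeric(nrow(x))
  ok <- xn > 0 & qn > 0
  if (qn == 0 || any(!ok)) {
    warning("zero-vector embedding encountered; similarity set to 0")
  }
  if (qn > 0) {
    sims[ok] <- (x[ok, , drop = FALSE] %*% q)[, 1] / (xn[ok] * qn)
  }
  cand <- seq_len(nrow(pool))
  same <- pool$section_id == query_section$section_id
  if (any(same) && sum(!same) >= k) cand <- cand[!same]
  ord <- cand[order(-sims[cand])]
  pool[ord[seq_len(k)], ]
}

#' Bundle a few-shot strategy for [classify_sections()]
#'
#' Static strategies (random, targeted, kmeans) compute their example set
#' once at construction; the `knn` strategy retrieves per-query neighbours
#' dynamically.
#'
#' @param type One of `"random"`, `"targeted"`, `"kmeans"`, `"knn"`.
#' @param pool A `note_corpus` of candidate examples.
#' @param k Number of examples (default 5).
#' @param seed Integer seed.
#' @param provider An `embedding_provider`; default TF-IDF on the pool.
#' @param prior_predictions A `prediction_set` over the pool (targeted only).
#' @return A `fewshot_strategy` object.
#' @export
fewshot_strategy <- function(type = c("random", "targeted", "kmeans", "knn"),
                             pool, k = 5L, seed = 1L, provider = NULL,
                             prior_predictions = NULL) {
  type <- match.arg(type)
  if (is.null(provider) && type %in% c("kmeans", "knn")) {
    provider <- tfidf_provider(pool$text)
  }
  static <- switch(type,
    random = select_random(pool, k, seed),
    targeted = {
      if (is.null(prior_predictions)) {
        stop("targeted selection requires prior_predictions", call. = FALSE)
      }
      select_targeted(pool, prior_predictions, k, seed)
    },
    kmeans = select_kmeans_centers(pool, k, provider, seed),
    knn = NULL)
  cache <- if (type == "knn") embed_pool(provider, pool) else NULL
  structure(list(type = type, pool = pool, k = k, seed = seed,
                 provider = provider, static = static, cache = cache),
            class = "fewshot_strategy")
}

#' Resolve the example set of a strategy for one query section
#'
#' @param strategy A `fewshot_strategy`.
#' @param section The query section (one-row corpus slice).
#' @return A tibble with columns `text` and `label`.
#' @export
resolve_examples <- function(strategy, section) {
  sel <- if (strategy$type == "knn") {
    select_knn_dynamic(section, strategy$pool, strategy$k,
                       strategy$provider, pool_embeddings = strategy$cache)
  } else {
    strategy$static
  }
  tibble::tibble(text = sel$text, label = sel$label)
}
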