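make_pool <- function(n = 20, seed = 1) {
  set.seed(seed)
  words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
             "theta", "iota", "kappa")
  tiny_corpus(vapply(seq_len(n), function(i) {
    paste(sample(words, 6, replace = TRUE), collapse = " ")
  }, character(1)), rbinom(n, 1, 0.4))
}

fixed_provider <- function(vectors) {
  # maps each known text to a fixed embedding row
  structure(list(
    embed = function(texts) {
      vectors[texts, , drop = FALSE]
    },
    dim = ncol(vectors)), class = "embedding_provider")
}

test_that("random selection is uniform, distinct and seed-stable", {
  pool <- make_pool(10)
  expect_identical(select_random(pool, 5, seed = 3)$section_id,
                   select_random(pool, 5, seed = 3)$section_id)
  all10 <- select_random(pool, 10, seed = 4)
  expect_setequal(all10$section_id, pool$section_id)
  expect_error(select_random(pool, 11), "k = 11")
  # frequency: over many seeds each item is selected about k/n of the time
  hits <- integer(10)
  for (s in 1:4000) {
    idx <- match(select_random(pool, 5, seed = s)$section_id,
                 pool$section_id)
    hits[idx] <- hits[idx] + 1L
  }
  p <- 5 / 10
  sigma <- sqrt(4000 * p * (1 - p))
  expect_true(all(abs(hits - 4000 * p) <= 3 * sigma))
})

test_that("targeted selection prefers misclassified sections", {
  pool <- make_pool(12)
  wrong_idx <- c(2, 5, 7, 8, 11)
  pred <- prediction_set(pool$section_id,
                         ifelse(seq_len(12) %in% wrong_idx,
                                1L - pool$label, pool$label))
  got <- select_targeted(pool, pred, 5, seed = 2)
  expect_setequal(got$section_id, pool$section_id[wrong_idx])
  # fewer misclassified than k: pad with correct ones
  pred2 <- prediction_set(pool$section_id,
                          ifelse(seq_len(12) %in% c(3, 9),
                                 1L - pool$label, pool$label))
  got2 <- select_targeted(pool, pred2, 5, seed = 2)
  expect_true(all(pool$section_id[c(3, 9)] %in% got2$section_id))
  expect_equal(nrow(got2), 5)
  # no errors: pure random
  pred3 <- prediction_set(pool$section_id, pool$label)
  expect_equal(nrow(select_targeted(pool, pred3, 5, seed = 2)), 5)
  expect_error(select_targeted(pool, prediction_set("q", 1L), 5),
               "different section ids")
})

test_that("k-means center selection picks one member per tight cloud", {
  set.seed(7)
  centers <- diag(5) * 10
  vecs <- do.call(rbind, lapply(1:5, function(j) {
    matrix(rep(centers[j, ], 5), 5, byrow = TRUE) + rnorm(25, sd = 0.1)
  }))
  pool <- tiny_corpus(sprintf("cloud %d point %d", rep(1:5, each = 5),
                              rep(1:5, 5)), rep(c(0L, 1L), length.out = 25))
  rownames(vecs) <- pool$text
  got <- select_kmeans_centers(pool, 5, fixed_provider(vecs), seed = 3)
  clouds <- as.integer(sub("cloud (\\d).*", "\\1", got$text))
  expect_setequal(clouds, 1:5)
  # brute-force: selected member must be its cloud's nearest-to-mean point
  for (j in clouds) {
    members <- which(rep(1:5, each = 5) == j)
    mu <- colMeans(vecs[members, ])
    best <- members[which.min(rowSums((vecs[members, ] -
                                         matrix(mu, 5, 5,
                                                byrow = TRUE))^2))]
    expect_true(pool$text[best] %in% got$text)
  }
  # k = pool size: everyone is its own center
  small <- pool[1:4, ]
  got_all <- select_kmeans_centers(small, 4,
                                   fixed_provider(vecs[1:4, , drop = FALSE]),
                                   seed = 1)
  expect_setequal(got_all$section_id, small$section_id)
  # degenerate: identical vectors warn and still return k members
  dup <- matrix(1, 6, 3)
  rownames(dup) <- pool$text[1:6]
  expect_warning(
    got_dup <- select_kmeans_centers(pool[1:6, ], 3, fixed_provider(dup),
                                     seed = 1),
    "degenerate")
  expect_equal(nrow(got_dup), 3)
})

test_that("dynamic kNN matches an exhaustive similarity-sort oracle", {
  for (seed in c(5, 6)) {
    set.seed(seed)
    n <- sample(50:200, 1)
    x <- matrix(rpois(n * 8, 1), n, 8)
    x[rowSums(x) == 0, 1] <- 1
    x[sample(n, 5), ] <- matrix(x[1, ], 5, 8,
                                byrow = TRUE)   # duplicates force ties
    pool <- tiny_corpus(sprintf("pool %d", seq_len(n)),
                        rbinom(n, 1, 0.3))
    rownames(x) <- pool$text
    prov <- fixed_provider(rbind(x, query = rpois(8, 1) + c(1, rep(0, 7))))
    q <- list(section_id = "query", text = "query")
    got <- select_knn_dynamic(q, pool, 5, prov)
    want <- oracle_knn(prov$embed("query")[1, ], x, 5)
    expect_identical(got$section_id, pool$section_id[want])
  }
})

test_that("kNN self-similarity, whole-pool and tie-break cases", {
  vecs <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
  pool <- tiny_corpus(c("a", "b", "c"), c(1L, 0L, 0L))
  rownames(vecs) <- pool$text
  prov <- fixed_provider(vecs)
  got <- select_knn_dynamic(list(section_id = "q", text = "a"), pool, 2,
                            prov)
  expect_identical(got$text, c("a", "b"))   # axis match, then lowest index
  whole <- select_knn_dynamic(list(section_id = "q", text = "b"), pool, 3,
                              prov)
  expect_setequal(whole$text, pool$text)
  # zero vector: similarity 0 with warning
  vec0 <- rbind(vecs, z = c(0, 0, 0))
  pool0 <- tiny_corpus(c("a", "b", "c", "z"), c(1L, 0L, 0L, 0L))
  rownames(vec0) <- pool0$text
  expect_warning(select_knn_dynamic(list(section_id = "q", text = "z"),
                                    pool0, 2, fixed_provider(vec0)),
                 "zero-vector")
})

test_that("strategies never return the query and stay deterministic", {
  pool <- make_pool(30, seed = 9)
  prov <- tfidf_provider(pool$text)
  query <- list(section_id = "external-query", text = pool$text[1])
  for (type in c("random", "kmeans", "knn")) {
    st <- fewshot_strategy(type, pool, k = 5, seed = 13, provider = prov)
    ex1 <- resolve_examples(st, query)
    ex2 <- resolve_examples(st, query)
    expect_identical(ex1, ex2)
    expect_equal(nrow(ex1), 5)
    expect_true(all(ex1$text %in% pool$text))
  }
  # a pool member used as its own query is excluded by id
  member <- pool[1, ]
  got <- select_knn_dynamic(member, pool, 5, prov)
  expect_false(member$section_id %in% got$section_id)
})

test_that("tf-idf embeddings are deterministic unit vectors", {
  pool <- make_pool(15, seed = 4)
  prov <- tfidf_provider(pool$text)
  e1 <- prov$embed(pool$text)
  e2 <- prov$embed(pool$text)
  expect_identical(e1, e2)
  expect_equal(unname(sqrt(rowSums(e1^2))), rep(1, nrow(pool)))
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- embed_pool(prov, pool)
  write_embedding_cache(m, path)
  expect_equal(read_embedding_cache(path), m, tolerance = 1e-12)
})
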