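test_that("featurization builds the documented vocabulary and rows", {
  corpus <- tiny_corpus(c("a b", "b c"), c(0L, 1L))
  sp1 <- featurize(corpus, weighting = "counts", df_floor = 1)
  expect_identical(sp1$vocabulary, c("a", "b", "c"))
  sp2 <- featurize(corpus, weighting = "counts", df_floor = 2)
  expect_identical(sp2$vocabulary, "b")
  row <- featurize_apply(sp1, tiny_corpus("b b c", 0L))
  expect_equal(as.numeric(row), c(0, 2, 1))
  expect_error(featurize(tiny_corpus(c("x", "y"), c(0L, 1L)), df_floor = 2),
               "empty")
  # rows align with section order, tf-idf rows are unit length
  sp3 <- featurize(separable_corpus(40, seed = 2), df_floor = 1)
  expect_identical(rownames(sp3$matrix),
                   separable_corpus(40, seed = 2)$section_id)
  expect_equal(max(abs(sqrt(Matrix::rowSums(sp3$matrix^2)) - 1)), 0,
               tolerance = 1e-12)
})

test_that("boosted trees reach perfect CV F1 on the separable fixture", {
  sep <- separable_corpus(500, seed = 9)
  model <- train_boosted_trees(sep, seed = 3)
  expect_equal(max(model$grid$cv_f1), 1.0)
  # determinism of the selected grid point
  model2 <- train_boosted_trees(sep, seed = 3)
  expect_identical(model$best_params, model2$best_params)
  expect_equal(model$gain, model2$gain)
  # the planted keyword carries the maximum total gain
  expect_identical(names(which.max(model$gain)), "dementia")
  # grid of one point selects that point
  one <- train_boosted_trees(sep[1:200, ],
                             grid = data.frame(nrounds = 20L,
                                               max_depth = 3L, eta = 0.3),
                             seed = 4)
  expect_equal(one$best_params$nrounds, 20L)
  expect_error(train_boosted_trees(tiny_corpus(c("a", "b"), c(1L, 1L))),
               "single class")
})

test_that("score cutoffs follow the strict-inequality tie rule", {
  scores <- c(0.1, 0.5, 0.9, 0.0)
  fake <- structure(list(s = scores), class = "fixed_score_model")
  registerS3method("predict_score", "fixed_score_model",
                   function(model, corpus) model$s,
                   envir = asNamespace("cognote"))
  corpus <- tiny_corpus(letters[1:4], c(0L, 1L, 1L, 0L))
  pred <- predict_labels(fake, corpus)
  expect_identical(pred$label, c(0L, 0L, 1L, 0L))  # 0.5 is negative
  pred0 <- predict_labels(fake, corpus, cutoff = 0)
  expect_identical(pred0$label, c(1L, 1L, 1L, 0L))
})

test_that("attention-net gradients match central finite differences", {
  ns <- asNamespace("cognote")
  h <- attention_hyper(d_embed = 3, d_conv = 4, d_hidden = 3, d_attn = 3,
                       max_tokens = 10)
  set.seed(42)
  params <- ns$init_attention_params(5L, h)
  ids <- rbind(c(2L, 4L, 1L, 3L), c(5L, 1L, 6L, 1L))
  mask <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 0))
  y <- c(1, 0)
  loss <- function(p) {
    fw <- ns$attn_forward(p, ids, mask, h)
    -mean(y * log(fw$p) + (1 - y) * log(1 - fw$p))
  }
  g <- ns$attn_backward(params, ns$attn_forward(params, ids, mask, h), y, h)
  eps <- 1e-5
  for (nm in names(params)) {
    for (i in seq_len(min(length(params[[nm]]), 6))) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("the attention net learns the separable fixture", {
  sep <- separable_corpus(500, seed = 9)
  holdout <- separable_corpus(200, seed = 10)
  model <- train_attention_net(sep, small_net_hyper(), seed = 4)
  pred <- predict_labels(model, holdout)
  expect_gt(mean(pred$label == holdout$label), 0.9)
  # determinism
  model2 <- train_attention_net(sep, small_net_hyper(), seed = 4)
  expect_equal(model$params$wo, model2$params$wo, tolerance = 1e-12)
  # attention traces are a distribution over the section tokens
  w <- attention_trace(model, sep$text[1])
  expect_equal(sum(w), 1, tolerance = 1e-6)
  expect_true(all(w >= 0))
  expect_equal(length(w), length(tokenize_text(sep$text[1])[[1]]))
  # the planted token draws more attention than the average token
  pos <- sep[sep$label == 1, ][1:40, ]
  w_planted <- c(); w_all <- c()
  for (i in seq_len(nrow(pos))) {
    tr <- attention_trace(model, pos$text[i])
    w_planted <- c(w_planted, tr[names(tr) == "dementia"])
    w_all <- c(w_all, tr)
  }
  expect_gt(mean(w_planted), mean(w_all))
  expect_error(train_attention_net(sep,
                                   attention_hyper(vocab_cap = 5L)),
               "overflow")
  expect_error(train_attention_net(tiny_corpus(c("a", "b"), c(0L, 0L))),
               "single class")
})

test_that("both baselines clearly beat the majority-class baseline", {
  corpus <- generate_corpus(
    generator_config(800, 0.294, hard_negative_share = 0.3, seed = 41,
                     length_log_mean = log(300), length_max = 2000),
    fixture_bank())
  split <- 1:600
  train <- note_corpus(corpus[split, ], "train")
  test <- note_corpus(corpus[-split, ], "test")
  trees <- train_boosted_trees(train, grid = data.frame(nrounds = 50L,
                                                        max_depth = 3L,
                                                        eta = 0.3),
                               seed = 5)
  f1_of <- function(pred) {
    compute_metrics(confusion_matrix(pred, test))$f1
  }
  # majority baseline predicts all negative: F1 0 (undefined precision)
  expect_gt(f1_of(predict_labels(trees, test)), 0.10)
  net <- train_attention_net(train,
                             attention_hyper(d_embed = 16, d_conv = 16,
                                             d_hidden = 8, d_attn = 8,
                                             max_tokens = 64, epochs = 3),
                             seed = 6)
  expect_gt(f1_of(predict_labels(net, test)), 0.10)
})
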