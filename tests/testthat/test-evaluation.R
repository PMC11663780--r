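balanced_gold <- function(n_pos = 5, n_neg = 5) {
  tiny_corpus(rep("x", n_pos + n_neg), c(rep(1L, n_pos), rep(0L, n_neg)),
              patients = sprintf("p%02d", rep(seq_len((n_pos + n_neg) / 2),
                                              each = 2)))
}

test_that("confusion matrices count the standard 2x2 cells", {
  gold <- balanced_gold()
  perfect <- prediction_set(gold$section_id, gold$label)
  expect_identical(unclass(confusion_matrix(perfect, gold))[1:4],
                   list(tp = 5L, fp = 0L, fn = 0L, tn = 5L))
  allneg <- prediction_set(gold$section_id, rep(0L, 10))
  expect_identical(unclass(confusion_matrix(allneg, gold))[1:4],
                   list(tp = 0L, fp = 0L, fn = 5L, tn = 5L))
  inverted <- prediction_set(gold$section_id, 1L - gold$label)
  expect_identical(unclass(confusion_matrix(inverted, gold))[1:4],
                   list(tp = 0L, fp = 5L, fn = 5L, tn = 0L))
  expect_error(confusion_matrix(prediction_set("q", 1L), gold),
               "different section ids")
})

test_that("metrics match their formulas, including degenerate cells", {
  m <- compute_metrics(structure(list(tp = 9L, fp = 1L, fn = 1L, tn = 89L),
                                 class = "confusion_matrix"))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  expect_equal(m$specificity, 89 / 90)
  expect_equal(m$npv, 89 / 90)
  perfect <- compute_metrics(structure(list(tp = 5L, fp = 0L, fn = 0L,
                                            tn = 5L),
                                       class = "confusion_matrix"))
  expect_true(all(unlist(perfect) == 1))
  degen <- compute_metrics(structure(list(tp = 0L, fp = 0L, fn = 5L,
                                          tn = 5L),
                                     class = "confusion_matrix"))
  expect_true(is.na(degen$precision))
  expect_equal(degen$recall, 0)
  expect_equal(degen$specificity, 1)
})

test_that("metrics agree exactly with the direct-formula oracle", {
  set.seed(8)
  for (i in 1:300) {
    cm <- as.list(rmultinom(1, sample(1:200, 1), runif(4))[, 1])
    names(cm) <- c("tp", "fp", "fn", "tn")
    got <- compute_metrics(structure(cm, class = "confusion_matrix"))
    want <- oracle_metrics(cm$tp, cm$fp, cm$fn, cm$tn)
    expect_identical(unclass(got)[names(want)], want)
  }
})

test_that("F1 lies between precision and recall whenever defined", {
  set.seed(9)
  for (i in 1:200) {
    cm <- as.list(rmultinom(1, 100, runif(4))[, 1])
    names(cm) <- c("tp", "fp", "fn", "tn")
    m <- compute_metrics(structure(cm, class = "confusion_matrix"))
    if (!is.na(m$precision) && !is.na(m$recall)) {
      expect_gte(m$f1 + 1e-12, min(m$precision, m$recall))
      expect_lte(m$f1 - 1e-12, max(m$precision, m$recall))
    }
  }
})

test_that("adding a correct positive never lowers recall or NPV", {
  set.seed(10)
  for (i in 1:50) {
    cm <- as.list(rmultinom(1, 60, runif(4))[, 1] + 1L)
    names(cm) <- c("tp", "fp", "fn", "tn")
    base <- compute_metrics(structure(cm, class = "confusion_matrix"))
    cm2 <- cm; cm2$tp <- cm2$tp + 1L
    more <- compute_metrics(structure(cm2, class = "confusion_matrix"))
    expect_gte(more$recall, base$recall)
    expect_gte(more$npv, base$npv)
  }
})

test_that("bootstrap intervals behave on exact and noisy classifiers", {
  gold <- balanced_gold(20, 20)
  perfect <- prediction_set(gold$section_id, gold$label)
  rep_perfect <- bootstrap_cis(perfect, gold, B = 200, seed = 2)
  ci <- attr(rep_perfect, "ci")
  expect_true(all(ci$lower == 1 & ci$upper == 1))
  set.seed(3)
  noisy <- prediction_set(gold$section_id,
                          ifelse(runif(40) < 0.2, 1L - gold$label,
                                 gold$label))
  rep_noisy <- bootstrap_cis(noisy, gold, B = 500, seed = 4)
  ci_n <- attr(rep_noisy, "ci")
  for (m in ci_n$metric) {
    est <- rep_noisy[[m]]
    row <- ci_n[ci_n$metric == m, ]
    expect_gte(est, row$lower)
    expect_lte(est, row$upper)
  }
  # reproducibility and guard rails
  expect_identical(attr(bootstrap_cis(noisy, gold, B = 200, seed = 9), "ci"),
                   attr(bootstrap_cis(noisy, gold, B = 200, seed = 9), "ci"))
  expect_warning(bootstrap_cis(noisy, gold, B = 50, seed = 1), "B < 100")
  single <- tiny_corpus(rep("x", 4), rep(0L, 4))
  expect_error(bootstrap_cis(prediction_set(single$section_id, rep(0L, 4)),
                             single, B = 200), "single class")
})

test_that("patient-level resampling uses whole patients", {
  gold <- balanced_gold(20, 20)
  set.seed(5)
  noisy <- prediction_set(gold$section_id,
                          ifelse(runif(40) < 0.2, 1L - gold$label,
                                 gold$label))
  rep_p <- bootstrap_cis(noisy, gold, B = 300, seed = 6, unit = "patient")
  expect_s3_class(attr(rep_p, "ci"), "tbl_df")
  expect_false(identical(attr(rep_p, "ci"),
                         attr(bootstrap_cis(noisy, gold, B = 300, seed = 6),
                              "ci")))
})

test_that("paired comparison is convention-correct and antisymmetric", {
  gold <- balanced_gold(30, 30)
  set.seed(7)
  a <- prediction_set(gold$section_id,
                      ifelse(runif(60) < 0.05, 1L - gold$label, gold$label))
  b <- prediction_set(gold$section_id,
                      ifelse(runif(60) < 0.3, 1L - gold$label, gold$label))
  same <- paired_metric_test(a, a, gold, B = 200, seed = 8)
  expect_true(all(same$p == 1))
  ab <- paired_metric_test(a, b, gold, B = 400, seed = 8)
  ba <- paired_metric_test(b, a, gold, B = 400, seed = 8)
  expect_equal(ab$t, -ba$t, tolerance = 1e-10)
  expect_equal(ab$p, ba$p, tolerance = 1e-10)
})

test_that("clearly different error rates give p below 0.01 for accuracy", {
  set.seed(11)
  n <- 2000
  gold <- tiny_corpus(rep("x", n), rbinom(n, 1, 0.3))
  strong <- prediction_set(gold$section_id,
                           ifelse(runif(n) < 0.02, 1L - gold$label,
                                  gold$label))
  weak <- prediction_set(gold$section_id,
                         ifelse(runif(n) < 0.20, 1L - gold$label,
                                gold$label))
  res <- paired_metric_test(strong, weak, gold, B = 1000, seed = 12)
  expect_lt(res$p[res$metric == "accuracy"], 0.01)
  expect_gt(res$mean_diff[res$metric == "accuracy"], 0)
})

test_that("metric reports serialise to JSON with their intervals", {
  gold <- balanced_gold(10, 10)
  pred <- prediction_set(gold$section_id, gold$label)
  rep <- bootstrap_cis(pred, gold, B = 200, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$precision$estimate, 1)
  expect_equal(back$n_bootstrap, 200)
  lines <- format_metrics_table(list(model = rep))
  expect_match(lines[2], "model")
  expect_match(lines[2], "100.0%")
})
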