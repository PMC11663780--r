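test_that("mean+2SD selection follows its arithmetic exactly", {
  expect_identical(mean2sd_select(c(5, 5, 5)), integer(0))
  expect_identical(mean2sd_select(c(1, 2, 3)), integer(0))
  # twenty 1s and one 21: mean ~1.95, sd ~4.36, threshold ~10.7
  v <- c(rep(1, 20), 21)
  expect_identical(mean2sd_select(v), 21L)
  expect_error(mean2sd_select(1), "two values")
  # one dominant weight among twenty
  w <- c(0.9, rep(0.1 / 19, 19))
  expect_identical(mean2sd_select(w), 1L)
})

test_that("mean+2SD agrees with an independent script and scales freely", {
  set.seed(14)
  for (i in 1:300) {
    v <- rgamma(sample(2:40, 1), shape = 0.5)
    expect_identical(mean2sd_select(v), oracle_mean2sd(v))
    expect_identical(mean2sd_select(v * 37.5), mean2sd_select(v))
  }
})

fake_log <- function(keyword_sets, categories = NULL) {
  n <- length(keyword_sets)
  tibble::tibble(
    section_id = sprintf("s%03d", seq_len(n)),
    category = if (is.null(categories)) rep("effective_parseable", n) else
      categories,
    label = rep(1L, n), keywords = keyword_sets,
    flagged = rep(FALSE, n), raw = rep("", n))
}

test_that("LLM keyword counting selects the dominant citation", {
  log <- fake_log(c(replicate(30, "dementia", simplify = FALSE),
                    list("sleep", "mood", "exam", "score", "drive")))
  tab <- llm_keywords(log)
  expect_identical(tab$keyword[tab$selected], "dementia")
  expect_equal(tab$value[tab$keyword == "dementia"], 30)
  # all cited once: sd 0, nothing selected
  once <- llm_keywords(fake_log(list("a", "b", "c")))
  expect_false(any(once$selected))
  # case folding and trimming merge citations
  folded <- llm_keywords(fake_log(list(" Dementia ", "dementia", "x", "y",
                                       "z", "w", "dementia")))
  expect_equal(folded$value[folded$keyword == "dementia"], 3)
  # no parseable verdicts
  expect_warning(empty <- llm_keywords(fake_log(list("a"),
                                                "not_effective")),
                 "no parseable")
  expect_equal(nrow(empty), 0)
  # empty keyword lists throughout
  none <- llm_keywords(fake_log(list(character(0), character(0))))
  expect_equal(nrow(none), 0)
})

test_that("gain-based keywords recover the planted split and degenerate cases", {
  sep <- separable_corpus(400, seed = 15)
  model <- train_boosted_trees(sep, grid = data.frame(nrounds = 30L,
                                                      max_depth = 3L,
                                                      eta = 0.3), seed = 2)
  tab <- gain_keywords(model)
  expect_true("dementia" %in% tab$keyword[tab$selected])
  # constant gains select nothing
  const <- structure(list(gain = stats::setNames(rep(0.2, 5),
                                                 letters[1:5])),
                     class = "boosted_trees_model")
  expect_false(any(gain_keywords(const)$selected))
  expect_error(gain_keywords(structure(list(), class = "other")),
               "gain table")
})

test_that("noise-trained gain selection stays near-empty", {
  sizes <- vapply(1:8, function(s) {
    set.seed(100 + s)
    noise <- tiny_corpus(vapply(1:120, function(i) {
      paste(sample(letters[1:15], 8, replace = TRUE), collapse = " ")
    }, character(1)), rbinom(120, 1, 0.4))
    m <- train_boosted_trees(noise, grid = data.frame(nrounds = 20L,
                                                      max_depth = 3L,
                                                      eta = 0.3),
                             seed = s, df_floor = 1L)
    sum(gain_keywords(m)$selected)
  }, numeric(1))
  expect_lte(stats::median(sizes), 2)
})

test_that("attention keyword aggregation needs repeated concentration", {
  sep <- separable_corpus(300, seed = 16)
  model <- train_attention_net(sep, fixture_net_hyper(), seed = 3)
  tab <- attention_keywords(model, sep)
  expect_true("dementia" %in% tab$keyword[tab$selected])
  # floor: tokens spiking in a single section are not flagged
  expect_true(all(tab$value[tab$selected] >= 2))
})

test_that("the merged report mirrors the combined keyword table", {
  rows_a <- tibble::tibble(keyword = c("dementia", "noise"),
                           source = "boosted_trees", value = c(3, 0.1),
                           selected = c(TRUE, FALSE))
  rows_b <- tibble::tibble(keyword = "dementia", source = "llm",
                           value = 30, selected = TRUE)
  merged <- merge_keyword_report(list(rows_a, rows_b), fixture_lexicon())
  expect_equal(sum(merged$keyword == "dementia"),
               3)  # expert + boosted_trees + llm
  expect_false("noise" %in% merged$keyword)
  expect_true(all(merged$selected))
  expect_identical(unique(merged$source),
                   c("expert", "boosted_trees", "llm"))
  # expert rows only when model tables are empty
  only_expert <- merge_keyword_report(list(), fixture_lexicon())
  expect_setequal(unique(only_expert$source), "expert")
  expect_true(all(is.na(only_expert$value)))
  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_keyword_report(merged, path)
  expect_equal(as.data.frame(read_keyword_report(path)),
               as.data.frame(merged))
  lines <- format_keyword_table(merged)
  expect_length(lines, 4)
  expect_match(lines[1], "Expert")
})
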