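#' Confusion matrix of a prediction set against gold labels
#'
#' @param pred A `prediction_set`.
#' @param gold A `note_corpus` with gold labels.
#' @return A `confusion_matrix`: list with integer fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(pred, gold) {
  a <- align_predictions(pred, gold)
  cm <- list(tp = sum(a$pred == 1L & a$gold == 1L),
             fp = sum(a$pred == 1L & a$gold == 0L),
             fn = sum(a$pred == 0L & a$gold == 1L),
             tn = sum(a$pred == 0L & a$gold == 0L))
  structure(lapply(cm, as.integer), class = "confusion_matrix")
}

metrics_from_counts <- function(tp, fp, fn, tn) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- ifelse(is.na(precision) | is.na(recall), NA_real_,
               ifelse(precision + recall > 0,
                      2 * precision * recall / (precision + recall), 0))
  list(precision = precision,
       recall = recall,
       f1 = f1,
       specificity = safe_div(tn, tn + fp),
       npv = safe_div(tn, tn + fn),
       accuracy = safe_div(tp + tn, tp + fp + fn + tn))
}

#' Confusion-matrix metrics
#'
#' Computes precision (PPV), recall (sensitivity), F1, specificity, NPV and
#' accuracy from a 2x2 confusion matrix. Metrics with a zero denominator are
#' reported as `NA` (undefined), never coerced to 0; F1 is 0 when precision
#' and recall are both defined and both 0.
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report`: named list of the six metrics.
#' @export
compute_metrics <- function(cm) {
  out <- metrics_from_counts(cm$tp, cm$fp, cm$fn, cm$tn)
  structure(out, class = "metrics_report", confusion = cm)
}

metric_names <- c("precision", "recall", "f1", "specificity", "npv",
                  "accuracy")

# per-section outcome codes: 1 = tp, 2 = fp, 3 = fn, 4 = tn
outcome_codes <- function(pred, gold) {
  a <- align_predictions(pred, gold)
  ifelse(a$pred == 1L, ifelse(a$gold == 1L, 1L, 2L),
         ifelse(a$gold == 1L, 3L, 4L))
}

# B x 4 matrix of resampled confusion counts, resampling units with
# replacement; unit = section, or patient (clusters of sections)
resample_counts <- function(codes, B, patient = NULL) {
  n <- length(codes)
  if (is.null(patient)) {
    t(vapply(seq_len(B), function(b) {
      tabulate(codes[sample.int(n, n, replace = TRUE)], 4L)
    }, integer(4)))
  } else {
    groups <- split(codes, patient)
    g <- length(groups)
    t(vapply(seq_len(B), function(b) {
      tabulate(unlist(groups[sample.int(g, g, replace = TRUE)],
                      use.names = FALSE), 4L)
    }, integer(4)))
  }
}

#' Bootstrap confidence intervals for all metrics
#'
#' Resamples sections (or whole patients, if `unit = "patient"`) with
#' replacement `B` times and reports the percentile interval of each metric
#' at the requested level. Replicates where a metric is undefined are dropped
#' for that metric, with the dropped count recorded in the report.
#'
#' @param pred A `prediction_set`.
#' @param gold A `note_corpus` containing both classes.
#' @param B Number of bootstrap replicates (default 1000; below 100 warns).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param unit Resampling unit: `"section"` (default) or `"patient"`.
#' @return A `metrics_report` with, per metric, the point estimate plus a
#'   `ci` attribute: a tibble (metric, lower, upper, n_dropped), and
#'   `n_bootstrap`.
#' @export
bootstrap_cis <- function(pred, gold, B = 1000L, level = 0.95, seed = 1L,
                          unit = c("section", "patient")) {
  unit <- match.arg(unit)
  if (nrow(gold) < 2L) stop("need at least 2 sections", call. = FALSE)
  if (length(unique(gold$label)) < 2L) {
    stop("gold labels contain a single class; intervals are degenerate",
         call. = FALSE)
  }
  if (B < 100L) warning("B < 100 gives unstable percentile intervals")
  codes <- outcome_codes(pred, gold)
  patient <- if (unit == "patient") gold$patient_id else NULL
  counts <- with_seed(seed, resample_counts(codes, B, patient))
  reps <- metrics_from_counts(counts[, 1], counts[, 2], counts[, 3],
                              counts[, 4])
  alpha <- (1 - level) / 2
  ci <- do.call(rbind, lapply(metric_names, function(m) {
    v <- reps[[m]]
    dropped <- sum(is.na(v))
    v <- v[!is.na(v)]
    qs <- if (length(v) > 0L) stats::quantile(v, c(alpha, 1 - alpha),
                                              names = FALSE)
          else c(NA_real_, NA_real_)
    tibble::tibble(metric = m, lower = qs[1], upper = qs[2],
                   n_dropped = dropped)
  }))
  out <- compute_metrics(confusion_matrix(pred, gold))
  attr(out, "ci") <- ci
  attr(out, "n_bootstrap") <- B
  attr(out, "level") <- level
  out
}

#' Paired bootstrap comparison of two models
#'
#' Applies the same `B` bootstrap resamples to both prediction sets,
#' computes every metric on each replicate, and runs a paired t-test on the
#' replicate-wise differences (model a minus model b). When all differences
#' are zero the p-value is 1 by convention.
#'
#' @param pred_a,pred_b `prediction_set`s over the same ids.
#' @param gold A `note_corpus`.
#' @param B Number of shared bootstrap replicates.
#' @param seed Integer seed.
#' @param unit Resampling unit, as in [bootstrap_cis()].
#' @return A tibble (metric, mean_diff, t, p); replicates where either
#'   model's metric is undefined are dropped pairwise.
#' @export
paired_metric_test <- function(pred_a, pred_b, gold, B = 1000L, seed = 1L,
                               unit = c("section", "patient")) {
  unit <- match.arg(unit)
  codes_a <- outcome_codes(pred_a, gold)
  codes_b <- outcome_codes(pred_b, gold)
  n <- length(codes_a)
  patient <- if (match.arg(unit) == "patient") gold$patient_id else NULL
  pair <- with_seed(seed, {
    if (is.null(patient)) {
      idx <- lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
    } else {
      groups <- split(seq_len(n), patient)
      g <- length(groups)
      idx <- lapply(seq_len(B), function(b) {
        unlist(groups[sample.int(g, g, replace = TRUE)], use.names = FALSE)
      })
    }
    list(a = t(vapply(idx, function(i) tabulate(codes_a[i], 4L), integer(4))),
         b = t(vapply(idx, function(i) tabulate(codes_b[i], 4L), integer(4))))
  })
  ma <- metrics_from_counts(pair$a[, 1], pair$a[, 2], pair$a[, 3],
                            pair$a[, 4])
  mb <- metrics_from_counts(pair$b[, 1], pair$b[, 2], pair$b[, 3],
                            pair$b[, 4])
  do.call(rbind, lapply(metric_names, function(m) {
    d <- ma[[m]] - mb[[m]]
    d <- d[!is.na(d)]
    if (length(d) == 0L || all(d == 0)) {
      return(tibble::tibble(metric = m,
                            mean_diff = if (length(d)) 0 else NA_real_,
                            t = 0, p = 1))
    }
    tt <- stats::t.test(d)
    tibble::tibble(metric = m, mean_diff = mean(d),
                   t = unname(tt$statistic), p = tt$p.value)
  }))
}

#' Render a metrics report as JSON or a text table
#'
#' @param report A `metrics_report` (optionally with bootstrap CIs).
#' @param path Output path for [write_metrics_json()].
#' @return JSON path invisibly, or a character vector of table lines.
#' @export
write_metrics_json <- function(report, path) {
  ci <- attr(report, "ci")
  payload <- lapply(metric_names, function(m) {
    entry <- list(estimate = report[[m]])
    if (!is.null(ci)) {
      row <- ci[ci$metric == m, ]
      entry$ci_lower <- row$lower
      entry$ci_upper <- row$upper
      entry$n_dropped_replicates <- row$n_dropped
    }
    entry
  })
  names(payload) <- metric_names
  payload$n_bootstrap <- attr(report, "n_bootstrap")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_metrics_json
#' @param reports Named list of `metrics_report` objects (one per model).
#' @export
format_metrics_table <- function(reports) {
  header <- sprintf("%-16s %10s %10s %10s %12s %10s %10s", "model",
                    "precision", "recall", "f1", "specificity", "npv",
                    "accuracy")
  fmt <- function(x) ifelse(is.na(x), "   --", sprintf("%9.1f%%", 100 * x))
  rows <- vapply(names(reports), function(nm) {
    r <- reports[[nm]]
    sprintf("%-16s %s %s %s %s %s %s", nm, fmt(r$precision), fmt(r$recall),
            fmt(r$f1), paste0("  ", fmt(r$specificity)),
            fmt(r$npv), fmt(r$accuracy))
  }, character(1))
  c(header, rows)
}
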