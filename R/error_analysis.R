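#' Per-model error sets
#'
#' For each prediction set, the section ids where the prediction differs
#' from the gold label — both false positives and false negatives.
#'
#' @param pred_sets List of `prediction_set` objects.
#' @param gold A `note_corpus`.
#' @return Named list of character vectors of section ids.
#' @export
error_sets <- function(pred_sets, gold) {
  out <- lapply(pred_sets, function(ps) {
    a <- align_predictions(ps, gold)
    a$section_id[a$pred != a$gold]
  })
  names(out) <- vapply(pred_sets, model_name, character(1))
  out
}

new_overlap_counts <- function(a, b, c, ab, ac, bc, abc) {
  counts <- list(a = a, b = b, c = c, ab = ab, ac = ac, bc = bc, abc = abc)
  counts <- lapply(counts, as.integer)
  if (any(unlist(counts) < 0)) {
    stop("overlap counts must be non-negative", call. = FALSE)
  }
  with(counts, {
    if (abc > min(ab, ac, bc)) {
      stop("triple overlap exceeds a pairwise overlap", call. = FALSE)
    }
    if (ab > min(a, b) || ac > min(a, c) || bc > min(b, c)) {
      stop("pairwise overlap exceeds a per-model count", call. = FALSE)
    }
  })
  counts$union <- with(counts, a + b + c - ab - ac - bc + abc)
  structure(counts, class = "overlap_counts")
}

#' Three-set error-overlap decomposition
#'
#' Computes the per-model error counts, the pairwise overlaps (inclusive of
#' the triple overlap), the triple overlap, and the union — the accounting
#' behind a three-set error Venn diagram.
#'
#' @param sets Named list of exactly three character vectors (error sets).
#' @return An `overlap_counts` object with fields `a`, `b`, `c`, `ab`,
#'   `ac`, `bc`, `abc`, `union`.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) != 3L) {
    stop("overlap_counts requires exactly three error sets, got ",
         length(sets), call. = FALSE)
  }
  sets <- lapply(sets, unique)
  a <- sets[[1]]; b <- sets[[2]]; c <- sets[[3]]
  out <- new_overlap_counts(
    length(a), length(b), length(c),
    length(intersect(a, b)), length(intersect(a, c)),
    length(intersect(b, c)),
    length(intersect(intersect(a, b), c)))
  attr(out, "model_names") <- names(sets)
  out
}

#' @export
print.overlap_counts <- function(x, ...) {
  nms <- attr(x, "model_names")
  if (is.null(nms)) nms <- c("a", "b", "c")
  cat(sprintf("errors: %s=%d, %s=%d, %s=%d\n", nms[1], x$a, nms[2], x$b,
              nms[3], x$c))
  cat(sprintf("pairwise (incl. triple): ab=%d, ac=%d, bc=%d; triple=%d\n",
              x$ab, x$ac, x$bc, x$abc))
  cat(sprintf("union (missed by >=1 model): %d\n", x$union))
  invisible(x)
}

#' Union size by inclusion-exclusion
#'
#' Given per-model error counts, pairwise overlaps (inclusive of the triple)
#' and the triple overlap, returns the number of sections mispredicted by at
#' least one model: `a + b + c - ab - ac - bc + abc`. Inputs violating the
#' count invariants are rejected.
#'
#' @param a,b,c Per-model error counts.
#' @param ab,ac,bc Pairwise overlap counts, each including the triple.
#' @param abc Triple overlap count.
#' @return Integer union count.
#' @export
inclusion_exclusion_union <- function(a, b, c, ab, ac, bc, abc) {
  new_overlap_counts(a, b, c, ab, ac, bc, abc)$union
}

round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Mutual-error fraction
#'
#' The triple overlap as a percentage of the union, rounded half-up to one
#' decimal — the share of mispredicted sections that every model got wrong.
#'
#' @param counts An `overlap_counts` object.
#' @return Percentage with one decimal, or `NA` (with a warning) when the
#'   union is empty.
#' @export
mutual_error_fraction <- function(counts) {
  if (counts$union == 0L) {
    warning("union of error sets is empty; mutual-error fraction undefined")
    return(NA_real_)
  }
  round_half_up(100 * counts$abc / counts$union, 1L)
}

#' Write an overlap report as JSON
#'
#' @param counts An `overlap_counts`.
#' @param path JSON path.
#' @return `path` invisibly.
#' @export
write_overlap_json <- function(counts, path) {
  payload <- unclass(counts)
  payload$model_names <- attr(counts, "model_names")
  payload$mutual_error_pct <- if (counts$union > 0L)
    mutual_error_fraction(counts) else NA_real_
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Plot a three-set error Venn diagram
#'
#' A simple base-graphics three-circle diagram annotated with the exclusive
#' region counts derived from the inclusive overlap fields.
#'
#' @param counts An `overlap_counts`.
#' @param main Plot title.
#' @return `counts` invisibly.
#' @export
plot_error_venn <- function(counts, main = "Unique and overlapping errors") {
  nms <- attr(counts, "model_names")
  if (is.null(nms)) nms <- c("model a", "model b", "model c")
  only_a <- counts$a - counts$ab - counts$ac + counts$abc
  only_b <- counts$b - counts$ab - counts$bc + counts$abc
  only_c <- counts$c - counts$ac - counts$bc + counts$abc
  ab_ex <- counts$ab - counts$abc
  ac_ex <- counts$ac - counts$abc
  bc_ex <- counts$bc - counts$abc
  graphics::plot.new()
  graphics::plot.window(c(-2, 2), c(-2, 2), asp = 1)
  graphics::title(main = main)
  centers <- rbind(c(-0.5, 0.4), c(0.5, 0.4), c(0, -0.5))
  th <- seq(0, 2 * pi, length.out = 200)
  for (i in 1:3) {
    graphics::lines(centers[i, 1] + cos(th), centers[i, 2] + sin(th))
    graphics::text(centers[i, 1] * 2.1, centers[i, 2] * 2.6, nms[i])
  }
  lab <- function(x, y, v) graphics::text(x, y, v)
  lab(-0.9, 0.6, only_a); lab(0.9, 0.6, only_b); lab(0, -1.0, only_c)
  lab(0, 0.7, ab_ex); lab(-0.55, -0.25, ac_ex); lab(0.55, -0.25, bc_ex)
  lab(0, 0.05, counts$abc)
  invisible(counts)
}
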