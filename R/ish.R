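# In situ hybridization / immunohistochemistry composite scoring: staining
# intensity (0-3) times proportion-of-positive-cells category (0-4), the
# printed grade bands, and Youden-index optimal-cutoff selection.

#' Proportion-of-positive-cells category
#'
#' Maps a percentage of positive cells to the printed 0-4 category scale:
#' 0 for no positive cells; 1 for <= 10%; 2 for > 10% and <= 50%; 3 for
#' > 50% and <= 75%; 4 for > 75% (boundaries inclusive on the upper side).
#'
#' @param pct Percentage(s) in `[0, 100]`.
#' @return Integer category(ies) in 0-4.
#' @examples
#' proportion_category(c(0, 10, 10.5, 80))
#' @export
proportion_category <- function(pct) {
  check_flag(is.numeric(pct) && all(is.finite(pct)), "pct",
             "must be finite numeric")
  if (any(pct < 0 | pct > 100)) {
    stop_field("pct", "must lie in [0, 100]")
  }
  ifelse(pct == 0, 0L,
         ifelse(pct <= 10, 1L,
                ifelse(pct <= 50, 2L,
                       ifelse(pct <= 75, 3L, 4L))))
}

#' Composite staining score
#'
#' The product of the staining-intensity score (0 negative, 1 weak, 2
#' moderate, 3 strong) and the proportion category of positive cells;
#' attainable values are the products of `{0..3} x {0..4}`, at most 12.
#'
#' @param intensity Integer intensity score(s) in 0-3.
#' @param pct Percentage(s) of positive cells in `[0, 100]`.
#' @return Integer composite score(s) in 0-12.
#' @examples
#' composite_score(3, 80)  # 12
#' composite_score(2, 40)  # 4
#' @export
composite_score <- function(intensity, pct) {
  check_flag(is.numeric(intensity) && all(intensity %in% 0:3), "intensity",
             "must be integers in 0..3")
  as.integer(intensity) * proportion_category(pct)
}

#' Grade a composite score
#'
#' Bands a composite score per the printed scheme: 0 negative, 1-4 weak,
#' 5-8 moderate, 9-12 strong; scores 0-4 form the low-expression group and
#' 5-12 the high-expression group. The banding is defined on every integer
#' 0-12 even though only products of valid factors are attainable from
#' [composite_score()].
#'
#' @param composite Integer score(s) in 0-12.
#' @return `data.frame` with columns `composite`, `band`
#'   (negative/weak/moderate/strong) and `group` (low/high).
#' @examples
#' ish_grade(c(0, 4, 6, 12))
#' @export
ish_grade <- function(composite) {
  check_flag(is.numeric(composite) && all(composite == floor(composite)),
             "composite", "must be integer-valued")
  if (any(composite < 0 | composite > 12)) {
    stop_field("composite", "must lie in 0..12")
  }
  band <- ifelse(composite == 0, "negative",
                 ifelse(composite <= 4, "weak",
                        ifelse(composite <= 8, "moderate", "strong")))
  group <- ifelse(composite <= 4, "low", "high")
  data.frame(composite = as.integer(composite), band = band, group = group,
             stringsAsFactors = FALSE)
}

#' Youden-index optimal cutoff of composite scores
#'
#' Over candidate thresholds `c` in 1..12, specimens are classified high
#' iff `score >= c` against the binary outcome (1 = poor outcome), and the
#' Youden index `J(c) = sensitivity + specificity - 1` is maximized. Ties
#' at the maximum resolve to the smallest cutoff, making the result
#' deterministic and invariant to specimen order.
#'
#' @param scores Integer composite scores in 0-12.
#' @param outcomes Binary outcomes (1 = event within the horizon, 0 =
#'   event-free); both classes must be present.
#' @return `list(cutoff, J, table)` where `table` holds per-threshold
#'   sensitivity, specificity and J.
#' @examples
#' youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))  # cutoff 3, J = 1
#' @export
youden_cutoff <- function(scores, outcomes) {
  check_flag(is.numeric(scores) && length(scores) >= 2L, "scores",
             "needs >= 2 scores")
  check_flag(length(outcomes) == length(scores) &&
               all(outcomes %in% c(0, 1)), "outcomes", "must be 0/1")
  if (length(unique(outcomes)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  pos <- outcomes == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  cand <- 1:12
  sens <- vapply(cand, function(c) sum(scores >= c & pos) / n_pos, numeric(1))
  spec <- vapply(cand, function(c) sum(scores < c & !pos) / n_neg, numeric(1))
  J <- sens + spec - 1
  # smallest cutoff among ties; the tolerance absorbs float rounding of
  # mathematically equal J values reached via different fractions
  best <- which(J >= max(J) - 1e-9)[1]
  list(cutoff = cand[best], J = J[best],
       table = data.frame(cutoff = cand, sensitivity = sens,
                          specificity = spec, J = J))
}
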