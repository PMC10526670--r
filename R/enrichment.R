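# Pull-down miRNA enrichment: TPA normalization, enrichment ranking,
# threshold selection and top-k extraction.

#' Construct a miRNA tag library
#'
#' A tag library holds the raw mature-miRNA-mapped tag counts of one
#' sequencing library (pull-down or control probe) from one cell line. The
#' number of mapped tags is taken as the raw miRNA expression level;
#' `total_aligned` is the sum of all counts.
#'
#' @param counts Named non-negative integer vector of tag counts, one entry
#'   per miRNA.
#' @param cell_line Label of the originating cell line.
#' @param probe Either `"pulldown"` or `"control"`.
#' @return An object of class `tag_library`.
#' @examples
#' lib <- tag_library(c(`miR-a` = 50, `miR-b` = 50), "HGC27", "pulldown")
#' lib$total_aligned
#' @export
tag_library <- function(counts, cell_line = "", probe = c("pulldown", "control")) {
  probe <- match.arg(probe)
  check_flag(is.numeric(counts) && length(counts) > 0, "counts",
             "must be a non-empty numeric vector")
  check_flag(!is.null(names(counts)) && !anyNA(names(counts)) &&
               !any(names(counts) == "") && !anyDuplicated(names(counts)),
             "counts", "must have unique non-empty miRNA names")
  check_flag(all(is.finite(counts)) && all(counts >= 0) &&
               all(counts == floor(counts)),
             "counts", "must be non-negative integers")
  structure(
    list(cell_line = cell_line, probe = probe,
         counts = counts, total_aligned = sum(counts)),
    class = "tag_library"
  )
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("<tag_library> %s/%s: %d miRNAs, %.0f aligned tags\n",
              x$cell_line, x$probe, length(x$counts), x$total_aligned))
  invisible(x)
}

#' Tags-per-million-aligned (TPA) normalization
#'
#' Scales a library's raw tag counts to a common depth of one million
#' aligned tags: `TPA(m) = count(m) / total_aligned * 1e6`. The normalized
#' values always sum to exactly 1e6 (up to floating point).
#'
#' @param lib A [tag_library()].
#' @return Named numeric vector of TPA values.
#' @examples
#' tpa_normalize(tag_library(c(a = 1, b = 0, c = 3)))
#' @export
tpa_normalize <- function(lib) {
  check_flag(inherits(lib, "tag_library"), "lib", "must be a tag_library")
  if (lib$total_aligned <= 0) {
    stop("empty library: total aligned tag count is zero", call. = FALSE)
  }
  lib$counts / lib$total_aligned * 1e6
}

#' Rank miRNA enrichment of a pull-down library over its control
#'
#' Both libraries are TPA-normalized and each miRNA receives
#' `log2((TPA_pulldown + pseudocount) / (TPA_control + pseudocount))`.
#' Records are ranked by log2 enrichment (descending), ties broken by
#' pull-down TPA (descending) then miRNA id (ascending), so the ordering is
#' deterministic across platforms. The pseudocount (default 1 TPA) bounds
#' the ratio when the control count is zero. This is a ranking statistic,
#' not a hypothesis test: no p-values are produced.
#'
#' @param pulldown,control [tag_library()] objects over the same miRNA
#'   universe.
#' @param pseudocount Positive pseudocount on the TPA scale.
#' @return A `data.frame` of class `enrichment_table` with columns `mirna`,
#'   `tpa_pulldown`, `tpa_control`, `log2_enrichment`, `rank`, sorted by
#'   rank.
#' @seealso [select_enriched()], [top_k()]
#' @export
enrichment_scores <- function(pulldown, control, pseudocount = 1) {
  check_flag(is.numeric(pseudocount) && length(pseudocount) == 1L &&
               is.finite(pseudocount) && pseudocount > 0,
             "pseudocount", "must be a positive real")
  tpa_pd <- tpa_normalize(pulldown)
  tpa_ct <- tpa_normalize(control)
  only_pd <- setdiff(names(tpa_pd), names(tpa_ct))
  only_ct <- setdiff(names(tpa_ct), names(tpa_pd))
  if (length(only_pd) || length(only_ct)) {
    stop(sprintf(
      "mismatched miRNA universes; only in pulldown: {%s}; only in control: {%s}",
      paste(only_pd, collapse = ", "), paste(only_ct, collapse = ", ")),
      call. = FALSE)
  }
  ids <- names(tpa_pd)
  tpa_ct <- tpa_ct[ids]
  log2e <- log2((tpa_pd + pseudocount) / (tpa_ct + pseudocount))
  ord <- order(-log2e, -tpa_pd, ids, method = "radix")
  out <- data.frame(
    mirna = ids[ord],
    tpa_pulldown = unname(tpa_pd[ord]),
    tpa_control = unname(tpa_ct[ord]),
    log2_enrichment = unname(log2e[ord]),
    rank = seq_along(ids),
    stringsAsFactors = FALSE
  )
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Select enriched miRNAs by thresholds
#'
#' Keeps miRNAs with `log2_enrichment >= min_log2` and
#' `tpa_pulldown >= min_tpa`. The source study never states the thresholds
#' behind its "highly enriched" sets, so both are analyst knobs; the
#' defaults (one log2 unit, 10 TPA) are a conventional fold/abundance
#' double filter.
#'
#' @param records An `enrichment_table` from [enrichment_scores()].
#' @param min_log2 Minimum log2 enrichment.
#' @param min_tpa Minimum pull-down TPA.
#' @return Character vector of selected miRNA ids (in rank order).
#' @export
select_enriched <- function(records, min_log2 = 1, min_tpa = 10) {
  check_flag(is.data.frame(records), "records", "must be an enrichment table")
  check_flag(is.finite(min_log2), "min_log2", "must be finite")
  check_flag(is.finite(min_tpa), "min_tpa", "must be finite")
  keep <- records$log2_enrichment >= min_log2 & records$tpa_pulldown >= min_tpa
  records$mirna[keep]
}

#' Top-k miRNAs under the enrichment ranking
#'
#' Re-sorts the records under the canonical tie rule (score descending,
#' pull-down TPA descending, id ascending) and returns the first `k` ids,
#' so the result does not depend on the input row order. `k` larger than
#' the table returns all ids.
#'
#' @param records An `enrichment_table`.
#' @param k Non-negative count.
#' @return Ordered character vector of at most `k` miRNA ids.
#' @export
top_k <- function(records, k) {
  check_flag(is.data.frame(records), "records", "must be an enrichment table")
  check_flag(is.numeric(k) && length(k) == 1L && is.finite(k) && k >= 0 &&
               k == floor(k), "k", "must be a non-negative integer")
  ord <- order(-records$log2_enrichment, -records$tpa_pulldown,
               records$mirna, method = "radix")
  head(records$mirna[ord], k)
}
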