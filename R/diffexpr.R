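# RPKM quantification and the fold-change / p-value DEG filter on paired
# overexpression vs control count matrices.

#' Construct a gene-level count matrix
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample labels).
#' @param lengths Positive gene lengths in nucleotides, one per row.
#' @param condition Character/factor of `"case"`/`"control"`, one per
#'   sample column.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, condition) {
  check_flag(is.matrix(counts) && is.numeric(counts), "counts",
             "must be a numeric matrix")
  check_flag(!is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
             "counts", "must have unique gene rownames")
  check_flag(!is.null(colnames(counts)) && !anyDuplicated(colnames(counts)),
             "counts", "must have unique sample colnames")
  check_flag(all(is.finite(counts)) && all(counts >= 0) &&
               all(counts == floor(counts)),
             "counts", "must hold non-negative integers")
  check_flag(is.numeric(lengths) && length(lengths) == nrow(counts) &&
               all(is.finite(lengths)) && all(lengths > 0),
             "lengths", "must be positive, one per gene")
  condition <- as.character(condition)
  check_flag(length(condition) == ncol(counts) &&
               all(condition %in% c("case", "control")),
             "condition", "must be 'case'/'control', one per sample")
  check_flag(any(condition == "case") && any(condition == "control"),
             "condition", "needs at least one sample per condition")
  structure(
    list(counts = counts, lengths = setNames(lengths, rownames(counts)),
         condition = setNames(condition, colnames(counts))),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d case, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "case"), sum(x$condition == "control")))
  invisible(x)
}

#' RPKM matrix
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM(g, s) = 1e9 * count(g, s) / (total(s) * length(g))`.
#'
#' @param cm A [count_matrix()].
#' @return Numeric gene x sample matrix of RPKM values.
#' @export
rpkm_matrix <- function(cm) {
  check_flag(inherits(cm, "count_matrix"), "cm", "must be a count_matrix")
  totals <- colSums(cm$counts)
  if (any(totals <= 0)) {
    bad <- names(totals)[totals <= 0]
    stop(sprintf("zero-depth sample(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  1e9 * sweep(cm$counts / cm$lengths, 2L, totals, "/")
}

#' Log2 fold change of mean RPKM
#'
#' `log2((mean_case + pseudocount) / (mean_control + pseudocount))`, with
#' means taken across replicates. Matrix inputs are averaged by row; vector
#' inputs are used as the per-gene means directly. The pseudocount bounds
#' the ratio when a gene has zero counts in one condition.
#'
#' @param case_rpkm,ctrl_rpkm Per-gene RPKM vectors or gene x replicate
#'   matrices.
#' @param pseudocount Positive pseudocount on the RPKM scale.
#' @return Named per-gene log2 fold changes.
#' @export
log2_fold_change <- function(case_rpkm, ctrl_rpkm, pseudocount = 1) {
  check_flag(is.numeric(pseudocount) && length(pseudocount) == 1L &&
               pseudocount > 0, "pseudocount", "must be positive")
  mc <- if (is.matrix(case_rpkm)) rowMeans(case_rpkm) else case_rpkm
  mt <- if (is.matrix(ctrl_rpkm)) rowMeans(ctrl_rpkm) else ctrl_rpkm
  check_flag(length(mc) == length(mt), "case_rpkm",
             "case and control must cover the same genes")
  log2((mc + pseudocount) / (mt + pseudocount))
}

#' Differential expression test for one gene
#'
#' Two modes are offered because the replicate structure of a study is not
#' always known:
#' \describe{
#'   \item{`exact_unreplicated`}{Two-sided exact binomial test of the
#'     gene's pooled case count against the null proportion given by the
#'     pooled library depths (the classic test for unreplicated count
#'     libraries). The two-sided p-value sums all outcome probabilities not
#'     exceeding that of the observed count.}
#'   \item{`welch_replicated`}{Two-sided Welch (unequal-variance) t-test on
#'     `log2(RPKM + 1)` across replicates; requires at least two replicates
#'     per condition.}
#' }
#'
#' @param cm A [count_matrix()].
#' @param gene Gene id (must be a row of `cm`).
#' @param mode `"exact_unreplicated"` or `"welch_replicated"`.
#' @return A p-value in `[0, 1]`.
#' @export
de_test <- function(cm, gene,
                    mode = c("exact_unreplicated", "welch_replicated")) {
  mode <- match.arg(mode)
  check_flag(inherits(cm, "count_matrix"), "cm", "must be a count_matrix")
  check_flag(gene %in% rownames(cm$counts), "gene",
             sprintf("gene '%s' not present", gene))
  case <- cm$condition == "case"
  if (mode == "exact_unreplicated") {
    depth_case <- sum(cm$counts[, case, drop = FALSE])
    depth_ctrl <- sum(cm$counts[, !case, drop = FALSE])
    x <- sum(cm$counts[gene, case])
    y <- sum(cm$counts[gene, !case])
    exact_binom_p(x, x + y, depth_case / (depth_case + depth_ctrl))
  } else {
    if (sum(case) < 2L || sum(!case) < 2L) {
      stop("welch_replicated requires >= 2 replicates per condition",
           call. = FALSE)
    }
    rpkm <- rpkm_matrix(cm)
    a <- log2(rpkm[gene, case] + 1)
    b <- log2(rpkm[gene, !case] + 1)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    unname(t.test(a, b)$p.value)
  }
}

# Two-sided exact binomial p: sum of dbinom(k) over all k whose density
# does not exceed the observed one (with the customary relative tolerance
# guarding against floating-point ties).
exact_binom_p <- function(x, n, prob) {
  if (n == 0) return(1)
  d <- dbinom(0:n, n, prob)
  min(1, sum(d[d <= d[x + 1L] * (1 + 1e-7)]))
}

#' Per-gene differential expression table
#'
#' Computes log2 fold change and p-value for every gene and classifies the
#' direction under the DEG filter: `up` iff `log2fc > lfc_threshold` and
#' `p < alpha`, `down` symmetrically, otherwise `ns`. No multiple-testing
#' correction is applied by default, mirroring a raw `P < 0.05` screen; set
#' `p_adjust = "BH"` for Benjamini-Hochberg adjusted p-values.
#'
#' @inheritParams de_test
#' @param lfc_threshold,alpha DEG filter thresholds.
#' @param pseudocount RPKM pseudocount for fold changes.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A `data.frame` with columns `gene`, `log2fc`, `p_value`,
#'   `direction`.
#' @export
de_table <- function(cm, mode = c("exact_unreplicated", "welch_replicated"),
                     lfc_threshold = 1, alpha = 0.05, pseudocount = 1,
                     p_adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  p_adjust <- match.arg(p_adjust)
  check_flag(inherits(cm, "count_matrix"), "cm", "must be a count_matrix")
  case <- cm$condition == "case"
  rpkm <- rpkm_matrix(cm)
  lfc <- log2_fold_change(rpkm[, case, drop = FALSE],
                          rpkm[, !case, drop = FALSE], pseudocount)
  genes <- rownames(cm$counts)
  p <- vapply(genes, function(g) de_test(cm, g, mode), numeric(1))
  if (p_adjust == "BH") p <- p.adjust(p, "BH")
  direction <- ifelse(lfc > lfc_threshold & p < alpha, "up",
                      ifelse(lfc < -lfc_threshold & p < alpha, "down", "ns"))
  data.frame(gene = genes, log2fc = unname(lfc), p_value = unname(p),
             direction = unname(direction), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Partition a DEG table into up- and down-regulated gene sets
#'
#' Applies `|log2fc| > lfc_threshold` and `p < alpha` (strict
#' inequalities). The thresholds are re-applied here, so any table with
#' `gene`, `log2fc` and `p_value` columns can be re-filtered; the filter is
#' monotone in both thresholds.
#'
#' @param records A data.frame with columns `gene`, `log2fc`, `p_value`
#'   (e.g. from [de_table()]).
#' @param lfc_threshold,alpha Finite thresholds.
#' @return `list(up = <ids>, down = <ids>)`.
#' @export
filter_degs <- function(records, lfc_threshold = 1, alpha = 0.05) {
  check_flag(is.data.frame(records) &&
               all(c("gene", "log2fc", "p_value") %in% names(records)),
             "records", "needs columns gene, log2fc, p_value")
  check_flag(is.finite(lfc_threshold), "lfc_threshold", "must be finite")
  check_flag(is.finite(alpha), "alpha", "must be finite")
  sig <- records$p_value < alpha
  list(up = records$gene[sig & records$log2fc > lfc_threshold],
       down = records$gene[sig & records$log2fc < -lfc_threshold])
}
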