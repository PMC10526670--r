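# The screening cascade: per-line enrichment -> common set -> top-k union
# and core intersection -> target prediction -> up-DEG overlap ->
# prognostic filter -> core-target intersection -> correlation ranking ->
# core axis. Emits a core-anchored ceRNA network and a per-stage report.

#' Cascade configuration
#'
#' All thresholds of [run_screen()] in one validated object. Defaults
#' mirror the conventional screen: top-10 miRNAs per cell line,
#' `|log2FC| > 1` with `P < 0.05` for DEGs, log2 enrichment >= 1 at >= 10
#' TPA for "highly enriched" miRNAs, 7mer-A1 or better seed sites, median
#' expression split, and a 60-month (five-year) survival horizon.
#'
#' @param k_top Number of top enriched miRNAs taken per cell line.
#' @param lfc_threshold,alpha DEG filter thresholds.
#' @param min_log2_enrichment,min_tpa Enrichment selection thresholds.
#' @param min_site_class Weakest accepted seed-site class.
#' @param combine_mode How dual predictor maps combine (`"union"` or
#'   `"intersection"`).
#' @param split_method Cohort dichotomization method for the prognostic
#'   screen (`"median"`, `"cutoff"`, `"youden"`).
#' @param horizon_months Survival horizon for the direction check.
#' @param de_mode Differential expression test mode (see [de_test()]).
#' @param target_pool Which miRNA set feeds target prediction:
#'   `"topk_union"` (the top-k union; default) or `"common"` (the full
#'   common enriched set).
#' @param pseudocount_tpa,pseudocount_rpkm Pseudocounts for enrichment and
#'   fold-change ratios.
#' @return Object of class `cascade_config`.
#' @export
cascade_config <- function(k_top = 10L, lfc_threshold = 1, alpha = 0.05,
                           min_log2_enrichment = 1, min_tpa = 10,
                           min_site_class = "7mer-A1",
                           combine_mode = c("union", "intersection"),
                           split_method = c("median", "cutoff", "youden"),
                           horizon_months = 60,
                           de_mode = c("exact_unreplicated",
                                       "welch_replicated"),
                           target_pool = c("topk_union", "common"),
                           pseudocount_tpa = 1, pseudocount_rpkm = 1) {
  cfg <- list(
    k_top = k_top, lfc_threshold = lfc_threshold, alpha = alpha,
    min_log2_enrichment = min_log2_enrichment, min_tpa = min_tpa,
    min_site_class = min_site_class,
    combine_mode = match.arg(combine_mode),
    split_method = match.arg(split_method),
    horizon_months = horizon_months,
    de_mode = match.arg(de_mode),
    target_pool = match.arg(target_pool),
    pseudocount_tpa = pseudocount_tpa, pseudocount_rpkm = pseudocount_rpkm
  )
  check_flag(is.numeric(cfg$k_top) && cfg$k_top >= 1 &&
               cfg$k_top == floor(cfg$k_top), "k_top",
             "must be a positive integer")
  for (f in c("lfc_threshold", "alpha", "min_log2_enrichment", "min_tpa",
              "horizon_months")) {
    check_flag(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L &&
                 is.finite(cfg[[f]]), f, "must be a finite number")
  }
  check_flag(cfg$min_site_class %in% SITE_CLASSES, "min_site_class",
             "unknown site class")
  class(cfg) <- "cascade_config"
  cfg
}

#' Union and intersection of two top-k lists
#'
#' `|union| = |a| + |b| - |core|`; with two top-10 lists sharing exactly 4
#' ids this yields a 16-member union and a 4-member core.
#'
#' @param a,b Character vectors of miRNA ids.
#' @return `list(union =, core =)` of id sets.
#' @export
merge_topk <- function(a, b) {
  list(union = union(a, b), core = intersect(a, b))
}

#' Prognostic filter on a gene set
#'
#' Keeps a gene iff, after dichotomizing the cohort on its expression
#' (`cfg$split_method`), the two-sample log-rank test gives
#' `p < cfg$alpha` AND the high-expression group has the worse survival at
#' the horizon (`S_high(horizon) < S_low(horizon)`). The direction check
#' makes "associated with poor prognosis" explicit: protective genes are
#' excluded no matter how small their p-value.
#'
#' @param genes Character vector of gene ids.
#' @param cohort Cohort data.frame with `time_months`, `event` and
#'   `expr_<gene>` columns.
#' @param cfg A [cascade_config()].
#' @return Character vector of retained gene ids.
#' @export
prognostic_filter <- function(genes, cohort, cfg = cascade_config()) {
  check_flag(is.data.frame(cohort) &&
               all(c("time_months", "event") %in% names(cohort)),
             "cohort", "needs time_months and event columns")
  keep <- logical(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    col <- paste0("expr_", g)
    if (!col %in% names(cohort)) {
      stop(sprintf("cohort has no expression column for gene '%s'", g),
           call. = FALSE)
    }
    vals <- cohort[[col]]
    group <- tryCatch(
      split_cohort(vals, cohort, cfg),
      error = function(e) NULL
    )
    if (is.null(group) || length(unique(group)) < 2L) next
    lr <- tryCatch(logrank_test(cohort$time_months, cohort$event, group),
                   error = function(e) NULL)
    if (is.null(lr) || lr$p_value >= cfg$alpha) next
    s_high <- survival_at(km_estimate(cohort$time_months[group == "high"],
                                      cohort$event[group == "high"]),
                          cfg$horizon_months)
    s_low <- survival_at(km_estimate(cohort$time_months[group == "low"],
                                     cohort$event[group == "low"]),
                         cfg$horizon_months)
    keep[i] <- s_high < s_low
  }
  genes[keep]
}

# Dichotomize one gene's expression under the cascade configuration. The
# Youden variant classifies against death within the horizon, excluding
# subjects censored before it from cutoff estimation.
split_cohort <- function(vals, cohort, cfg) {
  if (cfg$split_method == "youden") {
    eligible <- !(cohort$event == 0 & cohort$time_months < cfg$horizon_months)
    outcome <- as.integer(cohort$event == 1 &
                            cohort$time_months <= cfg$horizon_months)
    yc <- youden_cutoff(vals[eligible], outcome[eligible])
    ifelse(vals >= yc$cutoff, "high", "low")
  } else {
    dichotomize(vals, cfg$split_method,
                cutoff = if (cfg$split_method == "cutoff") cfg$cutoff else NULL)
  }
}

#' Rank candidate genes by correlation with the core gene
#'
#' Spearman rank correlation of each gene's cohort expression against the
#' core gene's, sorted descending (ties by gene id).
#'
#' @param final_genes Character vector of gene ids (may be empty).
#' @param core_gene Core gene id.
#' @param cohort Cohort data.frame with `expr_<gene>` columns.
#' @return `data.frame(gene, rho, p_value)` in ranking order.
#' @export
rank_core_axis <- function(final_genes, core_gene, cohort) {
  if (!length(final_genes)) {
    return(data.frame(gene = character(0), rho = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  core_col <- paste0("expr_", core_gene)
  check_flag(core_col %in% names(cohort), "core_gene",
             sprintf("cohort has no expression column for '%s'", core_gene))
  rows <- lapply(final_genes, function(g) {
    col <- paste0("expr_", g)
    if (!col %in% names(cohort)) {
      stop(sprintf("cohort has no expression column for gene '%s'", g),
           call. = FALSE)
    }
    s <- spearman_rho(cohort[[col]], cohort[[core_col]])
    data.frame(gene = g, rho = s$rho, p_value = s$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rho, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full screening cascade
#'
#' Executes, in order: (1) per-cell-line enrichment scoring and threshold
#' selection; (2) intersection across lines into the common enriched set;
#' (3) per-line top-k and their union into the candidate miRNA set;
#' (4) intersection of the top-k lists into the core miRNAs; (5) seed-match
#' target prediction for the candidate set and intersection with the
#' up-regulated DEGs; (6) the prognostic filter; (7) intersection of the
#' surviving genes with the targets of core miRNAs; (8) Spearman ranking
#' against the core gene — the top gene and its strongest-enriched core
#' miRNA form the core axis. An empty stage empties everything downstream
#' with a warning but never errors.
#'
#' @param cfg A [cascade_config()].
#' @param pulldown Named list (one entry per cell line) of
#'   `list(pulldown =, control = <tag_library>)`.
#' @param counts A [count_matrix()] of the overexpression experiment.
#' @param sequences `list(mirnas = <named mature sequences>, core_utr =
#'   <named string>, target_utrs = <named character>)`.
#' @param cohort Cohort data.frame (`time_months`, `event`,
#'   `expr_<gene>`).
#' @param core_gene Core gene id for the correlation ranking.
#' @param verbose Log stage cardinalities to standard error.
#' @return `list(network = <cerna_network>, report = <cascade_report>)`.
#' @export
run_screen <- function(cfg, pulldown, counts, sequences, cohort,
                       core_gene = "FN1", verbose = FALSE) {
  check_flag(inherits(cfg, "cascade_config"), "cfg",
             "must be a cascade_config")
  check_flag(is.list(pulldown) && length(pulldown) >= 2L &&
               !is.null(names(pulldown)), "pulldown",
             "needs >= 2 named cell lines of pull-down data")
  say <- function(...) if (verbose) message(sprintf(...))

  # (1) per-line enrichment
  scores <- lapply(pulldown, function(pp) {
    enrichment_scores(pp$pulldown, pp$control, cfg$pseudocount_tpa)
  })
  enriched <- lapply(scores, select_enriched,
                     min_log2 = cfg$min_log2_enrichment,
                     min_tpa = cfg$min_tpa)
  n_enriched <- vapply(enriched, length, integer(1))
  say("enriched per line: %s", paste(n_enriched, collapse = "/"))

  # (2) common enriched set
  common <- Reduce(intersect, enriched)
  if (!length(common)) warning("empty stage: no common enriched miRNAs",
                               call. = FALSE)
  say("common enriched: %d", length(common))

  # (3)-(4) top-k union and core intersection
  topk <- lapply(scores, top_k, k = cfg$k_top)
  top_union <- Reduce(union, topk)
  core_mirnas <- Reduce(intersect, topk)
  if (!length(core_mirnas)) warning("empty stage: no core miRNAs",
                                    call. = FALSE)
  say("top-%d union: %d; core: %d", cfg$k_top, length(top_union),
      length(core_mirnas))

  # (5) target prediction for the candidate pool, overlap with up-DEGs
  candidates <- if (cfg$target_pool == "topk_union") top_union else common
  candidates <- candidates[candidates %in% names(sequences$mirnas)]
  tmap <- if (length(candidates)) {
    predict_targets(sequences$mirnas[candidates], sequences$target_utrs,
                    cfg$min_site_class)
  } else {
    structure(list(edges = setNames(list(), character(0)),
                   sites = empty_sites(), predictor = "seedmatch"),
              class = "target_map")
  }
  target_genes <- sort(unique(unlist(tmap$edges, use.names = FALSE)))
  de <- de_table(counts, mode = cfg$de_mode,
                 lfc_threshold = cfg$lfc_threshold, alpha = cfg$alpha,
                 pseudocount = cfg$pseudocount_rpkm)
  degs <- filter_degs(de, cfg$lfc_threshold, cfg$alpha)
  overlap <- intersect(target_genes, degs$up)
  if (!length(overlap)) warning("empty stage: no target/up-DEG overlap",
                                call. = FALSE)
  say("targets: %d; up-DEGs: %d; overlap: %d", length(target_genes),
      length(degs$up), length(overlap))

  # (6) prognostic filter
  prognostic <- if (length(overlap)) {
    prognostic_filter(overlap, cohort, cfg)
  } else character(0)
  say("prognostic: %d", length(prognostic))

  # (7) restrict to targets of the core miRNAs
  core_targets <- sort(unique(unlist(tmap$edges[intersect(core_mirnas,
                                                          names(tmap$edges))],
                                     use.names = FALSE)))
  final_genes <- intersect(prognostic, core_targets)
  if (!length(final_genes)) warning("empty stage: no final genes",
                                    call. = FALSE)
  say("final genes: %d", length(final_genes))

  # (8) correlation ranking and axis selection
  ranking <- rank_core_axis(final_genes, core_gene, cohort)
  core_axis <- NULL
  if (nrow(ranking)) {
    top_gene <- ranking$gene[1]
    linked <- intersect(core_mirnas, names(tmap$edges))
    linked <- linked[vapply(linked, function(m) top_gene %in% tmap$edges[[m]],
                            logical(1))]
    if (length(linked)) {
      mean_enr <- vapply(linked, function(m) {
        mean(vapply(scores, function(s) {
          s$log2_enrichment[match(m, s$mirna)]
        }, numeric(1)))
      }, numeric(1))
      best <- linked[order(-mean_enr, linked)][1]
      core_axis <- list(mirna = best, gene = top_gene)
      say("core axis: %s -> %s", best, top_gene)
    }
  }

  report <- structure(list(
    n_enriched = as.list(n_enriched), n_common = length(common),
    top_union = top_union, core_mirnas = core_mirnas,
    n_targets = length(target_genes),
    n_up_degs = length(degs$up), n_down_degs = length(degs$down),
    n_target_up_overlap = length(overlap),
    n_prognostic = length(prognostic),
    final_genes = final_genes, ranking = ranking, core_axis = core_axis
  ), class = "cascade_report")

  network <- build_network(names(sequences$core_utr)[1] %||% "core",
                           candidates, final_genes, tmap, sequences, cfg)
  list(network = network, report = report)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  cat(sprintf("  enriched per line: %s | common: %d\n",
              paste(unlist(x$n_enriched), collapse = "/"), x$n_common))
  cat(sprintf("  top-k union: %d | core miRNAs: %d\n",
              length(x$top_union), length(x$core_mirnas)))
  cat(sprintf("  targets: %d | up-DEGs: %d | overlap: %d | prognostic: %d\n",
              x$n_targets, x$n_up_degs, x$n_target_up_overlap,
              x$n_prognostic))
  cat(sprintf("  final genes: %s\n",
              paste(x$final_genes, collapse = ", ")))
  if (!is.null(x$core_axis)) {
    cat(sprintf("  core axis: %s -> %s\n", x$core_axis$mirna,
                x$core_axis$gene))
  }
  invisible(x)
}

# Assemble the core-anchored network: core edges are backed by predicted
# sites on the core UTR; target edges by the prediction provenance.
build_network <- function(core_id, candidates, final_genes, tmap,
                          sequences, cfg) {
  core_edges <- data.frame(source = character(0), target = character(0),
                           evidence = character(0), stringsAsFactors = FALSE)
  if (length(candidates)) {
    core_map <- predict_targets(sequences$mirnas[candidates],
                                setNames(as.character(sequences$core_utr[1]),
                                         core_id),
                                cfg$min_site_class)
    rows <- lapply(sort(candidates), function(m) {
      s <- core_map$sites[core_map$sites$mirna == m, , drop = FALSE]
      if (!nrow(s)) return(NULL)
      tab <- table(s$site_class)
      data.frame(source = core_id, target = m,
                 evidence = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                                  collapse = ","),
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) core_edges <- do.call(rbind, rows)
  }
  target_edges <- data.frame(source = character(0), target = character(0),
                             evidence = character(0),
                             stringsAsFactors = FALSE)
  if (length(final_genes)) {
    rows <- list()
    for (m in sort(names(tmap$edges))) {
      for (g in sort(intersect(tmap$edges[[m]], final_genes))) {
        s <- tmap$sites[tmap$sites$mirna == m & tmap$sites$utr == g, ,
                        drop = FALSE]
        tab <- table(s$site_class)
        rows[[length(rows) + 1L]] <- data.frame(
          source = m, target = g,
          evidence = paste(paste(tmap$predictor, collapse = "+"),
                           paste(sprintf("%s:%d", names(tab),
                                         as.integer(tab)), collapse = ","),
                           sep = ";"),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) target_edges <- do.call(rbind, rows)
  }
  structure(list(core = core_id,
                 mirna_nodes = sort(unique(c(core_edges$target,
                                             target_edges$source))),
                 gene_nodes = sort(unique(target_edges$target)),
                 core_edges = core_edges, target_edges = target_edges),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> core '%s': %d miRNA nodes, %d gene nodes, %d + %d edges\n",
              x$core, length(x$mirna_nodes), length(x$gene_nodes),
              nrow(x$core_edges), nrow(x$target_edges)))
  invisible(x)
}

#' Export a ceRNA network and cascade report to disk
#'
#' Writes `edges.tsv` (columns `source`, `target`, `edge_type`,
#' `evidence`; core edges first) and `report.json`. The pair round-trips
#' losslessly through [read_network()]: write -> read -> write produces
#' identical bytes.
#'
#' @param network A `cerna_network` (from [run_screen()]).
#' @param report The matching `cascade_report`.
#' @param path Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, report, path) {
  check_flag(inherits(network, "cerna_network"), "network",
             "must be a cerna_network")
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", path),
                  call. = FALSE)
  }
  edges <- rbind(
    if (nrow(network$core_edges)) {
      cbind(network$core_edges[, c("source", "target")],
            edge_type = "core", evidence = network$core_edges$evidence)
    },
    if (nrow(network$target_edges)) {
      cbind(network$target_edges[, c("source", "target")],
            edge_type = "target", evidence = network$target_edges$evidence)
    }
  )
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        edge_type = character(0), evidence = character(0))
  }
  edge_path <- file.path(path, "edges.tsv")
  report_path <- file.path(path, "report.json")
  write.table(edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  rep_list <- unclass(report)
  rep_list$core <- network$core
  jsonlite::write_json(rep_list, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(c(edges = edge_path, report = report_path))
}

#' Read back an exported network and report
#'
#' @param path Directory previously written by [export_network()].
#' @return `list(network = <cerna_network>, report = <cascade_report>)`.
#' @export
read_network <- function(path) {
  edge_path <- file.path(path, "edges.tsv")
  report_path <- file.path(path, "report.json")
  check_flag(file.exists(edge_path) && file.exists(report_path), "path",
             "must contain edges.tsv and report.json")
  edges <- read.delim(edge_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  rep_raw <- jsonlite::read_json(report_path, simplifyVector = TRUE)
  core_id <- rep_raw$core
  rep_raw$core <- NULL
  # read_json simplifies empty arrays to list(); restore character vectors
  for (f in c("top_union", "core_mirnas", "final_genes")) {
    rep_raw[[f]] <- as.character(unlist(rep_raw[[f]]))
  }
  if (is.null(rep_raw$core_axis) || !length(rep_raw$core_axis)) {
    rep_raw["core_axis"] <- list(NULL)
  }
  rep_raw$ranking <- as.data.frame(rep_raw$ranking)
  if (!nrow(rep_raw$ranking)) {
    rep_raw$ranking <- data.frame(gene = character(0), rho = numeric(0),
                                  p_value = numeric(0),
                                  stringsAsFactors = FALSE)
  }
  report <- structure(rep_raw, class = "cascade_report")
  ce <- edges[edges$edge_type == "core", c("source", "target", "evidence")]
  te <- edges[edges$edge_type == "target", c("source", "target", "evidence")]
  rownames(ce) <- rownames(te) <- NULL
  network <- structure(list(
    core = core_id,
    mirna_nodes = sort(unique(c(ce$target, te$source))),
    gene_nodes = sort(unique(te$target)),
    core_edges = ce, target_edges = te
  ), class = "cerna_network")
  list(network = network, report = report)
}
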