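# A coherent synthetic input set for the whole cascade, with one planted
# (miRNA, gene) core axis as ground truth.

#' Simulate a full screening bundle with a planted core axis
#'
#' Generates everything [run_screen()] consumes, wired so that one
#' (miRNA, gene) axis is the planted answer:
#' \itemize{
#'   \item a shared set of `cfg$n_planted_mirna` sponge miRNAs enriched in
#'     the pull-down of both cell lines at `cfg$enrichment_fold`; the axis
#'     miRNA is boosted to four times that fold (two extra log2 units,
#'     about 3 SD of the negative-binomial ratio noise at the default
#'     dispersion) so it reliably tops both lines;
#'   \item count matrices whose planted up-regulated genes include the
#'     axis gene;
#'   \item a core UTR carrying one site per planted miRNA and target UTRs
#'     in which the axis gene hosts the axis miRNA's site and a few other
#'     planted up-genes host sites of other planted miRNAs (backgrounds
#'     are site-free for the planted miRNA set); non-regulated genes get
#'     unconstrained random UTRs;
#'   \item a cohort in which the axis gene correlates 0.7 with the core
#'     gene (the decoy target genes 0.25) and the hazard rises with core
#'     expression at `cfg$beta` per SD.
#' }
#'
#' @param cfg A [sim_config()].
#' @param cell_lines Two or more cell-line labels.
#' @param core_gene Core gene id used in cohort and ranking.
#' @param n_decoy_edges How many non-axis planted up-genes also receive a
#'   planted miRNA site.
#' @param n_extra_utrs How many non-differential genes receive (random)
#'   UTRs and cohort expression.
#' @return `list(pulldown, counts, sequences, cohort, truth)`; `truth$axis`
#'   is `list(mirna =, gene =)`.
#' @export
simulate_bundle <- function(cfg, cell_lines = c("cell_A", "cell_B"),
                            core_gene = "FN1", n_decoy_edges = 5L,
                            n_extra_utrs = 170L) {
  validate_sim_config(cfg)
  check_flag(length(cell_lines) >= 2L, "cell_lines",
             "needs at least two cell lines")
  check_flag(cfg$n_planted_mirna >= 2L, "n_planted_mirna",
             "bundle needs >= 2 planted miRNAs")
  check_flag(cfg$n_up >= n_decoy_edges + 1L, "n_up",
             "bundle needs n_up > n_decoy_edges")

  mids <- mirna_ids(cfg$n_mirna)
  gids <- gene_ids(cfg$n_genes)
  with_seed(derive_seed(cfg$seed, 5L), {
    mirna_seqs <- random_mirna_set(cfg$n_mirna)
    planted_mirnas <- sort(compatible_subset(mirna_seqs, sample(mids),
                                             cfg$n_planted_mirna,
                                             cfg$site_classes[1]))
    axis_mirna <- sample(planted_mirnas, 1L)
    picked <- sample(gids, cfg$n_up + cfg$n_down)
    planted_up <- sort(picked[seq_len(cfg$n_up)])
    planted_down <- sort(setdiff(picked, planted_up))
    axis_gene <- sample(planted_up, 1L)
    decoy_genes <- sample(setdiff(planted_up, axis_gene), n_decoy_edges)
    decoy_mirnas <- sample(setdiff(planted_mirnas, axis_mirna),
                           n_decoy_edges, replace = n_decoy_edges >
                             (cfg$n_planted_mirna - 1L))
    extra <- sample(setdiff(gids, c(planted_up, planted_down)),
                    min(n_extra_utrs, cfg$n_genes - cfg$n_up - cfg$n_down))
  })

  folds <- setNames(rep(cfg$enrichment_fold, length(planted_mirnas)),
                    planted_mirnas)
  folds[axis_mirna] <- 4 * cfg$enrichment_fold
  pulldown <- lapply(cell_lines, function(cl) {
    sim <- simulate_pulldown(cfg, cell_line = cl, planted = planted_mirnas,
                             folds = folds)
    sim[c("pulldown", "control")]
  })
  names(pulldown) <- cell_lines

  counts <- simulate_counts(cfg, planted_up = planted_up,
                            planted_down = planted_down)

  edges <- c(setNames(list(axis_mirna), axis_gene),
             setNames(as.list(decoy_mirnas), decoy_genes))
  seqs <- simulate_sequences(cfg, mirna_seqs[planted_mirnas], edges = edges,
                             core_id = core_gene)
  # unconstrained random UTRs for genes outside the planted regulatory set
  other_utrs <- with_seed(derive_seed(cfg$seed, 6L), {
    other <- setdiff(c(planted_up, planted_down, extra), names(edges))
    setNames(vapply(other, function(g) random_dna(cfg$utr_length),
                    character(1)), other)
  })
  target_utrs <- c(seqs$target_utrs, other_utrs)
  target_utrs <- target_utrs[order(names(target_utrs))]

  cohort_genes <- names(target_utrs)
  cors <- setNames(rep(0, length(cohort_genes)), cohort_genes)
  cors[decoy_genes] <- 0.25
  cors[axis_gene] <- 0.7
  cohort <- simulate_cohort(cfg, core_gene = core_gene,
                            genes = cohort_genes, cors = unname(cors))

  truth <- list(
    axis = list(mirna = axis_mirna, gene = axis_gene),
    planted_mirnas = planted_mirnas, folds = folds,
    planted_up = planted_up, planted_down = planted_down,
    edges = edges, planted_sites = seqs$truth$planted_sites,
    cors = cors, true_beta = cfg$beta, core_gene = core_gene
  )
  list(
    pulldown = pulldown,
    counts = counts$counts,
    sequences = list(mirnas = mirna_seqs, core_utr = seqs$core_utr,
                     target_utrs = target_utrs),
    cohort = cohort$cohort,
    truth = truth
  )
}
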