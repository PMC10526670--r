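# Synthetic tag libraries and count matrices with planted ground truth.
# Counts are negative binomial with user overdispersion (variance
# mu + dispersion * mu^2; Poisson when dispersion = 0), which matches the
# overdispersion of real sequencing counts.

nb_counts <- function(mu, dispersion) {
  if (dispersion == 0) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  }
}

mirna_ids <- function(n) sprintf("mir-%04d", seq_len(n))

gene_ids <- function(n) sprintf("gene_%04d", seq_len(n))

#' Simulate a pull-down / control tag-library pair
#'
#' Baseline miRNA abundances are log-normal (sdlog 1) and shared between
#' the two libraries. Planted miRNAs have expected pull-down abundance
#' `enrichment_fold` times their control abundance; the pull-down library
#' depth therefore inflates with the captured material rather than being
#' renormalized, so the planted raw-count ratio is the fold itself in
#' expectation. Counts are negative binomial with `cfg$dispersion`.
#'
#' @param cfg A [sim_config()].
#' @param cell_line Label stored in both libraries.
#' @param planted Optional character vector of planted miRNA ids (defaults
#'   to a random draw of `cfg$n_planted_mirna` ids).
#' @param folds Optional named per-miRNA fold overrides for the planted
#'   set.
#' @return `list(pulldown =, control = <tag_library>, truth = list(
#'   planted_mirnas, folds))`.
#' @export
simulate_pulldown <- function(cfg, cell_line = "HGC27", planted = NULL,
                              folds = NULL) {
  validate_sim_config(cfg)
  ids <- mirna_ids(cfg$n_mirna)
  if (!is.null(planted)) {
    check_flag(all(planted %in% ids), "planted",
               "planted ids must exist in the miRNA universe")
  }
  with_seed(derive_seed(cfg$seed, 11L + sum(utf8ToInt(cell_line))), {
    prop <- rlnorm(cfg$n_mirna, meanlog = 0, sdlog = 1)
    prop <- prop / sum(prop)
    if (is.null(planted)) {
      planted <- sort(sample(ids, cfg$n_planted_mirna))
    }
    fold_vec <- setNames(rep(1, cfg$n_mirna), ids)
    fold_vec[planted] <- cfg$enrichment_fold
    if (!is.null(folds)) fold_vec[names(folds)] <- folds
    mu_ctrl <- prop * cfg$library_depth
    mu_pd <- mu_ctrl * fold_vec
    ctrl_counts <- setNames(nb_counts(mu_ctrl, cfg$dispersion), ids)
    pd_counts <- setNames(nb_counts(mu_pd, cfg$dispersion), ids)
    list(
      pulldown = tag_library(pd_counts, cell_line, "pulldown"),
      control = tag_library(ctrl_counts, cell_line, "control"),
      truth = list(planted_mirnas = planted,
                   folds = fold_vec[planted])
    )
  })
}

#' Simulate an overexpression vs control count matrix
#'
#' Gene lengths are sampled once (500-5000 nt) and shared across
#' conditions; baseline abundances are log-normal. Planted up/down genes
#' have expected log2 RPKM difference `+/- cfg$planted_lfc`, all other
#' genes 0 (up to the mild depth renormalization that RPKM induces when
#' planted mass shifts the case library total).
#'
#' @param cfg A [sim_config()].
#' @param planted_up,planted_down Optional explicit planted gene id sets.
#' @return `list(counts = <count_matrix>, truth = list(planted_up,
#'   planted_down, lengths))`.
#' @export
simulate_counts <- function(cfg, planted_up = NULL, planted_down = NULL) {
  validate_sim_config(cfg)
  ids <- gene_ids(cfg$n_genes)
  for (arg in list(planted_up, planted_down)) {
    if (!is.null(arg)) {
      check_flag(all(arg %in% ids), "planted_up",
                 "planted ids must exist in the gene universe")
    }
  }
  with_seed(derive_seed(cfg$seed, 23L), {
    lengths <- sample(500:5000, cfg$n_genes, replace = TRUE)
    prop <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
    prop <- prop / sum(prop)
    if (is.null(planted_up) || is.null(planted_down)) {
      pick <- sample(ids, cfg$n_up + cfg$n_down)
      if (is.null(planted_up)) planted_up <- sort(pick[seq_len(cfg$n_up)])
      if (is.null(planted_down)) {
        pool <- setdiff(pick, planted_up)
        planted_down <- sort(pool[seq_len(min(cfg$n_down, length(pool)))])
      }
    }
    effect <- setNames(rep(1, cfg$n_genes), ids)
    effect[planted_up] <- 2^cfg$planted_lfc
    effect[planted_down] <- 2^(-cfg$planted_lfc)
    mu_ctrl <- prop * cfg$library_depth
    mu_case <- mu_ctrl * effect
    n_samp <- 2L * cfg$n_reps
    counts <- matrix(0L, cfg$n_genes, n_samp,
                     dimnames = list(ids, c(paste0("case_", seq_len(cfg$n_reps)),
                                            paste0("ctrl_", seq_len(cfg$n_reps)))))
    for (r in seq_len(cfg$n_reps)) {
      counts[, r] <- nb_counts(mu_case, cfg$dispersion)
      counts[, cfg$n_reps + r] <- nb_counts(mu_ctrl, cfg$dispersion)
    }
    cm <- count_matrix(counts, lengths,
                       rep(c("case", "control"), each = cfg$n_reps))
    list(counts = cm,
         truth = list(planted_up = planted_up, planted_down = planted_down,
                      lengths = setNames(lengths, ids)))
  })
}
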