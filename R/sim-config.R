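#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. Defaults describe a desk-scale pull-down/RNA-seq/cohort study:
#' 500 miRNAs with 20 planted sponge miRNAs at 8-fold capture enrichment,
#' tag libraries of one million aligned tags, 2000 genes with 30 planted
#' up- and 30 down-regulated genes at |log2 fold change| 2 across three
#' replicates, 300-nt 3'-UTRs, and a 500-patient cohort whose hazard rises
#' with core-gene expression (log-hazard 0.8 per SD) under 30% independent
#' censoring over a 60-month horizon.
#'
#' @param seed Integer master RNG seed; every generator derives its own
#'   sub-stream from it.
#' @param n_mirna Number of miRNAs in the tag-library universe.
#' @param n_planted_mirna Number of miRNAs planted as truly enriched in the
#'   pull-down libraries. Must not exceed `n_mirna`.
#' @param enrichment_fold Expected pull-down/control abundance ratio of the
#'   planted miRNAs (>= 1; 1 means no enrichment anywhere).
#' @param library_depth Expected total tag count per library.
#' @param n_genes Number of genes in the count matrices.
#' @param n_up,n_down Numbers of planted up-/down-regulated genes;
#'   `n_up + n_down` must not exceed `n_genes`.
#' @param planted_lfc Planted absolute log2 fold change (RPKM scale) of the
#'   differential genes.
#' @param dispersion Negative-binomial overdispersion of all simulated
#'   counts (variance `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param n_reps RNA-seq replicates per condition.
#' @param utr_length Length in nucleotides of each simulated 3'-UTR.
#' @param site_classes Seed-site class(es) planted into UTRs; any of
#'   `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`.
#' @param n_patients Cohort size.
#' @param beta Per-SD log-hazard effect of standardized core-gene
#'   expression on survival.
#' @param censor_rate Fraction of subjects censored (independent
#'   exponential censoring), in `[0, 1)`.
#' @param horizon_months Follow-up horizon in months (5-year overall
#'   survival corresponds to 60).
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(seed = 42, n_mirna = 100, n_planted_mirna = 5)
#' cfg$enrichment_fold
#' @export
sim_config <- function(seed = 1L,
                       n_mirna = 500L,
                       n_planted_mirna = 20L,
                       enrichment_fold = 8,
                       library_depth = 1e6,
                       n_genes = 2000L,
                       n_up = 30L,
                       n_down = 30L,
                       planted_lfc = 2,
                       dispersion = 0.1,
                       n_reps = 3L,
                       utr_length = 300L,
                       site_classes = "8mer",
                       n_patients = 500L,
                       beta = 0.8,
                       censor_rate = 0.3,
                       horizon_months = 60) {
  cfg <- list(
    seed = seed, n_mirna = n_mirna, n_planted_mirna = n_planted_mirna,
    enrichment_fold = enrichment_fold, library_depth = library_depth,
    n_genes = n_genes, n_up = n_up, n_down = n_down,
    planted_lfc = planted_lfc, dispersion = dispersion, n_reps = n_reps,
    utr_length = utr_length, site_classes = site_classes,
    n_patients = n_patients, beta = beta, censor_rate = censor_rate,
    horizon_months = horizon_months
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  is_count <- function(x) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 &&
      x == floor(x)
  }
  is_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  check_flag(is_count(cfg$seed) || (is_num(cfg$seed) && cfg$seed == floor(cfg$seed)),
             "seed", "must be a single integer")
  check_flag(is_count(cfg$n_mirna), "n_mirna", "must be a positive integer")
  check_flag(is_count(cfg$n_planted_mirna) || cfg$n_planted_mirna == 0,
             "n_planted_mirna", "must be a non-negative integer")
  check_flag(cfg$n_planted_mirna <= cfg$n_mirna, "n_planted_mirna",
             "must not exceed n_mirna")
  check_flag(is_num(cfg$enrichment_fold) && cfg$enrichment_fold >= 1,
             "enrichment_fold", "must be a real >= 1")
  check_flag(is_num(cfg$library_depth) && cfg$library_depth > 0,
             "library_depth", "must be positive")
  check_flag(is_count(cfg$n_genes), "n_genes", "must be a positive integer")
  check_flag(is_num(cfg$n_up) && cfg$n_up >= 0 && cfg$n_up == floor(cfg$n_up),
             "n_up", "must be a non-negative integer")
  check_flag(is_num(cfg$n_down) && cfg$n_down >= 0 && cfg$n_down == floor(cfg$n_down),
             "n_down", "must be a non-negative integer")
  check_flag(cfg$n_up + cfg$n_down <= cfg$n_genes, "n_up",
             "n_up + n_down must not exceed n_genes")
  check_flag(is_num(cfg$planted_lfc), "planted_lfc", "must be a finite real")
  check_flag(is_num(cfg$dispersion) && cfg$dispersion >= 0,
             "dispersion", "must be non-negative")
  check_flag(is_count(cfg$n_reps), "n_reps", "must be a positive integer")
  check_flag(is_count(cfg$utr_length), "utr_length",
             "must be a positive integer")
  check_flag(is.character(cfg$site_classes) &&
               all(cfg$site_classes %in% SITE_CLASSES),
             "site_classes",
             sprintf("must be among %s", paste(SITE_CLASSES, collapse = ", ")))
  check_flag(is_count(cfg$n_patients), "n_patients",
             "must be a positive integer")
  check_flag(is_num(cfg$beta), "beta", "must be a finite real")
  check_flag(is_num(cfg$censor_rate) && cfg$censor_rate >= 0 &&
               cfg$censor_rate < 1,
             "censor_rate", "must lie in [0, 1)")
  check_flag(is_num(cfg$horizon_months) && cfg$horizon_months > 0,
             "horizon_months", "must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d miRNAs (%d planted, fold %.3g) | depth %.3g\n",
              as.integer(x$seed), x$n_mirna, x$n_planted_mirna,
              x$enrichment_fold, x$library_depth))
  cat(sprintf("  %d genes (%d up / %d down at lfc %.3g), %d reps, disp %.3g\n",
              x$n_genes, x$n_up, x$n_down, x$planted_lfc, x$n_reps,
              x$dispersion))
  cat(sprintf("  UTR %d nt | cohort n=%d, beta %.3g, censor %.3g, horizon %.3g mo\n",
              x$utr_length, x$n_patients, x$beta, x$censor_rate,
              x$horizon_months))
  invisible(x)
}
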