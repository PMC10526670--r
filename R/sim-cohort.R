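# Synthetic patient cohorts and ISH specimen tables with planted
# prognostic structure.

#' Simulate a survival cohort driven by core-gene expression
#'
#' Core-gene expression is standard normal; each target gene's expression
#' is correlated with the core at its stated correlation (Gaussian
#' copula-free construction `r * z + sqrt(1 - r^2) * noise`). Event times
#' are exponential with log-hazard `cfg$beta` per SD of core expression
#' around a baseline hazard tuned to a 36-month median survival; censoring
#' is an independent exponential time calibrated so that, at `beta = 0`, a
#' fraction `cfg$censor_rate` of subjects is censored (`censor_rate = 0`
#' gives all-event data).
#'
#' @param cfg A [sim_config()]; `beta` must be finite.
#' @param core_gene Id of the hazard-driving core gene.
#' @param genes Optional character vector of additional gene ids.
#' @param cors Correlations with the core gene, recycled over `genes`
#'   (default 0).
#' @return `list(cohort = <data.frame>, truth)`. The cohort has columns
#'   `patient_id`, `time_months`, `event` and one `expr_<gene>` column per
#'   gene (core first).
#' @export
simulate_cohort <- function(cfg, core_gene = "FN1", genes = character(0),
                            cors = 0) {
  validate_sim_config(cfg)
  check_flag(is.finite(cfg$beta), "beta", "must be finite")
  if (length(genes)) cors <- rep_len(cors, length(genes))
  check_flag(all(abs(cors) <= 1), "cors", "must lie in [-1, 1]")
  base_rate <- log(2) / 36   # 36-month baseline median survival
  with_seed(derive_seed(cfg$seed, 53L), {
    n <- cfg$n_patients
    z <- rnorm(n)
    expr <- matrix(z, n, 1L, dimnames = list(NULL, core_gene))
    if (length(genes)) {
      noise <- matrix(rnorm(n * length(genes)), n)
      tg <- sweep(noise, 2L, sqrt(1 - cors^2), "*") +
        outer(z, cors)
      colnames(tg) <- genes
      expr <- cbind(expr, tg)
    }
    rate <- base_rate * exp(cfg$beta * z)
    t_event <- rexp(n, rate)
    if (cfg$censor_rate > 0) {
      cens_rate <- base_rate * cfg$censor_rate / (1 - cfg$censor_rate)
      t_cens <- rexp(n, cens_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    cohort <- data.frame(patient_id = sprintf("pt_%04d", seq_len(n)),
                         time_months = time, event = event,
                         stringsAsFactors = FALSE)
    colnames(expr) <- paste0("expr_", colnames(expr))
    cohort <- cbind(cohort, as.data.frame(expr))
    list(cohort = cohort,
         truth = list(core_gene = core_gene, true_beta = cfg$beta,
                      cors = setNames(cors, genes)))
  })
}

#' Simulate an ISH specimen table
#'
#' Specimens receive a staining intensity (0-3) and a percentage of
#' positive cells; the five-year outcome is Bernoulli with poor-outcome
#' probability `p_low` below the planted composite-score cutoff and
#' `p_high` at or above it, so the Youden index is maximized at the
#' planted cutoff.
#'
#' @param cfg A [sim_config()] (`n_patients` specimens are drawn).
#' @param true_cutoff Planted composite-score cutoff (classify high iff
#'   score >= cutoff).
#' @param p_low,p_high Poor-outcome probabilities below/at-or-above the
#'   cutoff; equal values give an outcome independent of the score.
#' @return `list(specimens = <data.frame with id, intensity,
#'   proportion_pct, composite, outcome_5y>, truth)`.
#' @export
simulate_ish <- function(cfg, true_cutoff = 5, p_low = 0.15, p_high = 0.75) {
  validate_sim_config(cfg)
  check_flag(is.numeric(true_cutoff) && true_cutoff %in% 1:12,
             "true_cutoff", "must be an integer in 1..12")
  check_flag(p_low >= 0 && p_low <= 1 && p_high >= 0 && p_high <= 1,
             "p_low", "probabilities must lie in [0, 1]")
  with_seed(derive_seed(cfg$seed, 71L), {
    n <- cfg$n_patients
    intensity <- sample(0:3, n, replace = TRUE,
                        prob = c(0.15, 0.3, 0.3, 0.25))
    pct <- ifelse(intensity == 0, 0, runif(n, 0, 100))
    score <- composite_score(intensity, pct)
    p <- ifelse(score >= true_cutoff, p_high, p_low)
    outcome <- rbinom(n, 1L, p)
    specimens <- data.frame(id = sprintf("sp_%04d", seq_len(n)),
                            intensity = intensity,
                            proportion_pct = pct,
                            composite = score,
                            outcome_5y = outcome,
                            stringsAsFactors = FALSE)
    list(specimens = specimens,
         truth = list(true_cutoff = true_cutoff, p_low = p_low,
                      p_high = p_high))
  })
}
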