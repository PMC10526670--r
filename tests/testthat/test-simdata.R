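test_that("sim_config validates fields and names the offender", {
  expect_error(sim_config(n_planted_mirna = 10, n_mirna = 5),
               "n_planted_mirna")
  expect_error(sim_config(enrichment_fold = 0.5), "enrichment_fold")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_up = 300, n_down = 300, n_genes = 500), "n_up")
  expect_error(sim_config(beta = Inf), "beta")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(site_classes = "9mer"), "site_classes")
})

test_that("all generators are byte-deterministic under a fixed config", {
  cfg <- sim_config(seed = 11, n_mirna = 60, n_planted_mirna = 5,
                    n_genes = 80, n_up = 5, n_down = 5, n_patients = 50,
                    utr_length = 120)
  mirnas <- c(`mir-a` = "UGAGGUAGUAGUUUGUGCUGUU",
              `mir-b` = "ACCGUUAGCAUGCAUCCGAUAA")
  gens <- list(
    function() simulate_pulldown(cfg),
    function() simulate_counts(cfg),
    function() simulate_sequences(cfg, mirnas),
    function() simulate_cohort(cfg, genes = c("g1", "g2"), cors = 0.5),
    function() simulate_ish(cfg)
  )
  for (g in gens) expect_identical(g(), g())
  b1 <- simulate_bundle(sim_config(seed = 4, n_mirna = 60,
                                   n_planted_mirna = 6, n_genes = 120,
                                   n_up = 8, n_down = 5, n_patients = 40,
                                   utr_length = 150),
                        n_decoy_edges = 2L, n_extra_utrs = 10L)
  b2 <- simulate_bundle(sim_config(seed = 4, n_mirna = 60,
                                   n_planted_mirna = 6, n_genes = 120,
                                   n_up = 8, n_down = 5, n_patients = 40,
                                   utr_length = 150),
                        n_decoy_edges = 2L, n_extra_utrs = 10L)
  expect_identical(b1, b2)
})

test_that("pull-down enrichment is flat when enrichment_fold = 1", {
  cfg <- sim_config(seed = 21, enrichment_fold = 1)
  sim <- simulate_pulldown(cfg)
  es <- enrichment_scores(sim$pulldown, sim$control)
  planted_scores <- es$log2_enrichment[es$mirna %in% sim$truth$planted_mirnas]
  expect_lt(abs(mean(planted_scores)), 0.5)
  # recall of the "planted" set into the top 30 should look like chance
  recall <- mean(sim$truth$planted_mirnas %in% top_k(es, 30))
  expect_lt(recall, 0.3)
})

test_that("planted pull-down enrichment averages ~ log2(fold) (Monte Carlo)", {
  # oracle: average raw-count log2 ratios of the planted miRNAs over
  # replicated simulations; expectation is log2(8) = 3 (the +1 damping and
  # the NB noise cancel between numerator and denominator)
  ratios <- vapply(1:100, function(s) {
    sim <- simulate_pulldown(sim_config(seed = s))
    pd <- sim$pulldown$counts[sim$truth$planted_mirnas]
    ct <- sim$control$counts[sim$truth$planted_mirnas]
    mean(log2((pd + 1) / (ct + 1)))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.15)
})

test_that("planted DEG fold changes are recovered within 0.3", {
  cfg <- sim_config(seed = 31, n_genes = 500, n_up = 20, n_down = 20,
                    planted_lfc = 2, dispersion = 0.05, n_reps = 3)
  sim <- simulate_counts(cfg)
  de <- de_table(sim$counts)
  lfc_up <- de$log2fc[de$gene %in% sim$truth$planted_up]
  lfc_down <- de$log2fc[de$gene %in% sim$truth$planted_down]
  expect_lt(abs(mean(lfc_up) - 2), 0.3)
  expect_lt(abs(mean(lfc_down) + 2), 0.3)
})

test_that("null count simulation yields (almost) no DEGs", {
  cfg <- sim_config(seed = 32, n_genes = 500, n_up = 20, n_down = 20,
                    planted_lfc = 0, dispersion = 0.05)
  sim <- simulate_counts(cfg)
  fd <- filter_degs(de_table(sim$counts))
  expect_lte(length(fd$up) + length(fd$down), 5)
})

test_that("sequence planting is exact: a scan recovers the planted sites", {
  cfg <- sim_config(seed = 41, utr_length = 120)
  mirnas <- c(`mir-x` = "UGAGGUAGUAGUUUGUGCUGUU")
  sim <- simulate_sequences(cfg, mirnas)
  # core UTR: exactly one 8mer for the single miRNA
  found <- find_seed_sites(mature_mirna("mir-x", mirnas[[1]]),
                           sim$core_utr)
  planted <- sim$truth$planted_sites
  core_truth <- planted[planted$utr == names(sim$core_utr), ]
  expect_equal(found$start, core_truth$start)
  expect_equal(found$site_class, core_truth$site_class)
  # target UTR likewise
  tu <- sim$target_utrs[1]
  found_t <- find_seed_sites(mature_mirna("mir-x", mirnas[[1]]), tu)
  tgt_truth <- planted[planted$utr == names(tu), ]
  expect_equal(found_t$start, tgt_truth$start)
})

test_that("too-short UTRs are rejected with an informative error", {
  cfg <- sim_config(seed = 42, utr_length = 30)
  mirnas <- setNames(
    c("UGAGGUAGUAGUUUGUGCUGUU", "ACCGUUAGCAUGCAUCCGAUAA",
      "CGAUUACGGAUCGAUGCAUGCA", "UUACGGCAUCGGAUUACGGAUC"),
    paste0("m", 1:4))
  expect_error(simulate_sequences(cfg, mirnas), "too short")
})

test_that("cohort generator honors censoring and correlation settings", {
  cfg0 <- sim_config(seed = 51, censor_rate = 0, n_patients = 300)
  sim0 <- simulate_cohort(cfg0)
  expect_true(all(sim0$cohort$event == 1))

  cfg <- sim_config(seed = 52, n_patients = 800, censor_rate = 0.3)
  sim <- simulate_cohort(cfg, genes = c("tgt", "decoy"), cors = c(0.7, 0))
  expect_lt(abs(cor(sim$cohort$expr_FN1, sim$cohort$expr_tgt) - 0.7), 0.1)
  expect_lt(abs(cor(sim$cohort$expr_FN1, sim$cohort$expr_decoy)), 0.15)
  # censoring fraction near its nominal level (beta shifts it mildly)
  expect_lt(abs(mean(sim$cohort$event == 0) - 0.3), 0.1)
})

test_that("ISH simulation recovers the planted cutoff and has a null", {
  cfg <- sim_config(seed = 61, n_patients = 1000)
  null_sim <- simulate_ish(cfg, true_cutoff = 5, p_low = 0.3, p_high = 0.3)
  yc <- youden_cutoff(null_sim$specimens$composite,
                      null_sim$specimens$outcome_5y)
  expect_lt(yc$J, 0.1)

  hits <- vapply(1:60, function(s) {
    sim <- simulate_ish(sim_config(seed = s, n_patients = 400))
    youden_cutoff(sim$specimens$composite,
                  sim$specimens$outcome_5y)$cutoff == 5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
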