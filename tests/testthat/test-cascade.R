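small_bundle <- function(seed) {
  cfg <- sim_config(seed = seed, n_mirna = 80, n_planted_mirna = 8,
                    library_depth = 1e5, n_genes = 200, n_up = 10,
                    n_down = 5, n_patients = 150, utr_length = 200)
  simulate_bundle(cfg, n_decoy_edges = 3L, n_extra_utrs = 30L)
}

test_that("merge_topk obeys inclusion-exclusion", {
  a <- paste0("m", 1:10)
  b <- c(paste0("m", 1:4), paste0("x", 1:6))
  mt <- merge_topk(a, b)
  expect_length(mt$union, 16)
  expect_length(mt$core, 4)

  mt2 <- merge_topk(a, a)
  expect_setequal(mt2$union, a)
  expect_setequal(mt2$core, a)

  set.seed(25)
  for (i in 1:200) {
    u <- paste0("id", 1:30)
    x <- sample(u, sample(0:15, 1))
    y <- sample(u, sample(0:15, 1))
    m <- merge_topk(x, y)
    expect_equal(length(m$union), length(x) + length(y) - length(m$core))
  }
})

test_that("prognostic_filter keeps harmful genes, drops protective ones,
           and names missing columns", {
  cfg_bad <- sim_config(seed = 26, beta = 0.8, n_patients = 1000)
  harmful <- simulate_cohort(cfg_bad)$cohort
  expect_equal(prognostic_filter("FN1", harmful), "FN1")

  cfg_prot <- sim_config(seed = 27, beta = -0.8, n_patients = 1000)
  protective <- simulate_cohort(cfg_prot)$cohort
  # strongly significant, but in the protective direction
  grp <- dichotomize(protective$expr_FN1)
  lr <- logrank_test(protective$time_months, protective$event, grp)
  expect_lt(lr$p_value, 0.001)
  expect_length(prognostic_filter("FN1", protective), 0)

  expect_error(prognostic_filter("GHOST", harmful), "GHOST")
})

test_that("rank_core_axis ranks by correlation and ignores monotone
           transforms", {
  cfg <- sim_config(seed = 28, n_patients = 500)
  sim <- simulate_cohort(cfg, genes = c("tgt", "d1", "d2"),
                         cors = c(0.7, 0, 0))
  ranked <- rank_core_axis(c("d1", "tgt", "d2"), "FN1", sim$cohort)
  expect_equal(ranked$gene[1], "tgt")
  expect_equal(rank_core_axis("d1", "FN1", sim$cohort)$gene, "d1")
  expect_equal(nrow(rank_core_axis(character(0), "FN1", sim$cohort)), 0)

  transformed <- sim$cohort
  for (cl in grep("^expr_", names(transformed), value = TRUE)) {
    transformed[[cl]] <- exp(transformed[[cl]])
  }
  expect_equal(rank_core_axis(c("d1", "tgt", "d2"), "FN1", transformed)$gene,
               ranked$gene)
  expect_equal(rank_core_axis(c("d1", "tgt", "d2"), "FN1", transformed)$rho,
               ranked$rho)
})

test_that("run_screen recovers the planted axis and reports consistent
           cardinalities", {
  b <- small_bundle(301)
  res <- run_screen(cascade_config(), b$pulldown, b$counts, b$sequences,
                    b$cohort)
  rep <- res$report
  expect_equal(rep$core_axis, b$truth$axis)
  # stage arithmetic
  expect_lte(rep$n_target_up_overlap, min(rep$n_targets, rep$n_up_degs))
  expect_lte(rep$n_prognostic, rep$n_target_up_overlap)
  expect_true(all(rep$core_mirnas %in% rep$top_union))
  expect_true(all(rep$final_genes %in% rep$ranking$gene))
  expect_length(union(rep$top_union, character(0)),
                2 * 10 - length(intersect(top_k(enrichment_scores(
                  b$pulldown[[1]]$pulldown, b$pulldown[[1]]$control), 10),
                  top_k(enrichment_scores(b$pulldown[[2]]$pulldown,
                                          b$pulldown[[2]]$control), 10))))
  # network invariants
  net <- res$network
  expect_true(all(net$target_edges$source %in% net$mirna_nodes))
  expect_true(all(net$target_edges$target %in% net$gene_nodes))
  expect_true(all(net$core_edges$source == net$core))
})

test_that("disjoint enriched sets give an empty downstream cascade, not a
           crash", {
  ids <- paste0("m", 1:6)
  mk <- function(hot) {
    counts <- setNames(rep(50, 6), ids)
    pd <- counts; pd[hot] <- 5000
    list(pulldown = tag_library(pd, "x", "pulldown"),
         control = tag_library(counts, "x", "control"))
  }
  pulldown <- list(A = mk(1:3), B = mk(4:6))
  mirnas <- setNames(
    c("UGAGGUAGUAGUUUGUGCUGUU", "ACCGUUAGCAUGCAUCCGAUAA",
      "CGAUUACGGAUCGAUGCAUGCA", "UUACGGCAUCGGAUUACGGAUC",
      "AGGCAUUCGAUACGAUCGAUCG", "CAUGGAUCCGAUAGCUAGGAUC"), ids)
  m <- matrix(c(100L, 200L, 150L, 110L, 190L, 160L), 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  counts <- count_matrix(m, rep(1000, 3), c("case", "control"))
  sequences <- list(mirnas = mirnas,
                    core_utr = c(FN1 = strrep("C", 100)),
                    target_utrs = setNames(rep(strrep("C", 100), 3),
                                           paste0("g", 1:3)))
  set.seed(29)
  cohort <- data.frame(patient_id = paste0("p", 1:30),
                       time_months = rexp(30, 0.02), event = 1,
                       expr_FN1 = rnorm(30), expr_g1 = rnorm(30),
                       expr_g2 = rnorm(30), expr_g3 = rnorm(30))
  ws <- capture_warnings(
    res <- run_screen(cascade_config(), pulldown, counts, sequences,
                      cohort))
  expect_true(any(grepl("empty stage", ws)))
  expect_equal(res$report$n_common, 0)
  expect_equal(res$report$n_targets, 0)
  expect_length(res$report$final_genes, 0)
  expect_null(res$report$core_axis)
  expect_equal(nrow(res$network$core_edges) + nrow(res$network$target_edges),
               0)

  # empty network exports as a header-only TSV and round-trips
  dir1 <- tempfile(); dir2 <- tempfile()
  export_network(res$network, res$report, dir1)
  expect_equal(readLines(file.path(dir1, "edges.tsv")),
               "source\ttarget\tedge_type\tevidence")
  rt <- read_network(dir1)
  export_network(rt$network, rt$report, dir2)
  expect_identical(readBin(file.path(dir1, "edges.tsv"), "raw", 1e6),
                   readBin(file.path(dir2, "edges.tsv"), "raw", 1e6))
  expect_identical(readBin(file.path(dir1, "report.json"), "raw", 1e6),
                   readBin(file.path(dir2, "report.json"), "raw", 1e6))
})

test_that("a populated network round-trips losslessly through disk", {
  b <- small_bundle(302)
  res <- run_screen(cascade_config(), b$pulldown, b$counts, b$sequences,
                    b$cohort)
  dir1 <- tempfile(); dir2 <- tempfile()
  export_network(res$network, res$report, dir1)
  rt <- read_network(dir1)
  export_network(rt$network, rt$report, dir2)
  for (f in c("edges.tsv", "report.json")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6),
                     label = f)
  }
  # counts in files equal in-memory counts
  edges <- read.delim(file.path(dir1, "edges.tsv"))
  expect_equal(nrow(edges),
               nrow(res$network$core_edges) + nrow(res$network$target_edges))
})
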