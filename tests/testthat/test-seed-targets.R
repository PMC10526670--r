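test_that("mature_from_probe reverse-complements and transcribes", {
  expect_equal(mature_from_probe("AAAA"), "UUUU")
  probe <- "AACAGCACAAACTACTACCTCA"   # antisense DNA probe of let-7i-5p
  expect_equal(mature_from_probe(probe),
               chartr("T", "U", oracle_revcomp(probe)))
  expect_equal(mature_from_probe(probe), "UGAGGUAGUAGUUUGUGCUGUU")
  expect_error(mature_from_probe(""), "probe")
  expect_error(mature_from_probe("ACGX"), "position 4")
})

test_that("find_seed_sites classifies the canonical example", {
  m <- mature_mirna("let-7i-5p", "UGAGGUAGUAGUUUGUGCUGUU")
  sites <- find_seed_sites(m, c(u1 = "GGGCTACCTCAGGG"))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_class, "8mer")
  expect_equal(sites$start, 3)
  expect_equal(sites$end, 11)
  # the matched 8-mer is the seed complement plus the A anchor
  expect_equal(substr("GGGCTACCTCAGGG", 4, 11), "CTACCTCA")

  # seed with C/G cannot match a poly-A UTR
  empty <- find_seed_sites(m, c(u2 = strrep("A", 60)))
  expect_equal(nrow(empty), 0)
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(14)
  for (i in 1:100) {
    mir <- chartr("T", "U", random_dna(22))
    L <- sample(30:200, 1)
    utr <- random_dna(L)
    got <- find_seed_sites(mature_mirna("m", mir), c(u = utr))
    want <- oracle_scan("m", mir, "u", utr)
    expect_equal(got, want, label = sprintf("case %d", i))
    # class dominance: one report per interval, intervals unique
    expect_false(anyDuplicated(paste(got$start, got$end)) > 0)
  }
})

test_that("6mer background rate matches the analytic expectation", {
  set.seed(15)
  m <- mature_mirna("m", chartr("T", "U", random_dna(22)))
  L <- 60
  n_utr <- 1000
  total <- sum(vapply(seq_len(n_utr), function(i) {
    nrow(find_seed_sites(m, c(u = random_dna(L))))
  }, numeric(1)))
  expected <- n_utr * (L - 5) * 4^-6
  sd3 <- 3 * sqrt(n_utr * (L - 5) * 4^-6)
  expect_lt(abs(total - expected), sd3)
})

test_that("predict_targets respects min_class and recovers planted edges", {
  mirs <- c(mA = "UGAGGUAGUAGUUUGUGCUGUU")
  # a UTR holding only the 6mer core (no m8 flank, no A anchor)
  utr6 <- paste0("GGGG", "TACCTC", "GGGG")
  tm <- predict_targets(mirs, c(g1 = utr6), min_class = "7mer-A1")
  expect_length(tm$edges$mA, 0)
  tm6 <- predict_targets(mirs, c(g1 = utr6), min_class = "6mer")
  expect_equal(tm6$edges$mA, "g1")
  expect_equal(nrow(predict_targets(mirs, c(g1 = strrep("A", 40)))$sites), 0)

  cfg <- sim_config(seed = 71, utr_length = 150)
  mirnas <- setNames(
    c("UGAGGUAGUAGUUUGUGCUGUU", "ACCGUUAGCAUGCAUCCGAUAA",
      "CGAUUACGGAUCGAUGCAUGCA"),
    paste0("m", 1:3))
  edges <- list(gX = c("m1", "m2"), gY = "m3", gZ = "m2")
  sim <- simulate_sequences(cfg, mirnas, edges = edges)
  tm2 <- predict_targets(mirnas, sim$target_utrs, min_class = "8mer")
  planted <- lapply(mirnas, function(x) character(0))
  for (g in names(edges)) for (m in edges[[g]]) {
    planted[[m]] <- sort(c(planted[[m]], g))
  }
  expect_equal(tm2$edges, planted[names(tm2$edges)])
})

test_that("combine_predictions obeys idempotence and inclusion-exclusion", {
  mirs <- c(mA = "UGAGGUAGUAGUUUGUGCUGUU", mB = "ACCGUUAGCAUGCAUCCGAUAA")
  set.seed(16)
  utrs1 <- setNames(vapply(1:30, function(i) random_dna(120), character(1)),
                    paste0("g", 1:30))
  utrs2 <- setNames(vapply(1:30, function(i) random_dna(120), character(1)),
                    paste0("g", 1:30))
  a <- predict_targets(mirs, utrs1, min_class = "6mer")
  b <- predict_targets(mirs, utrs2, min_class = "6mer")

  expect_equal(combine_predictions(a, a, "union")$edges, a$edges)
  expect_equal(combine_predictions(a, a, "intersection")$edges, a$edges)

  u <- combine_predictions(a, b, "union")
  i <- combine_predictions(a, b, "intersection")
  for (m in names(a$edges)) {
    expect_equal(length(u$edges[[m]]) + length(i$edges[[m]]),
                 length(a$edges[[m]]) + length(b$edges[[m]]))
  }

  b2 <- b
  names(b2$edges)[1] <- "other"
  expect_error(combine_predictions(a, b2), "universes")
})
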