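# Independent oracles used to cross-check the implementation. These are
# deliberately written with different mechanics than the package code
# (Biostrings reverse complement, explicit enumeration loops, naive
# risk-set bookkeeping).

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Brute-force seed-site scan: enumerate matches of every class pattern as
# plain substrings, then keep each core occurrence once under its best
# class (an 8mer subsumes the 7mers and the 6mer it contains).
oracle_scan <- function(mirna_id, mirna_rna, utr_id, utr_dna) {
  m <- chartr("U", "T", toupper(mirna_rna))
  rc27 <- oracle_revcomp(substr(m, 2, 7))
  rc28 <- oracle_revcomp(substr(m, 2, 8))
  pats <- list(`8mer` = paste0(rc28, "A"), `7mer-m8` = rc28,
               `7mer-A1` = paste0(rc27, "A"), `6mer` = rc27)
  u <- toupper(utr_dna)
  L <- nchar(u)
  hits <- list()
  for (cl in names(pats)) {
    p <- pats[[cl]]
    w <- nchar(p)
    for (i in seq_len(max(L - w + 1, 0))) {
      if (substr(u, i, i + w - 1) == p) {
        # core (positions 2-7 complement) start within this match
        core_start <- i + if (cl %in% c("8mer", "7mer-m8")) 1L else 0L
        key <- as.character(core_start)
        if (is.null(hits[[key]])) {
          hits[[key]] <- data.frame(mirna = mirna_id, utr = utr_id,
                                    start = i - 1L, end = i - 1L + w,
                                    site_class = cl,
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(mirna = character(0), utr = character(0),
                      start = integer(0), end = integer(0),
                      site_class = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact two-sided binomial p-value by explicit enumeration.
oracle_binom_p <- function(x, n, prob) {
  if (n == 0) return(1)
  d_obs <- dbinom(x, n, prob)
  total <- 0
  for (k in 0:n) {
    dk <- dbinom(k, n, prob)
    if (dk <= d_obs * (1 + 1e-7)) total <- total + dk
  }
  min(1, total)
}

# Exhaustive Youden search with explicit confusion-matrix counting.
oracle_youden <- function(scores, outcomes) {
  best_c <- NA_integer_
  best_j <- -Inf
  for (cc in 1:12) {
    tp <- sum(scores >= cc & outcomes == 1)
    fn <- sum(scores < cc & outcomes == 1)
    tn <- sum(scores < cc & outcomes == 0)
    fp <- sum(scores >= cc & outcomes == 0)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- cc
    }
  }
  list(cutoff = best_c, J = best_j)
}

# Naive product-limit estimator: walk through time, shrinking an explicit
# risk set.
oracle_km <- function(time, event) {
  alive <- seq_along(time)
  s <- 1
  out_t <- numeric(0)
  out_s <- numeric(0)
  for (t in sort(unique(time))) {
    at_risk <- sum(time[alive] >= t)
    deaths <- sum(time == t & event == 1)
    if (deaths > 0) {
      s <- s * (1 - deaths / at_risk)
      out_t <- c(out_t, t)
      out_s <- c(out_s, s)
    }
    alive <- alive[time[alive] > t]
  }
  list(time = out_t, surv = out_s)
}

# Random tag library over a given id set.
random_library <- function(ids, max_count = 1000, probe = "pulldown") {
  tag_library(setNames(sample.int(max_count, length(ids), replace = TRUE),
                       ids), "test", probe)
}

# Small count matrix with prescribed per-gene counts.
make_cm <- function(case, ctrl, lengths = NULL) {
  genes <- names(case) %||% paste0("g", seq_along(case))
  m <- cbind(case_1 = unname(case), ctrl_1 = unname(ctrl))
  rownames(m) <- genes
  count_matrix(m, lengths %||% rep(1000, length(case)),
               c("case", "control"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
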