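# Synthetic 3'-UTR sequences with planted seed sites. Backgrounds are
# rejection-sampled to be free of seed matches for the supplied miRNA set,
# so the planted site list is exactly what a scanner should recover.
# Sequences are emitted in the DNA alphabet (U -> T), matching FASTA
# convention; the scanner normalizes on input.

# The UTR-side sequence a site of the given class must carry, 5'->3'.
site_sequence <- function(mirna_seq, site_class) {
  m <- rna_to_dna(toupper(mirna_seq))
  core6 <- revcomp_dna(substr(m, 2L, 7L))
  core7 <- revcomp_dna(substr(m, 2L, 8L))
  switch(site_class,
         "8mer" = paste0(core7, "A"),
         "7mer-m8" = core7,
         "7mer-A1" = paste0(core6, "A"),
         "6mer" = core6,
         stop_field("site_class", "unknown class"))
}

# Random miRNA set with pairwise-distinct seed cores, so planted sites are
# unambiguous.
random_mirna_set <- function(n, length = 22L) {
  ids <- mirna_ids(n)
  seqs <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      s <- dna_to_rna(random_dna(length))
      core <- substr(s, 2L, 7L)
      if (!core %in% seen) break
    }
    seen <- c(seen, core)
    seqs[i] <- s
  }
  setNames(seqs, ids)
}

# Greedily choose n miRNAs from `pool` whose planted sites cannot be
# recognized by each other's seeds: no chosen miRNA's 6mer core may occur
# inside another chosen miRNA's site sequence, otherwise a background
# carrying exactly the planted sites is unconstructible.
compatible_subset <- function(seqs, pool, n, site_class) {
  chosen <- sites <- cores <- character(0)
  for (id in pool) {
    s <- site_sequence(seqs[[id]], site_class)
    core <- revcomp_dna(substr(rna_to_dna(toupper(seqs[[id]])), 2L, 7L))
    clash <- any(vapply(cores, grepl, logical(1), x = s, fixed = TRUE)) ||
      any(vapply(sites, function(ss) grepl(core, ss, fixed = TRUE),
                 logical(1)))
    if (!clash) {
      chosen <- c(chosen, id)
      sites <- c(sites, s)
      cores <- c(cores, core)
      if (length(chosen) == n) return(chosen)
    }
  }
  stop(sprintf("could only select %d of %d seed-compatible miRNAs",
               length(chosen), n), call. = FALSE)
}

# One UTR holding exactly the requested sites: rejection-sample a
# background free of 6mer-or-better matches for every miRNA in `mirnas`,
# splice the site sequences into evenly spaced slots, and verify that a
# full scan recovers exactly the planted list (splice junctions can create
# spurious matches; those drafts are rejected).
plant_utr <- function(utr_id, length, plant, mirnas, max_tries = 200L) {
  n_sites <- nrow(plant)
  site_seqs <- mapply(function(m, cl) site_sequence(mirnas[[m]], cl),
                      plant$mirna, plant$site_class)
  need <- sum(nchar(site_seqs)) + 2L * n_sites
  if (length < need) {
    stop(sprintf("utr_length %d too short to host %d sites (needs >= %d)",
                 length, n_sites, need), call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    seq <- random_dna(length)
    planted <- empty_sites()
    if (n_sites > 0) {
      slot <- floor(length / n_sites)
      ok <- TRUE
      rows <- vector("list", n_sites)
      for (s in seq_len(n_sites)) {
        w <- nchar(site_seqs[s])
        lo <- (s - 1L) * slot + 2L                 # keep 1-nt margins
        hi <- s * slot - w
        if (hi < lo) { ok <- FALSE; break }
        at <- sample(lo:hi, 1L)
        substr(seq, at, at + w - 1L) <- site_seqs[s]
        rows[[s]] <- data.frame(mirna = plant$mirna[s], utr = utr_id,
                                start = at - 1L, end = at - 1L + w,
                                site_class = plant$site_class[s],
                                stringsAsFactors = FALSE)
      }
      if (!ok) next
      planted <- do.call(rbind, rows)
      planted <- planted[order(planted$start), , drop = FALSE]
      rownames(planted) <- NULL
    }
    found <- do.call(rbind, lapply(names(mirnas), function(m) {
      find_seed_sites(mature_mirna(m, mirnas[[m]]), setNames(seq, utr_id))
    }))
    found <- found[order(found$start), , drop = FALSE]
    rownames(found) <- NULL
    if (identical(found, planted) ||
        (nrow(found) == 0 && nrow(planted) == 0)) {
      return(list(sequence = seq, sites = planted))
    }
  }
  stop(sprintf("could not build a clean UTR '%s' in %d tries", utr_id,
               max_tries), call. = FALSE)
}

#' Simulate a core 3'-UTR and target UTRs with planted seed sites
#'
#' The core UTR receives at least one site (of class
#' `cfg$site_classes[1]`) per planted miRNA; each designated target UTR
#' receives sites for its designated miRNAs. Backgrounds are
#' rejection-sampled so that a scanner finds exactly the planted sites and
#' nothing else (for the supplied miRNA set).
#'
#' @param cfg A [sim_config()]; `utr_length` must be able to host the
#'   requested sites.
#' @param mirnas Named character vector of mature miRNA sequences
#'   (A/C/G/U), non-empty.
#' @param edges Named list: target UTR id -> character vector of miRNA ids
#'   whose sites it should carry. Defaults to one UTR per miRNA
#'   (`utr_<mirna>`).
#' @param core_id Id of the core UTR.
#' @return `list(core_utr = <named string>, target_utrs = <named character
#'   vector>, truth = list(planted_sites = <data.frame>, edges))`.
#' @export
simulate_sequences <- function(cfg, mirnas, edges = NULL,
                               core_id = "core-3UTR") {
  validate_sim_config(cfg)
  check_flag(is.character(mirnas) && length(mirnas) >= 1L &&
               !is.null(names(mirnas)), "mirnas",
             "must be a non-empty named character vector")
  for (s in mirnas) {
    check_flag(!grepl("[^ACGUTacgut]", s), "mirnas",
               "sequences must be over A/C/G/U (or T)")
  }
  if (is.null(edges)) {
    edges <- setNames(as.list(names(mirnas)), paste0("utr_", names(mirnas)))
  }
  check_flag(all(unlist(edges) %in% names(mirnas)), "edges",
             "edge miRNA ids must exist in `mirnas`")
  cls <- cfg$site_classes[1]

  with_seed(derive_seed(cfg$seed, 37L), {
    core_plant <- data.frame(mirna = names(mirnas), site_class = cls,
                             stringsAsFactors = FALSE)
    core <- plant_utr(core_id, cfg$utr_length, core_plant, mirnas)
    targets <- lapply(names(edges), function(g) {
      plant <- data.frame(mirna = edges[[g]], site_class = cls,
                          stringsAsFactors = FALSE)
      plant_utr(g, cfg$utr_length, plant, mirnas)
    })
    names(targets) <- names(edges)
    sites <- do.call(rbind, c(list(core$sites),
                              lapply(targets, `[[`, "sites")))
    rownames(sites) <- NULL
    list(
      core_utr = setNames(core$sequence, core_id),
      target_utrs = setNames(vapply(targets, `[[`, character(1), "sequence"),
                             names(edges)),
      truth = list(planted_sites = sites, edges = edges)
    )
  })
}
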