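# Canonical seed-match target prediction: 8mer / 7mer-m8 / 7mer-A1 / 6mer
# sites of a mature miRNA on 3'-UTR sequences. This is the transparent
# stand-in for database predictors of the TargetScan family: the seed is
# miRNA positions 2-8 and a site is the reverse complement of (part of) it
# on the UTR, optionally followed by an A opposite miRNA position 1.

# Ascending priority order; the reported class of a site is maximal.
SITE_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

site_class_rank <- function(x) match(x, SITE_CLASSES)

#' Construct and validate a mature miRNA
#'
#' @param id miRNA name.
#' @param sequence 5'->3' mature sequence over A/C/G/U (T accepted and
#'   normalized to U), length >= 8 so that the seed (positions 2-8) exists.
#' @return Object of class `mature_mirna` with fields `id` and `sequence`.
#' @export
mature_mirna <- function(id, sequence) {
  check_flag(is.character(id) && length(id) == 1L && nzchar(id), "id",
             "must be a non-empty string")
  check_flag(is.character(sequence) && length(sequence) == 1L, "sequence",
             "must be a single string")
  seq <- dna_to_rna(toupper(sequence))
  bad <- regmatches(seq, regexpr("[^ACGU]", seq))
  if (length(bad) && nzchar(bad)) {
    stop_field("sequence", sprintf("invalid character '%s'", bad))
  }
  check_flag(nchar(seq) >= 8L, "sequence", "must be at least 8 nt")
  structure(list(id = id, sequence = seq), class = "mature_mirna")
}

as_mature_mirna <- function(x, id = NULL) {
  if (inherits(x, "mature_mirna")) return(x)
  mature_mirna(id %||% names(x) %||% "miRNA", unname(x))
}

#' Mature miRNA sequence from an antisense DNA probe
#'
#' An in situ hybridization probe is the DNA antisense of its target, so
#' the mature miRNA is the probe's reverse complement transcribed to RNA.
#'
#' @param probe 5'->3' DNA probe sequence over A/C/G/T.
#' @return The mature miRNA sequence (5'->3', RNA alphabet).
#' @examples
#' mature_from_probe("AACAGCACAAACTACTACCTCA") # let-7i-5p
#' @export
mature_from_probe <- function(probe) {
  check_flag(is.character(probe) && length(probe) == 1L && nzchar(probe),
             "probe", "must be a non-empty DNA string")
  probe <- toupper(probe)
  chars <- strsplit(probe, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  }
  dna_to_rna(revcomp_dna(probe))
}

normalize_utr <- function(sequence) {
  seq <- rna_to_dna(toupper(sequence))
  check_flag(nzchar(seq), "utr", "must be non-empty")
  check_flag(!grepl("[^ACGT]", seq), "utr",
             "must be over A/C/G/T after U->T normalization")
  seq
}

#' Find canonical seed sites of a miRNA on a UTR
#'
#' Scans the UTR 5'->3' for matches to the reverse complement of the
#' miRNA seed. With `seed6` = positions 2-7 and `m8` = position 8, a match
#' position is classified as:
#' \itemize{
#'   \item `8mer` - reverse complement of positions 2-8 followed (3' on
#'     the UTR) by an A;
#'   \item `7mer-m8` - reverse complement of positions 2-8;
#'   \item `7mer-A1` - reverse complement of positions 2-7 followed by A;
#'   \item `6mer` - reverse complement of positions 2-7 alone.
#' }
#' Each match is reported once with its best class
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer); overlapping sites with distinct
#' start positions are all reported. Intervals are 0-based half-open on
#' the UTR and span 8, 7, 7 and 6 nucleotides respectively.
#'
#' @param mirna A [mature_mirna()] (or a raw sequence, optionally named).
#' @param utr A UTR sequence as a single (optionally named) string over
#'   A/C/G/T or A/C/G/U; normalized to uppercase DNA before matching.
#' @return `data.frame` with columns `mirna`, `utr`, `start`, `end`,
#'   `site_class`, ordered by `start`.
#' @examples
#' m <- mature_mirna("let-7i-5p", "UGAGGUAGUAGUUUGUGCUGUU")
#' find_seed_sites(m, c(utr1 = "GGGCTACCTCAGGG"))
#' @export
find_seed_sites <- function(mirna, utr) {
  m <- as_mature_mirna(mirna)
  utr_id <- names(utr) %||% "utr"
  seq <- normalize_utr(utr[[1]])
  L <- nchar(seq)

  mir_dna <- rna_to_dna(m$sequence)
  seed6 <- substr(mir_dna, 2L, 7L)
  core6 <- revcomp_dna(seed6)                    # UTR match of positions 2-7
  m8_comp <- revcomp_dna(substr(mir_dna, 8L, 8L)) # base 5' of the core

  pos <- match_positions(seq, core6)             # 1-based core starts
  if (!length(pos)) {
    return(empty_sites())
  }
  has_m8 <- pos > 1L & substr_vec(seq, pos - 1L) == m8_comp
  has_a1 <- (pos + 6L) <= L & substr_vec(seq, pos + 6L) == "A"

  cls <- ifelse(has_m8 & has_a1, "8mer",
                ifelse(has_m8, "7mer-m8",
                       ifelse(has_a1, "7mer-A1", "6mer")))
  # 0-based half-open interval per class: the m8 base extends the 5' end,
  # the A1 base the 3' end.
  start0 <- (pos - 1L) - ifelse(has_m8, 1L, 0L)
  end0 <- (pos - 1L) + 6L + ifelse(has_a1, 1L, 0L)

  out <- data.frame(mirna = m$id, utr = utr_id, start = start0, end = end0,
                    site_class = cls, stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

substr_vec <- function(x, pos) {
  vapply(pos, function(i) substr(x, i, i), character(1))
}

empty_sites <- function() {
  data.frame(mirna = character(0), utr = character(0),
             start = integer(0), end = integer(0),
             site_class = character(0), stringsAsFactors = FALSE)
}

#' Predict a miRNA -> target-gene map by seed matching
#'
#' An edge (miRNA, gene) is present iff the gene's UTR holds at least one
#' site of class `min_class` or better for that miRNA. Per-edge site lists
#' are kept as provenance.
#'
#' @param mirnas Named character vector of mature sequences, or a list of
#'   [mature_mirna()] objects.
#' @param utrs Named character vector of UTR sequences (names are
#'   gene/transcript ids).
#' @param min_class Weakest accepted site class.
#' @param predictor Label recorded as the provenance of every edge.
#' @return Object of class `target_map`: `edges` (named list, miRNA id ->
#'   character vector of gene ids), `sites` (data.frame of supporting
#'   sites), `predictor`.
#' @export
predict_targets <- function(mirnas, utrs, min_class = "7mer-A1",
                            predictor = "seedmatch") {
  check_flag(min_class %in% SITE_CLASSES, "min_class",
             sprintf("must be one of %s", paste(SITE_CLASSES, collapse = ", ")))
  mir_list <- if (is.list(mirnas)) {
    lapply(mirnas, as_mature_mirna)
  } else {
    check_flag(!is.null(names(mirnas)), "mirnas", "must be named")
    lapply(names(mirnas), function(id) mature_mirna(id, mirnas[[id]]))
  }
  ids <- vapply(mir_list, `[[`, character(1), "id")
  check_flag(!anyDuplicated(ids), "mirnas", "ids must be unique")
  check_flag(is.character(utrs) && !is.null(names(utrs)), "utrs",
             "must be a named character vector")

  min_rank <- site_class_rank(min_class)
  all_sites <- vector("list", length(mir_list))
  edges <- setNames(vector("list", length(ids)), ids)
  for (i in seq_along(mir_list)) {
    m <- mir_list[[i]]
    per_utr <- lapply(names(utrs), function(g) {
      find_seed_sites(m, setNames(utrs[g], g))
    })
    sites <- if (length(per_utr)) do.call(rbind, per_utr) else empty_sites()
    sites <- sites[site_class_rank(sites$site_class) >= min_rank, ,
                   drop = FALSE]
    all_sites[[i]] <- sites
    edges[[ids[i]]] <- sort(unique(sites$utr))
  }
  sites <- if (length(all_sites)) do.call(rbind, all_sites) else empty_sites()
  rownames(sites) <- NULL
  structure(list(edges = edges, sites = sites, predictor = predictor),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("<target_map> [%s] %d miRNAs, %d edges, %d sites\n",
              paste(unique(x$predictor), collapse = "+"), length(x$edges),
              sum(lengths(x$edges)), nrow(x$sites)))
  invisible(x)
}

#' Combine two target maps
#'
#' Per-miRNA union or intersection of target sets from two predictors over
#' the same miRNA universe. Site provenance is merged: union keeps all
#' sites; intersection keeps sites whose edge survives.
#'
#' @param a,b `target_map` objects over the same miRNA ids.
#' @param mode `"union"` or `"intersection"`.
#' @return A combined `target_map`.
#' @export
combine_predictions <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  check_flag(inherits(a, "target_map") && inherits(b, "target_map"),
             "a", "inputs must be target_map objects")
  if (!setequal(names(a$edges), names(b$edges))) {
    stop("target maps cover different miRNA universes", call. = FALSE)
  }
  ids <- names(a$edges)
  op <- if (mode == "union") union else intersect
  edges <- setNames(lapply(ids, function(m) sort(op(a$edges[[m]], b$edges[[m]]))),
                    ids)
  sites <- rbind(a$sites, b$sites)
  keep <- mapply(function(m, g) g %in% edges[[m]], sites$mirna, sites$utr)
  sites <- sites[as.logical(keep), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(edges = edges, sites = sites,
                 predictor = unique(c(a$predictor, b$predictor))),
            class = "target_map")
}
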