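# Plain-text interchange: TSV tag libraries, TSV count matrices with a
# JSON design sidecar, CSV cohorts, and FASTA sequences (via Biostrings).

#' Write / read a tag library as TSV
#'
#' Columns `mirna_id`, `count`.
#' @param lib A [tag_library()].
#' @param path File path.
#' @return `write_tag_library` invisibly returns `path`;
#'   `read_tag_library` returns a [tag_library()].
#' @export
write_tag_library <- function(lib, path) {
  check_flag(inherits(lib, "tag_library"), "lib", "must be a tag_library")
  write.table(data.frame(mirna_id = names(lib$counts),
                         count = unname(lib$counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_library
#' @param cell_line,probe Metadata attached on read.
#' @export
read_tag_library <- function(path, cell_line = "",
                             probe = c("pulldown", "control")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_flag(all(c("mirna_id", "count") %in% names(df)), "path",
             "TSV needs columns mirna_id, count")
  tag_library(setNames(df$count, df$mirna_id), cell_line, match.arg(probe))
}

#' Write / read a count matrix as TSV plus a JSON design sidecar
#'
#' The TSV holds `gene_id`, `length`, then one column per sample; the JSON
#' sidecar maps sample names to conditions.
#' @param cm A [count_matrix()].
#' @param path TSV path.
#' @param design_path JSON sidecar path (default `<path>.design.json`).
#' @export
write_count_matrix <- function(cm, path,
                               design_path = paste0(path, ".design.json")) {
  check_flag(inherits(cm, "count_matrix"), "cm", "must be a count_matrix")
  df <- data.frame(gene_id = rownames(cm$counts),
                   length = unname(cm$lengths),
                   cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(cm$condition), design_path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path,
                              design_path = paste0(path, ".design.json")) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_flag(all(c("gene_id", "length") %in% names(df)), "path",
             "TSV needs gene_id and length columns")
  design <- jsonlite::read_json(design_path, simplifyVector = TRUE)
  samples <- setdiff(names(df), c("gene_id", "length"))
  m <- as.matrix(df[, samples, drop = FALSE])
  rownames(m) <- df$gene_id
  count_matrix(m, df$length, unlist(design[samples]))
}

#' Write / read a cohort table as CSV
#'
#' Columns `patient_id`, `time_months`, `event`, then `expr_<gene>`.
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_flag(all(c("time_months", "event") %in% names(df)), "path",
             "CSV needs time_months and event columns")
  df
}

#' Write / read sequences as FASTA
#'
#' Thin wrappers around Biostrings; sequences are plain named character
#' vectors on the R side (DNA alphabet; U is normalized to T on write).
#' @param seqs Named character vector of sequences.
#' @param path FASTA path.
#' @export
write_fasta <- function(seqs, path) {
  check_flag(is.character(seqs) && !is.null(names(seqs)), "seqs",
             "must be a named character vector")
  x <- Biostrings::DNAStringSet(vapply(seqs, rna_to_dna, character(1)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a simulated bundle to a directory
#'
#' Emits every pipeline input as plain text: per-line pull-down/control
#' TSVs, the count matrix TSV + design JSON, miRNA and UTR FASTA files,
#' the cohort CSV, and the ground truth as JSON.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param path Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_bundle <- function(bundle, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (cl in names(bundle$pulldown)) {
    write_tag_library(bundle$pulldown[[cl]]$pulldown,
                      file.path(path, sprintf("%s_pulldown.tsv", cl)))
    write_tag_library(bundle$pulldown[[cl]]$control,
                      file.path(path, sprintf("%s_control.tsv", cl)))
  }
  write_count_matrix(bundle$counts, file.path(path, "counts.tsv"))
  write_fasta(bundle$sequences$mirnas, file.path(path, "mirnas.fa"))
  write_fasta(c(bundle$sequences$core_utr, bundle$sequences$target_utrs),
              file.path(path, "utrs.fa"))
  write_cohort(bundle$cohort, file.path(path, "cohort.csv"))
  jsonlite::write_json(bundle$truth, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
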