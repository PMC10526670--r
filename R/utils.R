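# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulators are deterministic without clobbering the
#' session stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One sub-stream per dataset: a fixed affine map keeps the derived seed a
# valid 32-bit integer and decouples the generators, so regenerating one
# dataset never perturbs another.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6 * 2011 + offset * 7919) %% 2147483629)
}

# All positions (1-based) where `pattern` occurs in `text`, including
# overlapping occurrences (gregexpr(fixed = TRUE) skips those).
match_positions <- function(text, pattern) {
  tr <- charToRaw(text)
  pr <- charToRaw(pattern)
  np <- length(pr)
  nt <- length(tr)
  if (nt < np || np == 0L) return(integer(0))
  idx <- seq_len(nt - np + 1L)
  hit <- rep(TRUE, length(idx))
  for (j in seq_len(np)) {
    hit <- hit & (tr[idx + j - 1L] == pr[j])
  }
  which(hit)
}

# Reverse complement of a DNA string (vectorized over its characters).
revcomp_dna <- function(x) {
  stopifnot(length(x) == 1L)
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

rna_to_dna <- function(x) chartr("Uu", "Tt", x)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Validation error that names the offending field/argument.
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_flag <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop_field(field, msg)
  invisible(TRUE)
}
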