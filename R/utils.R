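# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards, so simulators are deterministic without clobbering
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All simulators draw their randomness from one integer master seed; each
#' stage derives its own stream so that adding a stage never perturbs the
#' draws of another. The result is always a valid 32-bit R seed.
#'
#' @param seed integer master seed.
#' @param tag character stream label (e.g. `"cohort"`, `"trace:geneA:3"`).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(tag)) {
    h <- (h * 69069 + k * 1013904223) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA of a given length (sense-codon CDS helper lives in sim-genomes)
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string (delegates to Biostrings)
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate one codon to an amino acid (one-letter code, "*" for stop)
#' @noRd
codon_to_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Split a CDS string into codons
#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  substring(cds, seq(1, n, by = 3), seq(3, n, by = 3))
}
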