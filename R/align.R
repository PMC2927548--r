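# Pairwise global alignment wrapper around the C++ affine-gap DP.

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch over the full lengths of both sequences with an affine
#' gap model: a gap of length `k` costs `gap_open + k * gap_extend`.
#' Traceback is deterministic (diagonal preferred over a gap in `seq2`,
#' preferred over a gap in `seq1`), so identical inputs always give the
#' identical alignment.
#'
#' Only two sequences are ever compared per exon in this pipeline (tumor
#' consensus vs normal consensus, or a read vs its reference exon), so a
#' pairwise aligner is the whole requirement.
#'
#' @param seq1,seq2 character strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; defaults
#'   `+1/-2/-5/-2`.
#' @return List of class `pairwise_alignment`: `seq1`, `seq2` (gapped
#'   strings of equal length), `ops` (per-column `M`atch, `S`ubstitution,
#'   `D`eletion from seq1, `I`nsertion into seq1), `score`.
#' @export
align_global <- function(seq1, seq2, match = 1, mismatch = -2,
                         gap_open = -5, gap_extend = -2) {
  stopifnot(is.character(seq1), is.character(seq2),
            nchar(seq1) > 0, nchar(seq2) > 0)
  res <- .align_global_cpp(seq1, seq2, match, mismatch, gap_open, gap_extend)
  structure(res, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<alignment, %d columns, score %.1f>\n", nchar(x$seq1),
              x$score))
  w <- 60
  n <- nchar(x$seq1)
  for (i in seq(1, n, by = w)) {
    j <- min(i + w - 1, n)
    cat(substr(x$seq1, i, j), "\n")
    cat(substr(x$seq2, i, j), "\n\n")
  }
  invisible(x)
}
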