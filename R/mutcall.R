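# Quality-aware tumor/normal mutation calling from paired Sanger-style exon
# reads: phred arithmetic, end-trimming, bidirectional consensus assembly,
# Q-filtered difference calling, and codon-level effect annotation.

#' Phred quality to error probability
#'
#' `10^(-q/10)`: Q20 is a 1% base-call error rate, Q30 is 0.1%.
#'
#' @param q non-negative phred score (vectorized).
#' @return Error probability in `(0, 1]`.
#' @export
phred_error <- function(q) {
  if (any(q < 0)) stop("phred score must be non-negative")
  10^(-q / 10)
}

#' Trim low-quality read ends
#'
#' Retains the longest contiguous interval of the read in which every
#' sliding window of `window` bases has mean quality at least `qmin`
#' (leftmost interval on ties). Reads shorter than one window are kept
#' whole if their overall mean quality passes, else emptied.
#'
#' @param read a [trace_read()].
#' @param window sliding-window width in bases.
#' @param qmin minimum mean window quality.
#' @return The trimmed [trace_read()]; `$failed` is `TRUE` when nothing
#'   survives. Attributes `trim_start`/`trim_end` give the retained
#'   interval in original read coordinates (0/0 when empty).
#' @export
trim_read <- function(read, window = 10, qmin = 20) {
  stopifnot(inherits(read, "trace_read"), window >= 1)
  q <- read$quals
  n <- length(q)
  empty <- function() {
    out <- trace_read(read$id, read$orientation, "", integer(0))
    attr(out, "trim_start") <- 0L
    attr(out, "trim_end") <- 0L
    out
  }
  if (n == 0) return(empty())
  if (n < window) {
    if (mean(q) >= qmin) {
      attr(read, "trim_start") <- 1L
      attr(read, "trim_end") <- n
      return(read)
    }
    return(empty())
  }
  # window sums via cumulative sums; integer comparison avoids float fuzz
  cs <- c(0, cumsum(as.numeric(q)))
  wsum <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
  ok <- wsum >= qmin * window
  if (!any(ok)) return(empty())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  a <- starts[best]
  b <- ends[best] + window - 1
  out <- trace_read(read$id, read$orientation,
                    substr(read$bases, a, b), q[a:b])
  attr(out, "trim_start") <- as.integer(a)
  attr(out, "trim_end") <- as.integer(b)
  out
}

# Project one read onto reference coordinates via global alignment.
# Returns per-reference-position base ('-' for a deletion in the read) and
# quality, plus insertions keyed by the reference position they follow.
project_read <- function(read, reference) {
  aln <- align_global(read$bases, reference)
  rq <- read$quals
  m <- nchar(reference)
  base_at <- rep(NA_character_, m)
  qual_at <- rep(NA_integer_, m)
  ins <- list()
  i <- 0; j <- 0
  ops <- strsplit(aln$ops, "")[[1]]
  c1 <- strsplit(aln$seq1, "")[[1]]
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op == "M" || op == "S") {
      i <- i + 1; j <- j + 1
      base_at[j] <- c1[k]
      qual_at[j] <- rq[i]
    } else if (op == "D") {          # base in read, absent from reference
      i <- i + 1
      key <- as.character(j)
      prev <- ins[[key]] %||% list(bases = character(0), quals = integer(0))
      ins[[key]] <- list(bases = c(prev$bases, c1[k]),
                         quals = c(prev$quals, rq[i]))
    } else {                          # reference base missing from read
      j <- j + 1
      base_at[j] <- "-"
      qual_at[j] <- NA_integer_
    }
  }
  # positions outside the read's aligned extent are uncovered, not deleted
  covered <- which(!is.na(base_at) & base_at != "-")
  if (length(covered)) {
    lo <- min(covered); hi <- max(covered)
    outside <- c(seq_len(lo - 1), seq_len(m)[seq_len(m) > hi])
    base_at[outside] <- NA_character_
  } else {
    base_at[] <- NA_character_
  }
  list(base = base_at, qual = qual_at, ins = ins)
}

merge_ins <- function(a, b, covers_a, covers_b) {
  # keep an insertion when both reads report it identically, or when only
  # one read covers the locus; a one-read insertion contradicted by the
  # other covering read is dropped (conservative)
  if (!is.null(a) && !is.null(b)) {
    if (identical(a$bases, b$bases)) {
      return(list(bases = a$bases, quals = pmax(a$quals, b$quals)))
    }
    return(NULL)
  }
  if (!is.null(a) && !covers_b) return(a)
  if (!is.null(b) && !covers_a) return(b)
  NULL
}

#' Assemble a per-exon consensus from a forward/reverse read pair
#'
#' Both reads (the reverse read is reverse-complemented into reference
#' orientation first) are anchored on the reference exon by global
#' alignment, then merged base by base: agreeing calls take the higher
#' quality; disagreeing calls are resolved toward the higher-quality base,
#' with quality ties yielding `N` at quality 0. A consensus succeeds when
#' it contains at least `min_hq` bases at or above quality `hq_q`.
#'
#' @param forward,reverse trimmed [trace_read()]s (either may be failed).
#' @param reference the reference exon/amplicon sequence.
#' @param min_hq minimum number of high-quality bases for success
#'   (default 100).
#' @param hq_q quality threshold defining "high quality" (default 20).
#' @return List of class `consensus_seq`: `bases`, `quals`, `ref_start`
#'   (reference position of the first consensus base), `ref_pos`
#'   (per-base reference position, `NA` for inserted bases), `n_hq`,
#'   `success`.
#' @export
assemble_exon_consensus <- function(forward, reverse, reference,
                                    min_hq = 100, hq_q = 20) {
  failed <- function() {
    structure(list(bases = "", quals = integer(0), ref_start = NA_integer_,
                   ref_pos = integer(0), n_hq = 0L, success = FALSE),
              class = "consensus_seq")
  }
  reads <- list()
  if (!is.null(forward) && !forward$failed) reads$f <- forward
  if (!is.null(reverse) && !reverse$failed) {
    reads$r <- trace_read(reverse$id, "reverse",
                          revcomp(reverse$bases), rev(reverse$quals))
  }
  if (length(reads) == 0) return(failed())
  prj <- lapply(reads, project_read, reference = reference)
  m <- nchar(reference)
  pf <- prj$f %||% list(base = rep(NA_character_, m),
                        qual = rep(NA_integer_, m), ins = list())
  pr <- prj$r %||% list(base = rep(NA_character_, m),
                        qual = rep(NA_integer_, m), ins = list())
  bases <- character(0); quals <- integer(0); ref_pos <- integer(0)
  emit <- function(b, q, p) {
    bases <<- c(bases, b); quals <<- c(quals, as.integer(q))
    ref_pos <<- c(ref_pos, p)
  }
  covered <- which(!is.na(pf$base) | !is.na(pr$base))
  if (length(covered) == 0) return(failed())
  for (j in seq(min(covered), max(covered))) {
    bf <- pf$base[j]; br <- pr$base[j]
    qf <- pf$qual[j]; qr <- pr$qual[j]
    if (!is.na(bf) && !is.na(br)) {
      if (bf == "-" && br == "-") {
        # deletion supported by both reads: no consensus base here
      } else if (bf == "-" || br == "-") {
        # contradicted deletion: keep the observed base
        if (bf == "-") emit(br, qr, j) else emit(bf, qf, j)
      } else if (bf == br) {
        emit(bf, max(qf, qr), j)
      } else if (qf > qr) {
        emit(bf, qf, j)
      } else if (qr > qf) {
        emit(br, qr, j)
      } else {
        emit("N", 0L, j)
      }
    } else if (!is.na(bf)) {
      if (bf != "-") emit(bf, qf, j)
    } else if (!is.na(br)) {
      if (br != "-") emit(br, qr, j)
    } else {
      emit("N", 0L, j)    # interior gap in coverage
    }
    insm <- merge_ins(pf$ins[[as.character(j)]], pr$ins[[as.character(j)]],
                      covers_a = !is.na(bf), covers_b = !is.na(br))
    if (!is.null(insm)) {
      for (t in seq_along(insm$bases)) {
        emit(insm$bases[t], insm$quals[t], NA_integer_)
      }
    }
  }
  n_hq <- sum(quals >= hq_q)
  structure(list(bases = paste(bases, collapse = ""), quals = quals,
                 ref_start = min(covered),
                 ref_pos = ref_pos, n_hq = as.integer(n_hq),
                 success = n_hq >= min_hq),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("<consensus, %d bp, %d HQ bases, %s>\n", nchar(x$bases),
              x$n_hq, if (x$success) "success" else "FAILED"))
  invisible(x)
}

#' Call quality-filtered differences between tumor and normal consensi
#'
#' Walks a tumor-vs-normal [align_global()] alignment and emits a call for
#' every difference in which all involved bases pass the quality cutoff:
#' for substitutions both the tumor and the normal base, for indels every
#' inserted/deleted base plus one flanking anchor base in both sequences.
#' `N` bases never produce calls. Positions are reported in normal-sequence
#' coordinates (deletions start at the first deleted base; insertions are
#' anchored after the reported position).
#'
#' @param aln [align_global()] alignment of tumor (`seq1`) vs normal
#'   (`seq2`) consensus bases.
#' @param tumor_quals,normal_quals per-base quality vectors of the two
#'   ungapped sequences.
#' @param qmin phred cutoff (default 20, i.e. error rate at most 1%).
#' @return Data frame (`pos`, `ref`, `alt`, `kind`, `min_qual`).
#' @export
call_variants <- function(aln, tumor_quals, normal_quals, qmin = 20) {
  ops <- strsplit(aln$ops, "")[[1]]
  c1 <- strsplit(aln$seq1, "")[[1]]
  c2 <- strsplit(aln$seq2, "")[[1]]
  n_col <- length(ops)
  # tumor/normal positions *after* consuming each column
  ti <- cumsum(c1 != "-")
  nj <- cumsum(c2 != "-")
  calls <- list()
  add <- function(pos, ref, alt, kind, mq) {
    calls[[length(calls) + 1]] <<- data.frame(
      pos = pos, ref = ref, alt = alt, kind = kind, min_qual = mq,
      stringsAsFactors = FALSE)
  }
  # anchor quality at a column boundary: min of the last consumed tumor and
  # normal base qualities before column k (or after the run if k = 0)
  anchor_q <- function(k_prev, k_next) {
    if (k_prev >= 1) {
      qt <- if (ti[k_prev] >= 1) tumor_quals[ti[k_prev]] else NA
      qn <- if (nj[k_prev] >= 1) normal_quals[nj[k_prev]] else NA
    } else if (k_next <= n_col) {
      qt <- if (c1[k_next] != "-") tumor_quals[ti[k_next]] else NA
      qn <- if (c2[k_next] != "-") normal_quals[nj[k_next]] else NA
    } else {
      return(NA_real_)
    }
    if (is.na(qt) || is.na(qn)) NA_real_ else min(qt, qn)
  }
  k <- 1
  while (k <= n_col) {
    op <- ops[k]
    if (op == "S") {
      bt <- c1[k]; bn <- c2[k]
      qt <- tumor_quals[ti[k]]; qn <- normal_quals[nj[k]]
      if (bt != "N" && bn != "N" && qt >= qmin && qn >= qmin) {
        add(nj[k], bn, bt, "substitution", min(qt, qn))
      }
      k <- k + 1
    } else if (op == "D" || op == "I") {
      run_end <- k
      while (run_end < n_col && ops[run_end + 1] == op) run_end <- run_end + 1
      if (k == 1 || run_end == n_col) {
        # a gap run touching an alignment end reflects a difference in
        # consensus extent (coverage), not a somatic indel
        k <- run_end + 1
        next
      }
      aq <- anchor_q(k - 1, run_end + 1)
      if (op == "D") {    # bases present in tumor only: insertion
        idx <- ti[k]:ti[run_end]
        ins_b <- c1[k:run_end]
        qs <- tumor_quals[idx]
        if (!any(ins_b == "N") && !is.na(aq) &&
            all(qs >= qmin) && aq >= qmin) {
          add(nj[k], "", paste(ins_b, collapse = ""), "insertion",
              min(qs, aq))
        }
      } else {            # bases present in normal only: deletion
        idx <- nj[k]:nj[run_end]
        del_b <- c2[k:run_end]
        qs <- normal_quals[idx]
        if (!any(del_b == "N") && !is.na(aq) &&
            all(qs >= qmin) && aq >= qmin) {
          add(nj[k], paste(del_b, collapse = ""), "", "deletion",
              min(qs, aq))
        }
      }
      k <- run_end + 1
    } else {
      k <- k + 1
    }
  }
  if (length(calls) == 0) {
    return(data.frame(pos = numeric(0), ref = character(0),
                      alt = character(0), kind = character(0),
                      min_qual = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}

#' Map a CDS position to its codon
#'
#' @param p 1-based CDS position (vectorized).
#' @return Data frame (`codon`, `offset`) with `codon = ceiling(p / 3)` and
#'   `offset` in 1..3, so `3 * (codon - 1) + offset = p`.
#' @export
map_to_codon <- function(p) {
  if (any(p < 1)) stop("CDS position must be >= 1")
  data.frame(codon = ceiling(p / 3), offset = ((p - 1) %% 3) + 1)
}

#' An exon model
#'
#' @param gene gene id.
#' @param exon exon ordinal within the gene.
#' @param chrom,start,end,strand genomic placement (1-based inclusive).
#' @param coding whether the exon is protein-coding.
#' @param cds_offset 1-based CDS position of the exon's first coding base.
#' @return A one-row data frame of class `exon_model`.
#' @export
exon_model <- function(gene, exon = 1L, chrom = NA, start = NA, end = NA,
                       strand = "+", coding = TRUE, cds_offset = 1L) {
  if (coding && cds_offset < 1) stop("coding exon needs cds_offset >= 1")
  structure(data.frame(gene = gene, exon = exon, chrom = chrom,
                       start = start, end = end, strand = strand,
                       coding = coding, cds_offset = cds_offset,
                       stringsAsFactors = FALSE),
            class = c("exon_model", "data.frame"))
}

#' Codon-level consequence of a variant
#'
#' Substitutions are translated against the reference CDS (standard code):
#' synonymous, missense or nonsense (premature stop). Coding indels are
#' frameshift exactly when their length is not a multiple of 3, otherwise
#' in-frame. Variants in noncoding exons are `noncoding`.
#'
#' @param variant one-row data frame with `cds_pos`, `ref`, `alt`, `kind`.
#' @param exon the covering [exon_model()].
#' @param cds reference CDS sequence of the gene (required for
#'   substitutions in coding exons).
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`,
#'   `"frameshift"`, `"inframe_indel"`, `"noncoding"`.
#' @export
classify_effect <- function(variant, exon, cds = NULL) {
  if (!isTRUE(exon$coding)) return("noncoding")
  if (variant$kind %in% c("insertion", "deletion")) {
    len <- max(nchar(variant$ref), nchar(variant$alt))
    return(if (len %% 3 != 0) "frameshift" else "inframe_indel")
  }
  stopifnot(!is.null(cds))
  p <- variant$cds_pos
  if (p < 1 || p > nchar(cds)) stop("variant at CDS position ", p,
                                    " lies outside the ", nchar(cds),
                                    "-base CDS")
  mc <- map_to_codon(p)
  lo <- 3 * (mc$codon - 1) + 1
  ref_codon <- substr(cds, lo, lo + 2)
  if (substr(ref_codon, mc$offset, mc$offset) != variant$ref) {
    stop("reference allele mismatch at CDS position ", p)
  }
  alt_codon <- ref_codon
  substr(alt_codon, mc$offset, mc$offset) <- variant$alt
  aa_ref <- codon_to_aa(ref_codon)
  aa_alt <- codon_to_aa(alt_codon)
  if (is.na(aa_alt)) return("missense")
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_alt == "*") return("nonsense")
  "missense"
}

#' Cohort-level mutation and sequencing bookkeeping
#'
#' @param calls data frame of annotated calls with at least `sample`,
#'   `gene`, `effect` columns (as produced by the resequencing pipeline).
#' @param read_success data frame with one row per sequencing attempt and a
#'   logical `success` column (an attempt is one read; a success is a
#'   trimmed read retaining at least the high-quality base minimum).
#' @return List of class `cohort_summary`: `gene_summary` (per gene:
#'   tumors with truncating (nonsense/frameshift) calls, total mutated
#'   tumors), `attempts`, `successes`, `success_rate_pct` (rounded to the
#'   nearest integer; `NA` with `rate_undefined = TRUE` when there were no
#'   attempts).
#' @export
summarize_cohort <- function(calls, read_success) {
  attempts <- nrow(read_success)
  successes <- if (attempts > 0) sum(read_success$success) else 0L
  rate <- if (attempts > 0) round(100 * successes / attempts) else NA_real_
  genes <- sort(unique(c(calls$gene, read_success$gene)))
  gene_summary <- do.call(rbind, lapply(genes, function(g) {
    gc <- calls[calls$gene == g, , drop = FALSE]
    trunc <- gc[gc$effect %in% c("nonsense", "frameshift"), , drop = FALSE]
    data.frame(gene = g,
               truncating_tumors = length(unique(trunc$sample)),
               mutated_tumors = length(unique(gc$sample)),
               n_calls = nrow(gc), stringsAsFactors = FALSE)
  })) %||% data.frame(gene = character(0), truncating_tumors = integer(0),
                      mutated_tumors = integer(0), n_calls = integer(0))
  structure(list(gene_summary = gene_summary, attempts = attempts,
                 successes = as.integer(successes),
                 success_rate_pct = rate,
                 rate_undefined = attempts == 0),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort: %d/%d reads successful (%s%%)>\n", x$successes,
              x$attempts,
              if (x$rate_undefined) "NA" else x$success_rate_pct))
  print(x$gene_summary)
  invisible(x)
}
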