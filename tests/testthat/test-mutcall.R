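test_that("phred transform matches its closed form and rejects negatives", {
  expect_equal(phred_error(20), 0.01)
  expect_equal(phred_error(0), 1.0)
  expect_equal(phred_error(30), 0.001)
  expect_true(all(diff(phred_error(0:60)) < 0))
  expect_error(phred_error(-1), "non-negative")
})

test_that("trimming matches the brute-force optimum", {
  q <- c(rep(5, 20), rep(40, 60), rep(5, 20))
  read <- make_read(paste(rep("A", 100), collapse = ""), q)
  tr <- trim_read(read, window = 10, qmin = 20)
  oracle <- brute_force_trim(q, 10, 20)
  expect_equal(attr(tr, "trim_start"), oracle[1])
  expect_equal(attr(tr, "trim_end"), oracle[2])
  set.seed(303)
  for (i in 1:8) {
    q <- sample(0:45, 60, TRUE)
    read <- make_read(paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                            collapse = ""), q)
    tr <- trim_read(read, window = 8, qmin = 20)
    oracle <- brute_force_trim(q, 8, 20)
    expect_equal(c(attr(tr, "trim_start"), attr(tr, "trim_end")),
                 oracle, info = paste("case", i))
  }
})

test_that("trimming keeps uniformly good reads and empties uniformly bad ones", {
  good <- make_read(paste(rep("C", 50), collapse = ""), rep(40, 50))
  tr <- trim_read(good)
  expect_equal(tr$bases, good$bases)
  bad <- make_read(paste(rep("C", 50), collapse = ""), rep(5, 50))
  trb <- trim_read(bad)
  expect_true(trb$failed)
  expect_equal(nchar(trb$bases), 0)
})

test_that("consensus merging follows the quality rules", {
  ref <- paste(rep("ACGTT", 30), collapse = "")    # 150 bp
  f <- make_read(ref, rep(30, 150), id = "f")
  r_bases <- ref
  substr(r_bases, 10, 10) <- "T"    # disagrees with forward "T"? position 10 is T already
  # force a disagreement at position 11 (ref A)
  substr(r_bases, 11, 11) <- "G"
  r <- make_read(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r_bases))), rep(46, 150), id = "r",
    orientation = "reverse")
  cons <- assemble_exon_consensus(f, r, ref, min_hq = 100)
  # higher-quality base wins the disagreement: T(46)-style rule
  expect_equal(substr(cons$bases, 11, 11), "G")
  expect_equal(cons$quals[11], 46L)
  # agreement keeps the max quality
  expect_equal(cons$quals[12], 46L)
  expect_true(cons$success)
  # quality tie gives N at quality 0
  r2 <- make_read(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r_bases))), rep(30, 150), id = "r2",
    orientation = "reverse")
  cons2 <- assemble_exon_consensus(f, r2, ref, min_hq = 100)
  expect_equal(substr(cons2$bases, 11, 11), "N")
  expect_equal(cons2$quals[11], 0L)
})

test_that("consensus success needs at least the high-quality base minimum", {
  ref <- paste(rep("A", 120), collapse = "")
  q99 <- c(rep(20, 99), rep(19, 21))
  f <- make_read(ref, q99)
  cons <- assemble_exon_consensus(f, NULL, ref, min_hq = 100, hq_q = 20)
  expect_equal(cons$n_hq, 99L)
  expect_false(cons$success)
  q100 <- c(rep(20, 100), rep(19, 20))
  cons2 <- assemble_exon_consensus(make_read(ref, q100), NULL, ref,
                                   min_hq = 100, hq_q = 20)
  expect_equal(cons2$n_hq, 100L)
  expect_true(cons2$success)
  # zero usable reads fail outright
  expect_false(assemble_exon_consensus(NULL, NULL, ref)$success)
})

test_that("variant calling applies the Q20 cutoff per involved base", {
  tum <- "ACGTACGTAC"
  nor <- "ACGAACGTAC"   # substitution at position 4 (A in normal, T in tumor)
  aln <- align_global(tum, nor)
  called <- call_variants(aln, rep(46, 10), rep(35, 10), qmin = 20)
  expect_equal(nrow(called), 1)
  expect_equal(called$pos, 4)
  expect_equal(called$ref, "A")
  expect_equal(called$alt, "T")
  expect_equal(called$min_qual, 35)
  # tumor base below the cutoff suppresses the call
  qt <- rep(46, 10); qt[4] <- 15
  expect_equal(nrow(call_variants(aln, qt, rep(35, 10))), 0)
  # identical consensi yield nothing
  aln0 <- align_global(tum, tum)
  expect_equal(nrow(call_variants(aln0, rep(40, 10), rep(40, 10))), 0)
})

test_that("indel calls require base and anchor quality", {
  nor <- "ACGTACGTACGTACGT"
  tum <- paste0(substr(nor, 1, 8), "GG", substr(nor, 9, 16))
  aln <- align_global(tum, nor)
  called <- call_variants(aln, rep(40, 18), rep(40, 16))
  expect_equal(nrow(called), 1)
  expect_equal(called$kind, "insertion")
  expect_equal(called$alt, "GG")
  # low quality on an inserted base suppresses the call
  qt <- rep(40, 18); qt[9] <- 10
  expect_equal(nrow(call_variants(aln, qt, rep(40, 16))), 0)
  # deletion: low quality on the anchor suppresses it
  aln_d <- align_global(nor, tum)
  called_d <- call_variants(aln_d, rep(40, 16), rep(40, 18))
  expect_equal(called_d$kind, "deletion")
  expect_equal(called_d$ref, "GG")
  qn <- rep(40, 18); qn[8] <- 10   # anchor before the gap
  expect_equal(nrow(call_variants(align_global(nor, tum), rep(40, 16), qn)),
               0)
})

test_that("codon arithmetic maps CDS positions to codons", {
  expect_equal(map_to_codon(2549), data.frame(codon = 850, offset = 2))
  expect_equal(map_to_codon(1), data.frame(codon = 1, offset = 1))
  expect_equal(map_to_codon(3), data.frame(codon = 1, offset = 3))
  expect_equal(map_to_codon(8529), data.frame(codon = 2843, offset = 3))
  p <- 1:10000
  mc <- map_to_codon(p)
  expect_true(all(3 * (mc$codon - 1) + mc$offset == p))
  expect_error(map_to_codon(0), ">= 1")
})

test_that("effect classification translates codons and detects frameshifts", {
  # codon 850 = TTG (leucine); T>A at its middle base gives the TAG stop
  cds <- paste(c(rep("GGC", 849), "TTG", rep("GGC", 150)), collapse = "")
  ex <- exon_model("apc_like")
  v <- data.frame(cds_pos = 2549, ref = "T", alt = "A",
                  kind = "substitution")
  expect_equal(map_to_codon(2549)$offset, 2)
  expect_equal(classify_effect(v, ex, cds), "nonsense")
  # synonymous and missense
  v_syn <- data.frame(cds_pos = 3, ref = "C", alt = "T",
                      kind = "substitution")   # GGC -> GGT, both glycine
  expect_equal(classify_effect(v_syn, ex, cds), "synonymous")
  v_mis <- data.frame(cds_pos = 1, ref = "G", alt = "A",
                      kind = "substitution")   # GGC -> AGC
  expect_equal(classify_effect(v_mis, ex, cds), "missense")
  # indels: 2 bp insertion shifts frame, 3 bp deletion stays in frame
  v_ins <- data.frame(cds_pos = 10, ref = "", alt = "GG", kind = "insertion")
  expect_equal(classify_effect(v_ins, ex, cds), "frameshift")
  v_del3 <- data.frame(cds_pos = 10, ref = "GCG", alt = "", kind = "deletion")
  expect_equal(classify_effect(v_del3, ex, cds), "inframe_indel")
  # noncoding exon
  ex_nc <- exon_model("utr", coding = FALSE)
  expect_equal(classify_effect(v, ex_nc), "noncoding")
  # frameshift iff indel length not divisible by 3 (property over lengths)
  for (len in 1:6) {
    vi <- data.frame(cds_pos = 10, ref = "",
                     alt = paste(rep("A", len), collapse = ""),
                     kind = "insertion")
    expect_equal(classify_effect(vi, ex, cds) == "frameshift",
                 len %% 3 != 0)
  }
})

test_that("cohort bookkeeping reproduces printed-style success rates", {
  mk_attempts <- function(total, good) {
    data.frame(gene = rep("g", total), sample = rep("s", total),
               read_id = sprintf("r%05d", seq_len(total)),
               success = c(rep(TRUE, good), rep(FALSE, total - good)))
  }
  empty_calls <- data.frame(sample = character(0), gene = character(0),
                            effect = character(0))
  mouse <- summarize_cohort(empty_calls, mk_attempts(3264, 3076))
  expect_equal(mouse$success_rate_pct, 94)
  human <- summarize_cohort(empty_calls, mk_attempts(9360, 8342))
  expect_equal(human$success_rate_pct, 89)
  none <- summarize_cohort(empty_calls, mk_attempts(0, 0))
  expect_true(none$rate_undefined)
  # truncating = nonsense + frameshift only
  calls <- data.frame(
    sample = c("t1", "t1", "t2", "t3", "t4"),
    gene = "g",
    effect = c("nonsense", "missense", "frameshift", "synonymous",
               "noncoding"))
  sm <- summarize_cohort(calls, mk_attempts(10, 10))
  expect_equal(sm$gene_summary$truncating_tumors, 2)
  expect_equal(sm$gene_summary$mutated_tumors, 4)
})
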