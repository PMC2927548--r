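# Fixtures built in code at test time.

# Minimal two-genome ortholog map laid out by hand (1-based inclusive).
# Genome X: five genes in a row on one chromosome; genome Y: genes 2 and 3
# inverted (order and strand reversed).
make_inversion_map <- function() {
  genes <- paste0("g", 1:5)
  x <- data.frame(gene = genes, genome = "X", chrom = "chr1",
                  start = c(100, 300, 500, 700, 900),
                  end = c(199, 399, 599, 799, 999),
                  strand = "+", stringsAsFactors = FALSE)
  y <- x
  y$genome <- "Y"
  y$start[2:3] <- c(500, 300)
  y$end[2:3] <- c(599, 399)
  y$strand[2:3] <- "-"
  rbind(x, y)
}

# A tiny simulation object (as from simulate_ortholog_genomes) with chosen
# gene placements and CDS lengths, for fast rate-law cohorts.
make_toy_sim <- function(starts_a, starts_b = starts_a, gene_len = 300,
                         chrom_b = NULL, seed = 99) {
  genes <- sprintf("t%02d", seq_along(starts_a))
  if (is.null(chrom_b)) chrom_b <- rep("chr1", length(starts_a))
  ann_a <- data.frame(gene = genes, chrom = "chr1", start = starts_a,
                      end = starts_a + gene_len - 1, strand = "+",
                      stringsAsFactors = FALSE)
  ann_b <- data.frame(gene = genes, chrom = chrom_b, start = starts_b,
                      end = starts_b + gene_len - 1, strand = "+",
                      stringsAsFactors = FALSE)
  orth <- rbind(cbind(genome = "genomeA", ann_a),
                cbind(genome = "genomeB", ann_b))
  orth <- orth[, c("gene", "genome", "chrom", "start", "end", "strand")]
  seqs <- withr_seed_seqs(genes, gene_len, seed)
  list(genomes = list(genomeA = ann_a, genomeB = ann_b), orthologs = orth,
       sequences = seqs, events = list())
}

withr_seed_seqs <- function(genes, gene_len, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  setNames(vapply(genes, function(g) {
    paste(c(sample(sense, gene_len / 3 - 1, replace = TRUE), "TAA"),
          collapse = "")
  }, character(1)), genes)
}

# A trace_read with chosen qualities and bases matching a reference.
make_read <- function(bases, quals, id = "r1", orientation = "forward") {
  trace_read(id, orientation, bases, quals)
}

uniform_q_config <- function(q, read_length = 800) {
  trace_sim_config(read_length = read_length,
                   quality_profile = function(n) rep(q, n))
}
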