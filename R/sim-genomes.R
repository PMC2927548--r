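# Simulation of a pair of rearrangement-related genomes sharing one gene set.
#
# Coordinates are 1-based inclusive throughout the package (the IRanges
# convention); BED files written to disk are 0-based half-open.

#' Configuration for the two-genome ortholog simulator
#'
#' @param n_chromosomes number of chromosomes per genome.
#' @param chrom_length chromosome length in bp (recycled across chromosomes).
#' @param n_genes number of genes placed per genome (non-overlapping).
#' @param gene_length gene (CDS) length in bp; must be a multiple of 3.
#' @param rearrangements list of [rearrangement_event()] specs applied to
#'   genome B (genome A is the unrearranged reference arrangement).
#' @param fixed_genes optional data frame (`gene`, `chrom`, `start`, `strand`)
#'   pinning named genes to exact positions in genome A, e.g. to place a
#'   driver/passenger pair a chosen distance apart before rearrangement.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return A list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_chromosomes = 1, chrom_length = 5e7,
                              n_genes = 30, gene_length = 1500,
                              rearrangements = list(), fixed_genes = NULL,
                              seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, n_genes >= 1,
            gene_length %% 3 == 0, gene_length >= 6)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.numeric(chrom_length),
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 rearrangements = rearrangements,
                 fixed_genes = fixed_genes,
                 seed = as.integer(seed)),
            class = "genome_sim_config")
}

#' A single rearrangement event
#'
#' An inversion reverses gene order within `[start, end]` of `chrom`, flips
#' the strand of every contained gene and reflects its coordinates about the
#' interval. A translocation moves the genes inside the source interval to
#' `dest_chrom` at `dest_pos`, preserving order, orientation and spacing.
#'
#' @param kind `"inversion"` or `"translocation"`.
#' @param chrom,start,end source interval (1-based inclusive).
#' @param dest_chrom,dest_pos destination (translocation only).
#' @return A list of class `rearrangement_event`.
#' @export
rearrangement_event <- function(kind = c("inversion", "translocation"),
                                chrom, start, end,
                                dest_chrom = NULL, dest_pos = NULL) {
  kind <- match.arg(kind)
  stopifnot(start >= 1, end > start)
  if (kind == "translocation" && (is.null(dest_chrom) || is.null(dest_pos))) {
    stop("translocation requires dest_chrom and dest_pos")
  }
  structure(list(kind = kind, chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), dest_chrom = dest_chrom,
                 dest_pos = if (is.null(dest_pos)) NULL else as.numeric(dest_pos)),
            class = "rearrangement_event")
}

# Non-overlapping gene placement on one genome. Fixed genes are honored
# exactly; the remainder are placed uniformly at random with rejection
# against previously placed genes.
place_genes <- function(config) {
  gl <- config$gene_length
  genes <- data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (!is.null(config$fixed_genes)) {
    fx <- config$fixed_genes
    genes <- data.frame(gene = fx$gene, chrom = fx$chrom,
                        start = as.numeric(fx$start),
                        end = as.numeric(fx$start) + gl - 1,
                        strand = fx$strand, stringsAsFactors = FALSE)
  }
  n_rand <- config$n_genes - nrow(genes)
  if (n_rand < 0) stop("more fixed genes than n_genes")
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  i <- 0
  while (i < n_rand) {
    chrom <- sample(chroms, 1)
    start <- floor(runif(1, 1, config$chrom_length - gl))
    hit <- genes$chrom == chrom &
      genes$start <= start + gl - 1 & genes$end >= start
    if (any(hit)) next
    i <- i + 1
    genes <- rbind(genes, data.frame(
      gene = sprintf("g%03d", i), chrom = chrom, start = start,
      end = start + gl - 1, strand = sample(c("+", "-"), 1),
      stringsAsFactors = FALSE))
  }
  genes[order(genes$chrom, genes$start), , drop = FALSE]
}

# Random CDS made of sense codons only, terminated by TAA, so that injected
# nonsense mutations are the first stop encountered.
random_cds <- function(n_bases) {
  n_codons <- n_bases / 3
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  body <- sample(sense, n_codons - 1, replace = TRUE)
  paste(c(body, "TAA"), collapse = "")
}

apply_event <- function(ann, ev) {
  if (ev$kind == "inversion") {
    inside <- ann$chrom == ev$chrom & ann$start >= ev$start & ann$end <= ev$end
    straddle <- ann$chrom == ev$chrom & !inside &
      ann$start <= ev$end & ann$end >= ev$start
    if (any(straddle)) {
      stop("inversion boundary splits gene(s): ",
           paste(ann$gene[straddle], collapse = ", "))
    }
    new_start <- ev$start + (ev$end - ann$end[inside])
    new_end <- ev$start + (ev$end - ann$start[inside])
    ann$start[inside] <- new_start
    ann$end[inside] <- new_end
    ann$strand[inside] <- ifelse(ann$strand[inside] == "+", "-", "+")
  } else {
    inside <- ann$chrom == ev$chrom & ann$start >= ev$start & ann$end <= ev$end
    span <- ev$end - ev$start
    dst_lo <- ev$dest_pos
    dst_hi <- ev$dest_pos + span
    clash <- ann$chrom == ev$dest_chrom & !inside &
      ann$start <= dst_hi & ann$end >= dst_lo
    if (any(clash)) {
      stop("translocation destination overlaps gene(s): ",
           paste(ann$gene[clash], collapse = ", "))
    }
    ann$chrom[inside] <- ev$dest_chrom
    shift <- ev$dest_pos - ev$start
    ann$start[inside] <- ann$start[inside] + shift
    ann$end[inside] <- ann$end[inside] + shift
  }
  ann[order(ann$chrom, ann$start), , drop = FALSE]
}

#' Simulate two genomes sharing one ortholog set
#'
#' Genome A is drawn from the configuration; genome B is genome A with the
#' configured rearrangement events applied in order. Gene identity (and the
#' CDS truth sequence attached to each gene) is preserved across genomes, so
#' the returned table is a complete one-to-one ortholog map.
#'
#' @param config a [genome_sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{genomes}{named list of per-genome annotation data frames
#'       (`gene`, `chrom`, `start`, `end`, `strand`).}
#'     \item{orthologs}{long-format ortholog map
#'       (`gene`, `genome`, `chrom`, `start`, `end`, `strand`).}
#'     \item{sequences}{named character vector of CDS truth sequences.}
#'     \item{events}{the realized rearrangement events.}
#'   }
#' @export
simulate_ortholog_genomes <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  evs <- config$rearrangements
  if (length(evs) >= 2) {
    for (i in seq_len(length(evs) - 1)) {
      for (j in seq((i + 1), length(evs))) {
        a <- evs[[i]]; b <- evs[[j]]
        if (identical(a$chrom, b$chrom) &&
            a$start <= b$end && a$end >= b$start) {
          stop("overlapping rearrangement intervals: events ", i, " and ", j)
        }
      }
    }
  }
  with_seed(config$seed, {
    ann_a <- place_genes(config)
    seqs <- vapply(ann_a$gene, function(g) random_cds(config$gene_length),
                   character(1))
    ann_b <- ann_a
    for (ev in evs) ann_b <- apply_event(ann_b, ev)
    rownames(ann_a) <- rownames(ann_b) <- NULL
    orth <- rbind(cbind(genome = "genomeA", ann_a),
                  cbind(genome = "genomeB", ann_b))
    orth <- orth[, c("gene", "genome", "chrom", "start", "end", "strand")]
    rownames(orth) <- NULL
    list(genomes = list(genomeA = ann_a, genomeB = ann_b),
         orthologs = orth, sequences = seqs, events = evs)
  })
}

#' The adjacent-vs-distant two-gene scenario
#'
#' Builds the packaged reference scenario: a driver gene and a nearby
#' candidate gene placed `pair_gap` bp apart (default 180 kb, i.e. adjacent
#' on the sub-200-kb scale) in genome A, with an inversion in genome B that
#' relocates the candidate more than 10 Mb away from the driver while the
#' background genes stay scattered. This is the configuration under which
#' proximity-driven collateral mutagenesis in genome A, absent in genome B,
#' identifies the candidate as a passenger.
#'
#' @param seed integer seed.
#' @param n_background number of background genes in addition to the tagged
#'   pair.
#' @param pair_gap start-to-start separation of the tagged pair in genome A.
#' @param gene_length CDS length in bp.
#' @return As [simulate_ortholog_genomes()], plus `$driver` and `$passenger`
#'   gene ids.
#' @export
sim_apc_mcc_genomes <- function(seed = 1L, n_background = 28,
                                pair_gap = 180000, gene_length = 1500) {
  fixed <- data.frame(gene = c("driverA", "candB"),
                      chrom = "chr1",
                      start = c(3.0e7, 3.0e7 + pair_gap),
                      strand = c("+", "+"),
                      stringsAsFactors = FALSE)
  # Inversion starts just downstream of the driver and spans ~11 Mb, so the
  # candidate lands >10 Mb from the driver in genome B.
  inv <- rearrangement_event("inversion", chrom = "chr1",
                             start = 3.0e7 + pair_gap - 30000, end = 4.1e7)
  cfg <- genome_sim_config(n_chromosomes = 1, chrom_length = 5e7,
                           n_genes = n_background + 2,
                           gene_length = gene_length,
                           rearrangements = list(inv),
                           fixed_genes = fixed, seed = seed)
  sim <- simulate_ortholog_genomes(cfg)
  sim$driver <- "driverA"
  sim$passenger <- "candB"
  sim
}

#' Simulate a repeat annotation with target coverage at breakpoints
#'
#' Places non-overlapping repeat intervals along each breakpoint interval by
#' alternating repeat and gap runs whose expected lengths realize the target
#' union coverage; a fraction of repeats is labelled `Alu` so the Alu-only
#' coverage hits its own target. Breakpoint regions in real genomes are
#' repeat-enriched (on the order of 61% total repeats, 26% Alu), which is
#' the regime this generator is meant to emulate.
#'
#' @param intervals data frame (`chrom`, `start`, `end`), 1-based inclusive.
#' @param total_density target union coverage in `[0, 1]`.
#' @param alu_density target Alu-only coverage; must not exceed
#'   `total_density`.
#' @param seed integer seed.
#' @param repeat_len_range repeat length range in bp.
#' @return Data frame (`chrom`, `start`, `end`, `family`) of repeat records,
#'   1-based inclusive.
#' @export
simulate_repeat_annotation <- function(intervals, total_density,
                                       alu_density = 0, seed = 1L,
                                       repeat_len_range = c(150, 600)) {
  stopifnot(total_density >= 0, total_density <= 1,
            alu_density >= 0, alu_density <= total_density)
  min_len <- repeat_len_range[1]
  out <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(intervals))) {
      lo <- intervals$start[i]; hi <- intervals$end[i]
      chrom <- intervals$chrom[i]
      len <- hi - lo + 1
      if (total_density == 0) next
      if (len < min_len) {
        warning("interval shorter than minimum repeat length; no repeats placed")
        next
      }
      if (total_density >= 1) {
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, start = lo, end = hi, family = "Alu",
          stringsAsFactors = FALSE)
        next
      }
      mean_rep <- mean(repeat_len_range)
      mean_gap <- mean_rep * (1 - total_density) / total_density
      p_alu <- alu_density / total_density
      pos <- lo + floor(stats::rexp(1, 1 / mean_gap))
      while (pos <= hi - min_len) {
        rl <- floor(runif(1, repeat_len_range[1], repeat_len_range[2] + 1))
        rend <- min(pos + rl - 1, hi)
        fam <- if (runif(1) < p_alu) "Alu" else "L1"
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, start = pos, end = rend, family = fam,
          stringsAsFactors = FALSE)
        pos <- rend + 1 + ceiling(stats::rexp(1, 1 / mean_gap))
      }
    }
  })
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), family = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
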