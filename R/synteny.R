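# Synteny blocks, rearrangement breakpoints, gene-pair distances and repeat
# density, all computed from ortholog gene order (no raw-sequence alignment).

validate_ortholog_map <- function(map) {
  need <- c("gene", "genome", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("ortholog map lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(map$start >= map$end)) stop("ortholog map has start >= end")
  key <- paste(map$gene, map$genome)
  if (anyDuplicated(key)) stop("a gene appears more than once in a genome")
  invisible(map)
}

genome_slice <- function(map, genome_id) {
  s <- map[map$genome == genome_id, , drop = FALSE]
  s[order(s$chrom, s$start), , drop = FALSE]
}

#' Build synteny blocks from ortholog gene order
#'
#' A block is a maximal run of genes shared by both genomes that are
#' consecutive in each genome and colinear: either order and relative
#' orientation both preserved (`same`) or both uniformly reversed
#' (`inverted`). Blocks partition the shared genes; genes present in only
#' one genome are excluded from blocks and reported in the `singletons`
#' attribute.
#'
#' @param map long-format ortholog map (`gene`, `genome`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param genome_a,genome_b the two genome ids to compare.
#' @return Data frame with one row per block: `block`, `n_genes`, `genes`
#'   (comma-joined, in `genome_a` order), `orientation`, and per-genome
#'   interval columns (`chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`,
#'   `end_b`).
#' @export
build_synteny_blocks <- function(map, genome_a, genome_b) {
  validate_ortholog_map(map)
  a <- genome_slice(map, genome_a)
  b <- genome_slice(map, genome_b)
  shared <- intersect(a$gene, b$gene)
  singletons <- setdiff(union(a$gene, b$gene), shared)
  if (length(shared) == 0) {
    warning("no genes shared between ", genome_a, " and ", genome_b)
    out <- data.frame(block = integer(0), n_genes = integer(0),
                      genes = character(0), orientation = character(0),
                      chrom_a = character(0), start_a = numeric(0),
                      end_a = numeric(0), chrom_b = character(0),
                      start_b = numeric(0), end_b = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "singletons") <- singletons
    return(out)
  }
  a <- a[a$gene %in% shared, , drop = FALSE]
  b <- b[b$gene %in% shared, , drop = FALSE]
  # rank of each shared gene in each genome's (chrom, start) order
  rank_b <- setNames(seq_len(nrow(b)), b$gene)
  chrom_b_of <- setNames(b$chrom, b$gene)
  strand_rel <- setNames(
    ifelse(a$strand == b$strand[match(a$gene, b$gene)], 1L, -1L), a$gene)
  n <- nrow(a)
  block_id <- integer(n)
  cur <- 1L
  block_id[1] <- cur
  if (n > 1) {
    for (i in 2:n) {
      g <- a$gene[i]; h <- a$gene[i - 1]
      chain <- a$chrom[i] == a$chrom[i - 1] &&
        chrom_b_of[[g]] == chrom_b_of[[h]] &&
        strand_rel[[g]] == strand_rel[[h]] &&
        (rank_b[[g]] - rank_b[[h]]) == strand_rel[[h]]
      if (!chain) cur <- cur + 1L
      block_id[i] <- cur
    }
  }
  rows <- lapply(split(seq_len(n), block_id), function(idx) {
    genes <- a$gene[idx]
    bid <- match(genes, b$gene)
    data.frame(
      n_genes = length(idx),
      genes = paste(genes, collapse = ","),
      orientation = if (strand_rel[[genes[1]]] == 1L) "same" else "inverted",
      chrom_a = a$chrom[idx[1]], start_a = min(a$start[idx]),
      end_a = max(a$end[idx]),
      chrom_b = b$chrom[bid[1]], start_b = min(b$start[bid]),
      end_b = max(b$end[bid]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(block = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "singletons") <- singletons
  attr(out, "genomes") <- c(a = genome_a, b = genome_b)
  out
}

#' Locate rearrangement breakpoints between adjacent blocks
#'
#' Because blocks are maximal, every pair of blocks that are adjacent on a
#' chromosome of the reference genome delimits a breakpoint: their far-side
#' arrangement is by construction not adjacent-and-colinear. The breakpoint
#' interval is the intergenic gap between the bounding genes of the two
#' blocks on the reference.
#'
#' @param blocks output of [build_synteny_blocks()].
#' @param reference `"a"` or `"b"`: which genome's coordinates to report.
#' @return Data frame (`chrom`, `start`, `end`, `left_block`, `right_block`),
#'   1-based inclusive intergenic intervals.
#' @export
find_breakpoints <- function(blocks, reference = c("a", "b")) {
  reference <- match.arg(reference)
  cs <- paste0("chrom_", reference)
  ss <- paste0("start_", reference)
  es <- paste0("end_", reference)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), left_block = integer(0),
                      right_block = integer(0), stringsAsFactors = FALSE)
  if (nrow(blocks) < 2) return(empty)
  ord <- order(blocks[[cs]], blocks[[ss]])
  b <- blocks[ord, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(b) - 1)) {
    if (b[[cs]][i] != b[[cs]][i + 1]) next
    out[[length(out) + 1]] <- data.frame(
      chrom = b[[cs]][i],
      start = b[[es]][i] + 1,
      end = b[[ss]][i + 1] - 1,
      left_block = b$block[i], right_block = b$block[i + 1],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Start-to-start distance between two genes in one genome
#'
#' @param gene_a,gene_b gene ids.
#' @param genome_id genome to measure in.
#' @param map long-format ortholog map.
#' @return Absolute difference of the gene start coordinates in bp, or `Inf`
#'   if the genes lie on different chromosomes (the unlinked sentinel).
#' @export
gene_pair_distance <- function(gene_a, gene_b, genome_id, map) {
  s <- map[map$genome == genome_id, , drop = FALSE]
  for (g in c(gene_a, gene_b)) {
    if (!g %in% s$gene) stop("gene ", g, " absent from genome ", genome_id)
  }
  ra <- s[s$gene == gene_a, ]
  rb <- s[s$gene == gene_b, ]
  if (ra$chrom != rb$chrom) return(Inf)
  abs(ra$start - rb$start)
}

#' Classify a region as rearrangement-unstable across a species panel
#'
#' A region counts as unstable when at least `min_species` species carry at
#' least one breakpoint inside the region extended by `flank` on each side
#' ("nearby" breakpoints count: rearrangements a few Mb outside a region
#' still bear on its stability).
#'
#' @param region list or data frame row with `chrom`, `start`, `end`.
#' @param breakpoints_by_species named list of per-species breakpoint data
#'   frames (as from [find_breakpoints()]).
#' @param min_species minimum number of supporting species.
#' @param flank bp added on each side of the region (default 5 Mb).
#' @return List of class `region_instability_report`: `region`, `counts`
#'   (named per-species breakpoint counts in the flanked region),
#'   `supporting`, `verdict` (`"stable"`/`"unstable"`).
#' @export
classify_region_instability <- function(region, breakpoints_by_species,
                                        min_species = 3, flank = 5e6) {
  stopifnot(min_species >= 1)
  lo <- region$start - flank
  hi <- region$end + flank
  counts <- vapply(breakpoints_by_species, function(bp) {
    if (nrow(bp) == 0) return(0L)
    sum(bp$chrom == region$chrom & bp$start <= hi & bp$end >= lo)
  }, integer(1))
  supporting <- sum(counts >= 1)
  structure(list(region = region, counts = counts, supporting = supporting,
                 min_species = min_species, flank = flank,
                 verdict = if (supporting >= min_species) "unstable"
                           else "stable"),
            class = "region_instability_report")
}

#' @export
print.region_instability_report <- function(x, ...) {
  cat(sprintf("<region %s:%s-%s: %s (%d of %d species with breakpoints, k=%d)>\n",
              x$region$chrom, format(x$region$start, big.mark = ","),
              format(x$region$end, big.mark = ","), x$verdict,
              x$supporting, length(x$counts), x$min_species))
  invisible(x)
}

#' Fraction of an interval covered by repeats
#'
#' Union coverage: overlapping repeat records are counted once. Records with
#' start > end or missing coordinates are skipped and their count reported
#' as an attribute.
#'
#' @param interval list or data frame row with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param repeats repeat annotation data frame (`chrom`, `start`, `end`,
#'   optional `family`).
#' @param family optional regular expression; only repeats whose family
#'   matches are counted.
#' @return Covered fraction in `[0, 1]`, with attribute `n_skipped`.
#' @export
repeat_density <- function(interval, repeats, family = NULL) {
  stopifnot(interval$end >= interval$start)
  width <- interval$end - interval$start + 1
  r <- repeats
  bad <- is.na(r$start) | is.na(r$end) | r$start > r$end
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    warning(n_skipped, " malformed repeat record(s) skipped")
    r <- r[!bad, , drop = FALSE]
  }
  if (!is.null(family) && "family" %in% names(r)) {
    r <- r[grepl(family, r$family), , drop = FALSE]
  }
  r <- r[r$chrom == interval$chrom & r$start <= interval$end &
           r$end >= interval$start, , drop = FALSE]
  if (nrow(r) == 0) {
    return(structure(0, n_skipped = n_skipped))
  }
  ir <- IRanges::IRanges(start = pmax(r$start, interval$start),
                         end = pmin(r$end, interval$end))
  covered <- sum(IRanges::width(IRanges::reduce(ir)))
  structure(covered / width, n_skipped = n_skipped)
}
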