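# Tumor-cohort simulator with a distance-decay proximity mutagenesis model.
#
# A non-driver gene acquires a truncating alteration in a given tumor with
# probability beta + sum over drivers of alpha * exp(-d / lambda), where d is
# the start-to-start distance to the driver in that species' genome and
# unlinked genes (different chromosomes) contribute nothing. Drivers mutate
# with their own rate p_driver. This is the mechanism by which a bystander
# gene adjacent to a driver in one genome, but megabases away in another,
# shows species-restricted alteration.

#' Configuration of the proximity mutagenesis model
#'
#' @param alpha amplitude of the collateral-mutagenesis excess rate
#'   (probability per gene per tumor at distance 0).
#' @param beta background truncating rate per gene per tumor.
#' @param lambda decay length of the proximity effect, in bp.
#' @param p_driver per-tumor truncating probability of each driver gene.
#' @param driver_genes character vector of driver gene ids.
#' @return A list of class `proximity_model_config`.
#' @export
proximity_model_config <- function(alpha = 0.5, beta = 0.01, lambda = 5e5,
                                   p_driver = 0.9,
                                   driver_genes = character(0)) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            alpha + beta <= 1, lambda > 0, p_driver >= 0, p_driver <= 1)
  structure(list(alpha = alpha, beta = beta, lambda = lambda,
                 p_driver = p_driver, driver_genes = driver_genes),
            class = "proximity_model_config")
}

#' Per-tumor truncating probability of each gene in one genome
#'
#' @param genes character vector of gene ids.
#' @param genome_id which genome's distances to use.
#' @param orthologs long-format ortholog map.
#' @param model a [proximity_model_config()].
#' @return Named numeric vector of probabilities.
#' @export
gene_mutation_rates <- function(genes, genome_id, orthologs, model) {
  missing_drv <- setdiff(model$driver_genes,
                         orthologs$gene[orthologs$genome == genome_id])
  if (length(missing_drv) > 0) {
    stop("driver gene(s) missing from ", genome_id, ": ",
         paste(missing_drv, collapse = ", "))
  }
  vapply(genes, function(g) {
    if (g %in% model$driver_genes) return(model$p_driver)
    excess <- 0
    for (drv in model$driver_genes) {
      d <- gene_pair_distance(g, drv, genome_id, orthologs)
      if (is.finite(d)) excess <- excess + model$alpha * exp(-d / model$lambda)
    }
    min(1, model$beta + excess)
  }, numeric(1))
}

# Find single-base substitutions that convert a sense codon into a stop.
# Returns a data frame (offset 1..3, alt) of the possibilities, or zero rows.
nonsense_options <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  out <- list()
  for (stop in STOP_CODONS) {
    sb <- strsplit(stop, "")[[1]]
    diff <- which(bases != sb)
    if (length(diff) == 1) {
      out[[length(out) + 1]] <- data.frame(offset = diff, alt = sb[diff],
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    data.frame(offset = integer(0), alt = character(0))
  } else {
    do.call(rbind, out)
  }
}

# Draw one truncating lesion on a CDS: 50/50 nonsense substitution vs a
# 1-2 bp frameshift indel, position uniform over eligible sites.
draw_truncating_mutation <- function(cds) {
  n <- nchar(cds)
  codons <- split_codons(cds)
  if (runif(1) < 0.5) {
    # nonsense: pick among codons admitting a 1-bp change to a stop
    idx <- sample(length(codons) - 1)   # spare the terminal stop codon
    for (ci in idx) {
      opts <- nonsense_options(codons[ci])
      if (nrow(opts) > 0) {
        pick <- opts[sample(nrow(opts), 1), ]
        pos <- (ci - 1) * 3 + pick$offset
        return(data.frame(cds_pos = pos, ref = substr(cds, pos, pos),
                          alt = pick$alt, kind = "substitution",
                          truncating = TRUE, stringsAsFactors = FALSE))
      }
    }
    # no eligible codon (vanishingly rare): fall through to an indel
  }
  len <- sample(1:2, 1)
  if (runif(1) < 0.5) {
    pos <- sample(n - 1, 1)   # insertion anchored after pos
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    data.frame(cds_pos = pos, ref = "", alt = ins, kind = "insertion",
               truncating = TRUE, stringsAsFactors = FALSE)
  } else {
    pos <- sample(n - len - 3, 1) + 1   # keep the terminal stop intact
    data.frame(cds_pos = pos, ref = substr(cds, pos, pos + len - 1),
               alt = "", kind = "deletion", truncating = TRUE,
               stringsAsFactors = FALSE)
  }
}

#' Simulate per-tumor truth mutations for both species
#'
#' For each genome in `sim` a cohort of `n_tumors` tumors is generated; each
#' gene is hit independently at the rate given by the proximity model in
#' that genome. Every injected lesion is recorded with its CDS position,
#' reference and alternate alleles, so downstream variant calling can be
#' scored against exact truth.
#'
#' @param sim output of [simulate_ortholog_genomes()].
#' @param model a [proximity_model_config()].
#' @param n_tumors tumors per species.
#' @param seed integer seed.
#' @return Data frame (`species`, `tumor`, `gene`, `cds_pos`, `ref`, `alt`,
#'   `kind`, `truncating`). One row per injected mutation.
#' @export
simulate_tumor_cohort <- function(sim, model, n_tumors, seed = 1L) {
  stopifnot(inherits(model, "proximity_model_config"), n_tumors >= 1)
  genomes <- names(sim$genomes)
  genes <- sim$genomes[[1]]$gene
  rows <- list()
  with_seed(seed, {
    for (gm in genomes) {
      rates <- gene_mutation_rates(genes, gm, sim$orthologs, model)
      for (t in seq_len(n_tumors)) {
        hit <- runif(length(genes)) < rates
        for (g in genes[hit]) {
          mut <- draw_truncating_mutation(sim$sequences[[g]])
          rows[[length(rows) + 1]] <- cbind(
            data.frame(species = gm, tumor = sprintf("%s_T%02d", gm, t),
                       gene = g, stringsAsFactors = FALSE),
            mut)
        }
      }
    }
  })
  if (length(rows) == 0) {
    return(data.frame(species = character(0), tumor = character(0),
                      gene = character(0), cds_pos = numeric(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), truncating = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Apply truth variants to a CDS sequence
#'
#' Produces the tumor haplotype sequence carrying the recorded lesions
#' (substitutions in place; insertions after their anchor base; deletions
#' removed). Variants are applied right-to-left so earlier coordinates stay
#' valid.
#'
#' @param cds reference CDS string.
#' @param variants data frame with `cds_pos`, `ref`, `alt`, `kind` (as
#'   emitted by [simulate_tumor_cohort()]).
#' @return The mutated sequence string.
#' @export
apply_variants <- function(cds, variants) {
  if (nrow(variants) == 0) return(cds)
  v <- variants[order(-variants$cds_pos), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    p <- v$cds_pos[i]
    if (v$kind[i] == "substitution") {
      stopifnot(substr(cds, p, p) == v$ref[i])
      substr(cds, p, p) <- v$alt[i]
    } else if (v$kind[i] == "insertion") {
      cds <- paste0(substr(cds, 1, p), v$alt[i],
                    substr(cds, p + 1, nchar(cds)))
    } else {
      stopifnot(substr(cds, p, p + nchar(v$ref[i]) - 1) == v$ref[i])
      cds <- paste0(substr(cds, 1, p - 1),
                    substr(cds, p + nchar(v$ref[i]), nchar(cds)))
    }
  }
  cds
}
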