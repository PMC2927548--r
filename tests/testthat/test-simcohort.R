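test_that("zero rearrangements give identical gene order and orientation", {
  cfg <- genome_sim_config(n_genes = 12, seed = 7)
  sim <- simulate_ortholog_genomes(cfg)
  expect_identical(sim$genomes$genomeA, sim$genomes$genomeB)
})

test_that("simulators are deterministic given the seed", {
  cfg <- genome_sim_config(n_genes = 10, seed = 11)
  expect_identical(simulate_ortholog_genomes(cfg),
                   simulate_ortholog_genomes(cfg))
  sim <- sim_apc_mcc_genomes(seed = 5)
  expect_identical(sim, sim_apc_mcc_genomes(seed = 5))
  m <- proximity_model_config(driver_genes = sim$driver)
  expect_identical(simulate_tumor_cohort(sim, m, 5, seed = 3),
                   simulate_tumor_cohort(sim, m, 5, seed = 3))
  expect_identical(simulate_trace_pair("ACGTACGTAC", seed = 2),
                   simulate_trace_pair("ACGTACGTAC", seed = 2))
  expect_identical(simulate_ct_table(c("a", "b"), 4, seed = 8),
                   simulate_ct_table(c("a", "b"), 4, seed = 8))
  cc <- cgh_sim_config(genome_length = 5e6, seed = 4)
  expect_identical(simulate_cgh_profile(cc), simulate_cgh_profile(cc))
})

test_that("the adjacent-vs-distant scenario realizes its distance asymmetry", {
  sim <- sim_apc_mcc_genomes(seed = 2)
  dA <- gene_pair_distance(sim$driver, sim$passenger, "genomeA",
                           sim$orthologs)
  dB <- gene_pair_distance(sim$driver, sim$passenger, "genomeB",
                           sim$orthologs)
  expect_lt(dA, 2e5)
  expect_gte(dB, 1e7)
})

test_that("overlapping rearrangement intervals are rejected", {
  evs <- list(rearrangement_event("inversion", "chr1", 1e6, 2e6),
              rearrangement_event("inversion", "chr1", 1.5e6, 3e6))
  cfg <- genome_sim_config(rearrangements = evs, seed = 1)
  expect_error(simulate_ortholog_genomes(cfg), "overlapping")
})

test_that("applying an inversion twice restores the annotation", {
  ann <- data.frame(gene = paste0("g", 1:6), chrom = "chr1",
                    start = c(1, 3, 5, 7, 9, 11) * 1e6,
                    end = c(1, 3, 5, 7, 9, 11) * 1e6 + 1499,
                    strand = c("+", "-", "+", "+", "-", "+"),
                    stringsAsFactors = FALSE)
  ev <- rearrangement_event("inversion", "chr1", 2e6, 10e6)
  once <- xenopass:::apply_event(ann, ev)
  expect_false(identical(once$start, ann$start))
  twice <- xenopass:::apply_event(once, ev)
  expect_equal(twice[order(twice$gene), ], ann[order(ann$gene), ],
               ignore_attr = TRUE)
  # a boundary that cuts through a gene is rejected by name
  bad <- rearrangement_event("inversion", "chr1", 3e6 + 100, 8e6)
  expect_error(xenopass:::apply_event(ann, bad), "g2")
})

test_that("proximity rate law matches its closed form empirically", {
  # driver at 1e6; target at 150 kb; an unlinked far gene on another chrom
  sim <- make_toy_sim(starts_a = c(1e6, 1.15e6, 2e7),
                      chrom_b = c("chr1", "chr1", "chr2"))
  model <- proximity_model_config(alpha = 0.5, beta = 0.01, lambda = 5e5,
                                  p_driver = 0.9,
                                  driver_genes = "t01")
  rates <- gene_mutation_rates(c("t01", "t02", "t03"), "genomeA",
                               sim$orthologs, model)
  expect_equal(unname(rates["t02"]), 0.01 + 0.5 * exp(-0.3),
               tolerance = 1e-12)
  n <- 10000
  cohort <- simulate_tumor_cohort(sim, model, n, seed = 31)
  k_near <- length(unique(cohort$tumor[cohort$gene == "t02" &
                                         cohort$species == "genomeA"]))
  p <- 0.01 + 0.5 * exp(-0.3)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(k_near / n - p), 3 * se)
  # unlinked gene in genome B: distance Inf leaves the background rate
  k_far <- length(unique(cohort$tumor[cohort$gene == "t03" &
                                        cohort$species == "genomeB"]))
  se0 <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(k_far / n - 0.01), 3 * se0)
})

test_that("every injected mutation is truncating with valid alleles", {
  sim <- make_toy_sim(starts_a = c(1e6, 1.2e6))
  model <- proximity_model_config(alpha = 0.5, beta = 0.05,
                                  driver_genes = "t01")
  cohort <- simulate_tumor_cohort(sim, model, 50, seed = 13)
  expect_true(all(cohort$truncating))
  expect_true(all(cohort$kind %in% c("substitution", "insertion",
                                     "deletion")))
  for (i in seq_len(nrow(cohort))) {
    cds <- sim$sequences[[cohort$gene[i]]]
    if (cohort$kind[i] == "substitution") {
      expect_equal(substr(cds, cohort$cds_pos[i], cohort$cds_pos[i]),
                   cohort$ref[i])
      # the substitution creates a stop codon
      mut <- apply_variants(cds, cohort[i, , drop = FALSE])
      mc <- map_to_codon(cohort$cds_pos[i])
      lo <- 3 * (mc$codon - 1) + 1
      expect_true(substr(mut, lo, lo + 2) %in% c("TAA", "TAG", "TGA"))
    } else {
      expect_true(max(nchar(cohort$ref[i]), nchar(cohort$alt[i])) %% 3 != 0)
    }
  }
})

test_that("missing driver gene is reported by name", {
  sim <- make_toy_sim(starts_a = c(1e6, 2e6))
  model <- proximity_model_config(driver_genes = "nosuchgene")
  expect_error(simulate_tumor_cohort(sim, model, 2, seed = 1),
               "nosuchgene")
})

test_that("trace error rate matches the phred model at fixed quality", {
  truth <- paste(rep("ACGT", 200), collapse = "")   # 800 bp
  for (q in c(10, 20, 30)) {
    n_bases <- 0; n_err <- 0
    n_rep <- if (q == 30) 80 else 40
    for (s in seq_len(n_rep)) {
      tp <- simulate_trace_pair(truth, uniform_q_config(q), seed = s)
      fwd <- strsplit(tp$forward$bases, "")[[1]]
      tru <- strsplit(truth, "")[[1]]
      n_bases <- n_bases + length(fwd)
      n_err <- n_err + sum(fwd != tru)
      rvc <- strsplit(tp$reverse$bases, "")[[1]]
      rv_truth <- strsplit(
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(truth))), "")[[1]]
      n_bases <- n_bases + length(rvc)
      n_err <- n_err + sum(rvc != rv_truth)
    }
    p <- 10^(-q / 10)
    se <- sqrt(p * (1 - p) / n_bases)
    expect_lt(abs(n_err / n_bases - p), 3 * se)
    expect_gte(n_bases, 6e4)
  }
})

test_that("high-quality traces reproduce the truth sequence", {
  truth <- paste(rep("GATTACA", 40), collapse = "")
  tp <- simulate_trace_pair(truth, uniform_q_config(60, 400), seed = 5)
  expect_equal(tp$forward$bases, substr(truth, 1, 400))
  expect_equal(tp$reverse$bases,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(truth, nchar(truth) - 399,
                                              nchar(truth))))))
})

test_that("repeat simulation hits its coverage targets", {
  iv <- data.frame(chrom = "chr1", start = 1, end = 2e5)
  rep0 <- simulate_repeat_annotation(iv, 0, 0, seed = 1)
  expect_equal(nrow(rep0), 0)
  reps <- simulate_repeat_annotation(iv, 0.61, 0.26, seed = 2)
  dens <- repeat_density(list(chrom = "chr1", start = 1, end = 2e5), reps)
  dens_alu <- repeat_density(list(chrom = "chr1", start = 1, end = 2e5),
                             reps, family = "Alu")
  expect_lt(abs(as.numeric(dens) - 0.61), 0.05)
  expect_lt(abs(as.numeric(dens_alu) - 0.26), 0.05)
  full <- simulate_repeat_annotation(iv, 1, 1, seed = 3)
  expect_equal(as.numeric(repeat_density(list(chrom = "chr1", start = 1,
                                              end = 2e5), full)), 1.0)
  expect_warning(
    simulate_repeat_annotation(
      data.frame(chrom = "chr1", start = 1, end = 50), 0.5, 0, seed = 4),
    "shorter")
})

test_that("Ct simulation honors effects and degenerate settings", {
  ct0 <- simulate_ct_table(c("g", "ref"), 5, replicate_sd = 0, pair_sd = 0.5,
                           seed = 3)
  tum <- ct0[ct0$tissue == "tumor", ]
  nor <- ct0[ct0$tissue == "normal", ]
  expect_equal(tum$ct1, nor$ct1)               # effect 0, sd 0
  expect_equal(ct0$ct1, ct0$ct2)               # sd 0: identical triplicates
  ct1 <- simulate_ct_table(c("g", "ref"), 10, effects = c(g = 1.0), seed = 9)
  res <- delta_ct_analysis(ct1, "g", "ref")
  expect_lt(abs(res$mean_diff - 1.0), 0.25)
})

test_that("aCGH simulator respects probe spacing and truth fraction", {
  cfg <- cgh_sim_config(genome_length = 1e8, probe_spacing = 5000,
                        altered_fraction = 0.04, seed = 6)
  out <- simulate_cgh_profile(cfg)
  expect_equal(nrow(out$profile), 20000)
  truth_len <- sum(out$truth$end - out$truth$start + 1)
  expect_lt(abs(truth_len / 1e8 - 0.04), 5000 / 1e8 * 2)
  out0 <- simulate_cgh_profile(cgh_sim_config(genome_length = 1e7,
                                              altered_fraction = 0,
                                              seed = 2))
  expect_equal(nrow(out0$truth), 0)
  expect_error(cgh_sim_config(altered_fraction = 0.05,
                              seg_len_range = c(10, 100)),
               "spacing")
})
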