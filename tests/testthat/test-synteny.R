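test_that("identical order and orientation form a single block", {
  map <- make_inversion_map()
  map$start[map$genome == "Y"] <- map$start[map$genome == "X"]
  map$end[map$genome == "Y"] <- map$end[map$genome == "X"]
  map$strand <- "+"
  blocks <- build_synteny_blocks(map, "X", "Y")
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_genes, 5)
  expect_equal(blocks$orientation, "same")
  expect_equal(nrow(find_breakpoints(blocks, "a")), 0)
})

test_that("an interior signed inversion yields 3 blocks and 2 breakpoints", {
  map <- make_inversion_map()    # (1,2,3,4,5) vs (1,-3,-2,4,5)
  blocks <- build_synteny_blocks(map, "X", "Y")
  expect_equal(nrow(blocks), 3)
  expect_setequal(blocks$genes, c("g1", "g2,g3", "g4,g5"))
  expect_equal(blocks$orientation[blocks$genes == "g2,g3"], "inverted")
  # partition invariant: every shared gene in exactly one block
  all_genes <- unlist(strsplit(blocks$genes, ","))
  expect_setequal(all_genes, paste0("g", 1:5))
  expect_equal(anyDuplicated(all_genes), 0)
  bp <- find_breakpoints(blocks, "a")
  expect_equal(nrow(bp), 2)
  # breakpoints are the intergenic gaps flanking the inverted run
  expect_equal(bp$start, c(200, 600))
  expect_equal(bp$end, c(299, 699))
})

test_that("genes split across chromosomes break blocks", {
  map <- make_inversion_map()
  map$start[map$genome == "Y"] <- map$start[map$genome == "X"]
  map$end[map$genome == "Y"] <- map$end[map$genome == "X"]
  map$strand <- "+"
  map$chrom[map$genome == "Y" & map$gene %in% c("g4", "g5")] <- "chr2"
  blocks <- build_synteny_blocks(map, "X", "Y")
  expect_gte(nrow(blocks), 2)
  expect_setequal(unlist(strsplit(blocks$genes, ",")), paste0("g", 1:5))
})

test_that("m separated inversions produce 2m breakpoints", {
  starts <- seq(1e6, 19e6, by = 1e6)   # 19 genes, 1 Mb apart
  genes <- sprintf("g%02d", seq_along(starts))
  ann <- data.frame(gene = genes, chrom = "chr1", start = starts,
                    end = starts + 1499, strand = "+",
                    stringsAsFactors = FALSE)
  for (m in 1:3) {
    b <- ann
    # inversions around genes {3,4}, {8,9}, {13,14}: reflect within window
    windows <- list(c(2.5e6, 4.5e6), c(7.5e6, 9.5e6), c(12.5e6, 14.5e6))
    for (w in windows[seq_len(m)]) {
      inside <- b$start >= w[1] & b$end <= w[2]
      ns <- w[1] + (w[2] - b$end[inside])
      ne <- w[1] + (w[2] - b$start[inside])
      b$start[inside] <- ns; b$end[inside] <- ne
      b$strand[inside] <- ifelse(b$strand[inside] == "+", "-", "+")
    }
    map <- rbind(cbind(genome = "X", ann), cbind(genome = "Y", b))
    map <- map[, c("gene", "genome", "chrom", "start", "end", "strand")]
    blocks <- build_synteny_blocks(map, "X", "Y")
    expect_equal(nrow(find_breakpoints(blocks, "a")), 2 * m,
                 info = paste("m =", m))
  }
})

test_that("the scenario fixture places a breakpoint between the gene pair", {
  sim <- sim_apc_mcc_genomes(seed = 4)
  blocks <- build_synteny_blocks(sim$orthologs, "genomeA", "genomeB")
  bp <- find_breakpoints(blocks, "a")
  expect_gte(nrow(bp), 2)
  ann <- sim$genomes$genomeA
  drv_end <- ann$end[ann$gene == sim$driver]
  cand_start <- ann$start[ann$gene == sim$passenger]
  between <- bp$start >= drv_end & bp$end <= cand_start
  expect_true(any(between))
})

test_that("gene_pair_distance is symmetric, start-to-start, Inf off-chromosome", {
  map <- data.frame(gene = c("a", "b", "c"), genome = "G",
                    chrom = c("chr5", "chr5", "chr7"),
                    start = c(112000000, 112180000, 500),
                    end = c(112000100, 112180100, 600),
                    strand = "+", stringsAsFactors = FALSE)
  expect_equal(gene_pair_distance("a", "b", "G", map), 180000)
  expect_equal(gene_pair_distance("b", "a", "G", map),
               gene_pair_distance("a", "b", "G", map))
  expect_equal(gene_pair_distance("a", "c", "G", map), Inf)
  expect_error(gene_pair_distance("a", "zz", "G", map), "zz")
})

test_that("region instability counts supporting species within the flank", {
  region <- list(chrom = "chr1", start = 1e6, end = 2e6)
  none <- replicate(4, data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0)), simplify = FALSE)
  names(none) <- paste0("sp", 1:4)
  r0 <- classify_region_instability(region, none, min_species = 3)
  expect_equal(r0$verdict, "stable")
  expect_equal(r0$supporting, 0)
  bp_in <- data.frame(chrom = "chr1", start = 1.5e6, end = 1.6e6)
  bp_near <- data.frame(chrom = "chr1", start = 4e6, end = 4.1e6)  # in flank
  bp_far <- data.frame(chrom = "chr1", start = 5e7, end = 5.1e7)
  lists <- c(replicate(10, bp_in, simplify = FALSE),
             replicate(4, bp_far, simplify = FALSE))
  names(lists) <- paste0("sp", 1:14)
  r1 <- classify_region_instability(region, lists, min_species = 3)
  expect_equal(r1$verdict, "unstable")
  expect_equal(r1$supporting, 10)
  # flank inclusion and the k > n_species guard
  r2 <- classify_region_instability(region, list(s1 = bp_near, s2 = bp_in),
                                    min_species = 2, flank = 5e6)
  expect_equal(r2$verdict, "unstable")
  r3 <- classify_region_instability(region, lists, min_species = 15)
  expect_equal(r3$verdict, "stable")
})

test_that("repeat_density equals the interval-union oracle", {
  iv <- list(chrom = "c", start = 1, end = 200)
  reps <- data.frame(chrom = "c", start = c(1, 51), end = c(100, 150),
                     family = c("Alu", "L1"), stringsAsFactors = FALSE)
  expect_equal(as.numeric(repeat_density(iv, reps)), 0.75)
  expect_equal(as.numeric(repeat_density(iv, reps)),
               brute_force_coverage(iv, reps))
  expect_equal(as.numeric(repeat_density(
    iv, reps[integer(0), , drop = FALSE])), 0)
  set.seed(77)
  # random cases against the oracle, and monotonicity under record addition
  for (rep_i in 1:5) {
    n <- sample(3:12, 1)
    r <- data.frame(chrom = "c",
                    start = sample(1:180, n, TRUE),
                    end = 0, family = "Alu", stringsAsFactors = FALSE)
    r$end <- r$start + sample(5:60, n, TRUE)
    expect_equal(as.numeric(repeat_density(iv, r)),
                 brute_force_coverage(iv, r))
    d_part <- as.numeric(repeat_density(iv, r[1:(n - 1), , drop = FALSE]))
    expect_lte(d_part, as.numeric(repeat_density(iv, r)))
  }
  malformed <- rbind(reps, data.frame(chrom = "c", start = 50, end = 10,
                                      family = "L1"))
  expect_warning(d <- repeat_density(iv, malformed), "malformed")
  expect_equal(as.numeric(d), 0.75)
})
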