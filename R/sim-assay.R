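# Simulators for the two alteration assays: qPCR Ct tables and aCGH
# log2-ratio profiles.

#' Simulate a paired tumor/normal Ct table
#'
#' Each (pair, tissue, gene) gets `n_replicates` technical replicates.
#' The generative model is
#' `Ct = base_g + pair_i + shift_{i,t} + effect_g * [t == tumor] + noise`,
#' with per-gene baselines, a shared biological pair effect (cancels in the
#' paired design), an optional per-sample loading shift (cancels under
#' reference-gene normalization) and replicate noise. Reference genes are
#' simply genes with effect 0.
#'
#' @param genes character vector of gene ids.
#' @param n_pairs number of tumor/normal pairs.
#' @param effects named numeric vector of tumor Ct shifts (Ct units; positive
#'   means higher Ct in tumor, i.e. less template). Genes absent from
#'   `effects` get 0.
#' @param replicate_sd technical replicate standard deviation (Ct units).
#' @param pair_sd between-pair biological standard deviation.
#' @param sample_shift_sd per-sample loading shift standard deviation.
#' @param n_replicates replicates per well (default triplicates).
#' @param seed integer seed.
#' @return Data frame (`pair_id`, `tissue`, `gene`, `ct1`..`ctk`).
#' @export
simulate_ct_table <- function(genes, n_pairs, effects = numeric(0),
                              replicate_sd = 0.2, pair_sd = 1,
                              sample_shift_sd = 0, n_replicates = 3,
                              seed = 1L) {
  stopifnot(replicate_sd >= 0, pair_sd >= 0, sample_shift_sd >= 0,
            n_replicates >= 1, n_pairs >= 1)
  eff <- setNames(rep(0, length(genes)), genes)
  eff[names(effects)] <- effects
  with_seed(seed, {
    base_ct <- setNames(runif(length(genes), 18, 28), genes)
    rows <- list()
    for (i in seq_len(n_pairs)) {
      pair_eff <- if (pair_sd > 0) rnorm(1, 0, pair_sd) else 0
      for (tissue in c("normal", "tumor")) {
        shift <- if (sample_shift_sd > 0) rnorm(1, 0, sample_shift_sd) else 0
        for (g in genes) {
          mu <- base_ct[[g]] + pair_eff + shift +
            if (tissue == "tumor") eff[[g]] else 0
          reps <- mu + if (replicate_sd > 0) {
            rnorm(n_replicates, 0, replicate_sd)
          } else {
            rep(0, n_replicates)
          }
          row <- data.frame(pair_id = sprintf("P%02d", i), tissue = tissue,
                            gene = g, stringsAsFactors = FALSE)
          for (r in seq_len(n_replicates)) row[[paste0("ct", r)]] <- reps[r]
          rows[[length(rows) + 1]] <- row
        }
      }
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

#' Configuration of the aCGH profile simulator
#'
#' Defaults emulate a high-density oligo array: one probe every 5 kb, with
#' a few percent of the genome in copy-number segments of a few hundred kb
#' at single-copy log2 magnitude, on top of Gaussian probe noise.
#'
#' @param genome_length genome length in bp.
#' @param probe_spacing probe spacing in bp (probe count =
#'   `floor(genome_length / probe_spacing)`).
#' @param altered_fraction target fraction of the genome in gain/loss
#'   segments.
#' @param seg_len_range min/max altered-segment length in bp.
#' @param gain_mean,loss_mean log2-ratio means of gains and losses.
#' @param noise_sd per-probe noise sd (log2 units).
#' @param seed integer seed.
#' @return A list of class `cgh_sim_config`.
#' @export
cgh_sim_config <- function(genome_length = 1e8, probe_spacing = 5000,
                           altered_fraction = 0.04,
                           seg_len_range = c(2e5, 1e6),
                           gain_mean = 0.8, loss_mean = -0.8,
                           noise_sd = 0.15, seed = 1L) {
  stopifnot(altered_fraction >= 0, altered_fraction <= 1,
            probe_spacing > 0, genome_length >= probe_spacing,
            noise_sd >= 0, seg_len_range[1] <= seg_len_range[2])
  if (altered_fraction > 0 && seg_len_range[2] < probe_spacing) {
    stop("max segment length is below probe spacing; segments would be invisible")
  }
  structure(list(genome_length = genome_length,
                 probe_spacing = probe_spacing,
                 altered_fraction = altered_fraction,
                 seg_len_range = seg_len_range,
                 gain_mean = gain_mean, loss_mean = loss_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cgh_sim_config")
}

#' Simulate an aCGH log2-ratio profile with known altered segments
#'
#' Truth segments are placed without overlap (separated by at least 10 probe
#' spacings) with lengths drawn from `seg_len_range`; the last segment is
#' trimmed so the total altered length matches the target fraction to within
#' one probe spacing. Segment states alternate gain/loss.
#'
#' @param config a [cgh_sim_config()].
#' @return List with `profile` (data frame `chrom`, `pos`, `log2ratio`) and
#'   `truth` (data frame `chrom`, `start`, `end`, `state`, `mean`).
#' @export
simulate_cgh_profile <- function(config) {
  stopifnot(inherits(config, "cgh_sim_config"))
  L <- config$genome_length
  sp <- config$probe_spacing
  n <- floor(L / sp)
  pos <- sp * seq_len(n) - floor(sp / 2)
  with_seed(config$seed, {
    target <- config$altered_fraction * L
    segs <- list()
    total <- 0
    guard <- 10 * sp
    if (config$altered_fraction > 0) {
      lens <- numeric(0)
      while (total < target) {
        l <- runif(1, config$seg_len_range[1], config$seg_len_range[2])
        l <- min(l, target - total)
        l <- max(l, sp)    # never below one probe spacing
        lens <- c(lens, l)
        total <- total + l
      }
      # place segments left to right with random gaps filling the free space
      free <- L - sum(lens) - guard * (length(lens) + 1)
      if (free < 0) stop("altered fraction too high for the segment spacing")
      gaps <- runif(length(lens) + 1)
      gaps <- gaps / sum(gaps) * free
      cur <- 0
      for (i in seq_along(lens)) {
        cur <- cur + gaps[i] + guard
        st <- if (i %% 2 == 1) "gain" else "loss"
        mu <- if (st == "gain") config$gain_mean else config$loss_mean
        segs[[i]] <- data.frame(chrom = "chr1", start = floor(cur) + 1,
                                end = floor(cur + lens[i]), state = st,
                                mean = mu, stringsAsFactors = FALSE)
        cur <- cur + lens[i]
      }
    }
    truth <- if (length(segs)) do.call(rbind, segs) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 state = character(0), mean = numeric(0),
                 stringsAsFactors = FALSE)
    mu <- rep(0, n)
    for (i in seq_len(nrow(truth))) {
      inside <- pos >= truth$start[i] & pos <= truth$end[i]
      mu[inside] <- truth$mean[i]
    }
    y <- mu + if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
    list(profile = data.frame(chrom = "chr1", pos = pos, log2ratio = y,
                              stringsAsFactors = FALSE),
         truth = truth)
  })
}
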