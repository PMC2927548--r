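# aCGH segmentation and chromosomal-instability quantification.
#
# Segmentation is recursive binary splitting: at each node the split point
# maximizing the two-sample t statistic between the flanking means is
# tested against a permutation null of the node's probe values; accepted
# splits recurse, rejected nodes become segments. The procedure is
# deterministic given its seed and validated by parameter recovery on
# simulated profiles.

# max-|t| split of x[lo..hi]; returns list(k, t) with k the last index of
# the left arm, or NULL if no admissible split
best_split <- function(x, min_probes) {
  n <- length(x)
  if (n < 2 * min_probes) return(NULL)
  ks <- min_probes:(n - min_probes)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  n1 <- ks
  n2 <- n - ks
  s1 <- cs[ks]
  s2 <- cs[n] - s1
  m1 <- s1 / n1
  m2 <- s2 / n2
  ss1 <- cs2[ks] - n1 * m1^2
  ss2 <- (cs2[n] - cs2[ks]) - n2 * m2^2
  pooled <- (ss1 + ss2) / (n - 2)
  se <- sqrt(pooled * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, abs(m1 - m2) / se,
               ifelse(abs(m1 - m2) > 0, Inf, 0))
  k <- which.max(tt)
  list(k = ks[k], t = tt[k])
}

segment_indices <- function(x, min_probes, n_perm, alpha_seg) {
  n <- length(x)
  sp <- best_split(x, min_probes)
  if (is.null(sp) || sp$t == 0) return(n)
  perm_t <- vapply(seq_len(n_perm), function(i) {
    p <- best_split(sample(x), min_probes)
    if (is.null(p)) 0 else p$t
  }, numeric(1))
  p_val <- (1 + sum(perm_t >= sp$t)) / (n_perm + 1)
  if (p_val >= alpha_seg) return(n)
  left <- segment_indices(x[1:sp$k], min_probes, n_perm, alpha_seg)
  right <- segment_indices(x[(sp$k + 1):n], min_probes, n_perm, alpha_seg)
  c(left, sp$k + right)
}

#' Segment an aCGH log2-ratio profile
#'
#' Recursive binary segmentation with permutation-calibrated split
#' acceptance, applied per chromosome. Segment boundaries in bp are placed
#' midway between the flanking probes; the outer boundaries sit half a
#' median probe spacing outside the terminal probes, so segments tile the
#' profile extent without overlap.
#'
#' @param profile data frame (`chrom`, `pos`, `log2ratio`), positions
#'   strictly increasing within each chromosome.
#' @param min_probes minimum probes per segment (default 5).
#' @param n_perm permutations per tested split (default 200).
#' @param alpha_seg significance level for accepting a split.
#' @param seed integer seed driving the permutations.
#' @param delta `|mean log2 ratio|` threshold separating gain/loss from
#'   neutral states.
#' @return Data frame (`chrom`, `start`, `end`, `n_probes`, `mean`,
#'   `state`) of class `cgh_segments`.
#' @export
segment_profile <- function(profile, min_probes = 5, n_perm = 200,
                            alpha_seg = 0.01, seed = 1L, delta = 0.3) {
  stopifnot(all(c("chrom", "pos", "log2ratio") %in% names(profile)))
  out <- list()
  with_seed(seed, {
    for (chrom in unique(profile$chrom)) {
      p <- profile[profile$chrom == chrom, , drop = FALSE]
      if (is.unsorted(p$pos, strictly = TRUE)) {
        stop("probe positions not strictly increasing on ", chrom)
      }
      x <- p$log2ratio
      n <- length(x)
      half <- if (n > 1) stats::median(diff(p$pos)) / 2 else 2500
      edges <- c(p$pos[1] - half,
                 if (n > 1) (p$pos[-n] + p$pos[-1]) / 2 else numeric(0),
                 p$pos[n] + half)
      ends_idx <- segment_indices(x, min_probes, n_perm, alpha_seg)
      starts_idx <- c(1, head(ends_idx, -1) + 1)
      for (s in seq_along(ends_idx)) {
        idx <- starts_idx[s]:ends_idx[s]
        mu <- mean(x[idx])
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom,
          start = edges[starts_idx[s]],
          end = edges[ends_idx[s] + 1],
          n_probes = length(idx), mean = mu,
          state = if (mu > delta) "gain" else if (mu < -delta) "loss"
                  else "neutral",
          stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cgh_segments", "data.frame")
  res
}

#' Fraction of the profiled genome in altered segments
#'
#' Gains and losses are pooled: the altered fraction is the summed length
#' of segments with `|mean| > delta` divided by the total tiled length.
#'
#' @param segments a [segment_profile()] result (or any data frame with
#'   `start`, `end`, `mean`).
#' @param delta `|mean log2 ratio|` threshold.
#' @return Proportion in `[0, 1]`.
#' @export
altered_fraction <- function(segments, delta = 0.3) {
  len <- segments$end - segments$start
  total <- sum(len)
  if (total <= 0) return(0)
  sum(len[abs(segments$mean) > delta]) / total
}

#' Classify chromosomal-instability level
#'
#' `none` below `cut_subtle`, `subtle` between the cuts (a few percent of
#' the genome altered), `extensive` above `cut_extensive` (the regime of
#' overtly aneuploid tumors, more than ~10% altered).
#'
#' @param fraction altered-genome fraction in `[0, 1]`.
#' @param cut_subtle,cut_extensive class boundaries.
#' @return List of class `cin_report`: `fraction`, `class`.
#' @export
classify_cin <- function(fraction, cut_subtle = 0.02, cut_extensive = 0.10) {
  stopifnot(fraction >= 0, fraction <= 1)
  cls <- if (fraction < cut_subtle) "none"
         else if (fraction > cut_extensive) "extensive"
         else "subtle"
  structure(list(fraction = fraction, class = cls,
                 cut_subtle = cut_subtle, cut_extensive = cut_extensive),
            class = "cin_report")
}

#' @export
print.cin_report <- function(x, ...) {
  cat(sprintf("<CIN: %.2f%% of genome altered -> %s>\n", 100 * x$fraction,
              x$class))
  invisible(x)
}
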