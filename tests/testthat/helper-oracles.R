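# Independent oracles used to freeze expected values. These deliberately
# share no code with the package implementation.

# Exhaustive alignment-score oracle: enumerate every monotone path of
# {diagonal, gap-in-seq2, gap-in-seq1} operations and score it with the
# affine model (a gap of length k costs open + k * extend). Tractable for
# short sequences only.
brute_force_align_score <- function(s1, s2, match = 1, mismatch = -2,
                                    gap_open = -5, gap_extend = -2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  rec <- function(i, j, last) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      s <- if (a[i + 1] == b[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i < n) {
      cost <- gap_extend + if (last != "D") gap_open else 0
      best <- max(best, cost + rec(i + 1, j, "D"))
    }
    if (j < m) {
      cost <- gap_extend + if (last != "I") gap_open else 0
      best <- max(best, cost + rec(i, j + 1, "I"))
    }
    best
  }
  rec(0, 0, "M")
}

# O(n^2) trimming oracle: longest substring (leftmost on ties) in which
# every length-w window has mean quality >= qmin.
brute_force_trim <- function(quals, w, qmin) {
  n <- length(quals)
  best <- c(0L, 0L)
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (b - a + 1 < w) next
      ok <- TRUE
      for (s in a:(b - w + 1)) {
        if (mean(quals[s:(s + w - 1)]) < qmin) { ok <- FALSE; break }
      }
      if (ok && (b - a + 1) > (best[2] - best[1] + 1)) best <- c(a, b)
    }
  }
  best
}

# Position-by-position interval-union coverage oracle.
brute_force_coverage <- function(interval, repeats) {
  hit <- rep(FALSE, interval$end - interval$start + 1)
  for (i in seq_len(nrow(repeats))) {
    if (repeats$chrom[i] != interval$chrom) next
    lo <- max(repeats$start[i], interval$start)
    hi <- min(repeats$end[i], interval$end)
    if (lo > hi) next
    hit[(lo - interval$start + 1):(hi - interval$start + 1)] <- TRUE
  }
  mean(hit)
}

# Exhaustive split-point oracle for a noiseless two-level step profile:
# the change point maximizing the between-means |t| equals the true step.
brute_force_best_step <- function(x) {
  n <- length(x)
  best_k <- NA; best_obj <- -Inf
  for (k in 1:(n - 1)) {
    m1 <- mean(x[1:k]); m2 <- mean(x[(k + 1):n])
    obj <- abs(m1 - m2)
    if (obj > best_obj) { best_obj <- obj; best_k <- k }
  }
  best_k
}
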