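# Sanger-style trace simulation: paired forward/reverse reads with per-base
# phred qualities and quality-dependent miscalls.

#' A trace read
#'
#' @param id read id.
#' @param orientation `"forward"` or `"reverse"`.
#' @param bases base string over `A,C,G,T,N`.
#' @param quals integer vector of per-base phred qualities, one per base.
#' @return A list of class `trace_read`.
#' @export
trace_read <- function(id, orientation = c("forward", "reverse"),
                       bases, quals) {
  orientation <- match.arg(orientation)
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals)) {
    stop("read ", id, ": bases (", nchar(bases), ") and qualities (",
         length(quals), ") differ in length")
  }
  if (any(quals < 0)) stop("read ", id, ": negative quality")
  structure(list(id = id, orientation = orientation, bases = bases,
                 quals = quals, failed = nchar(bases) == 0),
            class = "trace_read")
}

#' @export
print.trace_read <- function(x, ...) {
  cat(sprintf("<trace_read %s (%s), %d bp, median Q %s>\n", x$id,
              x$orientation, nchar(x$bases),
              if (length(x$quals)) stats::median(x$quals) else NA))
  invisible(x)
}

#' Configuration of the trace simulator
#'
#' The default quality profile emulates a Sanger trace: noisy first and last
#' `ramp` bases climbing from Q5 to the plateau quality, so end-trimming has
#' something to do.
#'
#' @param read_length maximum read length in bp.
#' @param read_overlap minimum forward/reverse overlap required to cover an
#'   amplicon from both ends.
#' @param plateau_q plateau phred quality.
#' @param end_q quality at the outermost base.
#' @param ramp number of ramp bases at each end.
#' @param quality_profile optional function `(n) -> integer vector` overriding
#'   the ramp profile entirely (used e.g. for uniform-quality calibration).
#' @return A list of class `trace_sim_config`.
#' @export
trace_sim_config <- function(read_length = 800, read_overlap = 50,
                             plateau_q = 40, end_q = 5, ramp = 20,
                             quality_profile = NULL) {
  stopifnot(read_length > 0, plateau_q >= 0, end_q >= 0, ramp >= 0)
  structure(list(read_length = as.integer(read_length),
                 read_overlap = as.integer(read_overlap),
                 plateau_q = plateau_q, end_q = end_q, ramp = ramp,
                 quality_profile = quality_profile),
            class = "trace_sim_config")
}

trace_quality_vector <- function(config, n) {
  if (!is.null(config$quality_profile)) {
    return(as.integer(config$quality_profile(n)))
  }
  i <- seq_len(n)
  r <- config$ramp
  q <- rep(config$plateau_q, n)
  if (r > 0) {
    up <- pmin(1, (i - 1) / r)
    down <- pmin(1, (n - i) / r)
    q <- config$end_q + (config$plateau_q - config$end_q) * pmin(up, down)
  }
  as.integer(round(q))
}

# Miscall bases independently with probability 10^(-Q/10); a miscall is a
# uniform draw over the three other bases.
inject_base_errors <- function(bases, quals) {
  v <- strsplit(bases, "")[[1]]
  perr <- 10^(-quals / 10)
  flip <- runif(length(v)) < perr
  if (any(flip)) {
    alts <- c("A", "C", "G", "T")
    v[flip] <- vapply(v[flip],
                      function(b) sample(setdiff(alts, b), 1), character(1))
  }
  paste(v, collapse = "")
}

#' Simulate a forward/reverse trace pair over one amplicon
#'
#' The forward read covers the amplicon from its 5' end and the reverse read
#' from its 3' end (stored reverse-complemented, as a sequencer would emit
#' it), each up to `read_length` bases with its own quality profile and
#' independent quality-dependent miscalls.
#'
#' @param truth_seq the (possibly mutant) amplicon sequence.
#' @param config a [trace_sim_config()].
#' @param seed integer seed.
#' @param id_prefix read id prefix.
#' @return List with `forward` and `reverse` [trace_read()]s.
#' @export
simulate_trace_pair <- function(truth_seq, config = trace_sim_config(),
                                seed = 1L, id_prefix = "amp") {
  n <- nchar(truth_seq)
  if (n == 0) {
    return(list(forward = trace_read(paste0(id_prefix, "_F"), "forward", "",
                                     integer(0)),
                reverse = trace_read(paste0(id_prefix, "_R"), "reverse", "",
                                     integer(0))))
  }
  rl <- min(n, config$read_length)
  if (2 * rl - n < config$read_overlap && rl < n) {
    stop("amplicon of ", n, " bp not reachable: reads of ", rl,
         " bp leave < ", config$read_overlap, " bp overlap")
  }
  with_seed(seed, {
    fwd_t <- substr(truth_seq, 1, rl)
    fq <- trace_quality_vector(config, rl)
    fwd <- trace_read(paste0(id_prefix, "_F"), "forward",
                      inject_base_errors(fwd_t, fq), fq)
    rev_t <- revcomp(substr(truth_seq, n - rl + 1, n))
    rq <- trace_quality_vector(config, rl)
    rev <- trace_read(paste0(id_prefix, "_R"), "reverse",
                      inject_base_errors(rev_t, rq), rq)
    list(forward = fwd, reverse = rev)
  })
}
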