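# Delta-Ct qPCR/qRT-PCR analysis: replicate aggregation, reference-gene
# stability screening, normalization and paired t-testing. The same code
# path serves expression (qRT-PCR, reference genes) and genomic copy number
# (qPCR, reference loci): the arithmetic is identical.

ct_value_cols <- function(ct_table) {
  grep("^ct[0-9]+$", names(ct_table), value = TRUE)
}

#' Aggregate technical replicates of one well
#'
#' @param replicates numeric vector of replicate Ct values (`NA` = missing).
#' @param sd_limit flag threshold on the replicate standard deviation.
#' @return List (`mean`, `sd`, `flag`): `flag` is `TRUE` when a replicate is
#'   missing or the spread exceeds `sd_limit`.
#' @export
aggregate_replicates <- function(replicates, sd_limit = 0.5) {
  ok <- !is.na(replicates)
  if (!any(ok)) stop("all replicates missing")
  m <- mean(replicates[ok])
  s <- if (sum(ok) > 1) sd(replicates[ok]) else 0
  list(mean = m, sd = s, flag = any(!ok) | s > sd_limit)
}

# Collapse a Ct table to one mean Ct per (pair, tissue, gene).
collapse_ct <- function(ct_table, sd_limit = 0.5) {
  cols <- ct_value_cols(ct_table)
  if (length(cols) == 0) stop("no ct1..ctk replicate columns found")
  agg <- lapply(seq_len(nrow(ct_table)), function(i) {
    aggregate_replicates(unlist(ct_table[i, cols]), sd_limit)
  })
  data.frame(pair_id = ct_table$pair_id, tissue = ct_table$tissue,
             gene = ct_table$gene,
             ct = vapply(agg, `[[`, numeric(1), "mean"),
             flag = vapply(agg, `[[`, logical(1), "flag"),
             stringsAsFactors = FALSE)
}

#' Paired t-test on a vector of paired differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom;
#' two-sided by default. All-identical differences give a degenerate
#' result (no p-value) rather than an infinite statistic.
#'
#' @param d numeric vector of per-pair differences.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List of class `paired_test_result`: `n`, `mean_diff`, `t`, `df`,
#'   `p`, `degenerate`.
#' @export
paired_t_test <- function(d, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  s <- sd(d)
  if (s == 0) {
    return(structure(list(n = n, mean_diff = mean(d), t = NA_real_,
                          df = n - 1, p = NA_real_, degenerate = TRUE,
                          alternative = alternative),
                     class = "paired_test_result"))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t_stat), df = n - 1),
              greater = pt(t_stat, df = n - 1, lower.tail = FALSE),
              less = pt(t_stat, df = n - 1))
  structure(list(n = n, mean_diff = mean(d), t = t_stat, df = n - 1, p = p,
                 degenerate = FALSE, alternative = alternative),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<paired t: n=%d, degenerate (zero variance)>\n", x$n))
  } else {
    cat(sprintf("<paired t: n=%d, mean diff %.3f, t=%.2f, df=%d, p=%.4g>\n",
                x$n, x$mean_diff, x$t, x$df, x$p))
  }
  invisible(x)
}

#' Screen candidate reference genes for stability
#'
#' A candidate is retained when its raw tumor-vs-normal paired Ct shift is
#' small (`|mean difference| <= threshold`) and not significant at `alpha`.
#' Degenerate (zero-variance) candidates are trivially stable.
#'
#' @param ct_table wide Ct table (`pair_id`, `tissue`, `gene`, `ct1`..).
#' @param candidates character vector of candidate reference genes.
#' @param threshold maximum tolerated |mean paired difference| in Ct units.
#' @param alpha significance level of the instability test.
#' @return List: `selected` (retained gene ids), `stats` (per-candidate
#'   data frame `gene`, `n`, `mean_diff`, `t`, `p`, `stable`).
#' @export
reference_stability <- function(ct_table, candidates, threshold = 0.5,
                                alpha = 0.05) {
  stopifnot(length(candidates) >= 1)
  cc <- collapse_ct(ct_table)
  stats_rows <- lapply(candidates, function(g) {
    d <- paired_differences(cc, g)
    res <- paired_t_test(d)
    stable <- abs(res$mean_diff) <= threshold &&
      (res$degenerate || res$p >= alpha)
    data.frame(gene = g, n = res$n, mean_diff = res$mean_diff,
               t = if (res$degenerate) NA_real_ else res$t,
               p = if (res$degenerate) NA_real_ else res$p,
               stable = stable, stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, stats_rows)
  selected <- stats$gene[stats$stable]
  if (length(selected) == 0) {
    stop("no stable reference gene among candidates (",
         paste(candidates, collapse = ", "),
         "); choose references manually")
  }
  list(selected = selected, stats = stats)
}

# tumor - normal per-pair difference of mean Ct for one gene
paired_differences <- function(collapsed, gene) {
  g <- collapsed[collapsed$gene == gene, , drop = FALSE]
  pairs <- intersect(g$pair_id[g$tissue == "tumor"],
                     g$pair_id[g$tissue == "normal"])
  vapply(pairs, function(p) {
    g$ct[g$pair_id == p & g$tissue == "tumor"] -
      g$ct[g$pair_id == p & g$tissue == "normal"]
  }, numeric(1))
}

#' Normalize target Ct values against a reference set
#'
#' Per sample (pair x tissue), `dCt = Ct_target - mean(Ct_references)`.
#' Samples missing any reference measurement are dropped with a warning;
#' with a single reference the mean reduces to plain subtraction.
#'
#' @param ct_table wide Ct table.
#' @param target target gene id.
#' @param references character vector of reference gene ids.
#' @return Data frame (`pair_id`, `tissue`, `dct`).
#' @export
normalize_ct <- function(ct_table, target, references) {
  stopifnot(length(references) >= 1)
  cc <- collapse_ct(ct_table)
  tgt <- cc[cc$gene == target, , drop = FALSE]
  out <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(tgt))) {
    sel <- cc$pair_id == tgt$pair_id[i] & cc$tissue == tgt$tissue[i] &
      cc$gene %in% references
    if (sum(sel) < length(references)) {
      dropped <- c(dropped, paste0(tgt$pair_id[i], "/", tgt$tissue[i]))
      next
    }
    out[[length(out) + 1]] <- data.frame(
      pair_id = tgt$pair_id[i], tissue = tgt$tissue[i],
      dct = tgt$ct[i] - mean(cc$ct[sel]), stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning("sample(s) missing a reference measurement, dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(out) == 0) {
    return(data.frame(pair_id = character(0), tissue = character(0),
                      dct = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call a gene altered or intact from its paired test
#'
#' Strictly `p < alpha` calls the gene altered. The default `alpha = 0.1`
#' treats borderline paired shifts (p just under 0.1) as alteration
#' evidence, which suits a small-cohort corroborating assay; tighten it
#' for confirmatory use.
#'
#' @param result a [paired_t_test()] result.
#' @param alpha significance level.
#' @return `"altered"` or `"intact"`.
#' @export
call_expression_alteration <- function(result, alpha = 0.1) {
  if (result$degenerate) stop("degenerate test result: no p-value")
  if (result$p < alpha) "altered" else "intact"
}

#' Full delta-Ct analysis over a panel of target genes
#'
#' For each target: normalize against the reference set, form per-pair
#' tumor-minus-normal dCt differences, run the paired t-test, and call
#' alteration at `alpha` on the raw p-value (Benjamini-Hochberg adjusted
#' p-values are reported alongside; set `use_adjusted = TRUE` to call on
#' them instead).
#'
#' @param ct_table wide Ct table.
#' @param targets character vector of target genes.
#' @param references character vector of reference genes.
#' @param alpha significance level for the alteration call.
#' @param alternative test sidedness (see [paired_t_test()]).
#' @param use_adjusted call on BH-adjusted p-values.
#' @return Data frame (`gene`, `n`, `mean_diff`, `t`, `df`, `p`, `p_adj`,
#'   `call`).
#' @export
delta_ct_analysis <- function(ct_table, targets, references, alpha = 0.1,
                              alternative = "two.sided",
                              use_adjusted = FALSE) {
  rows <- lapply(targets, function(g) {
    norm <- normalize_ct(ct_table, g, references)
    wide <- merge(norm[norm$tissue == "tumor", c("pair_id", "dct")],
                  norm[norm$tissue == "normal", c("pair_id", "dct")],
                  by = "pair_id", suffixes = c("_t", "_n"))
    res <- paired_t_test(wide$dct_t - wide$dct_n, alternative = alternative)
    data.frame(gene = g, n = res$n, mean_diff = res$mean_diff,
               t = if (res$degenerate) NA_real_ else res$t, df = res$df,
               p = if (res$degenerate) NA_real_ else res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  crit <- if (use_adjusted) out$p_adj else out$p
  out$call <- ifelse(is.na(crit), "degenerate",
                     ifelse(crit < alpha, "altered", "intact"))
  out
}
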