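# Fusing per-species alteration evidence with synteny context into
# driver / passenger / unresolved calls.
#
# The working logic: an abnormality recurrent across species is likely a
# driver; an abnormality confined to one species, sitting next to an
# altered driver in that species' genome while the same gene is far from
# every altered driver (and intact) in another species, is likely
# collateral damage - a passenger.

#' Sequence-alteration status of a gene in one cohort
#'
#' One-sided binomial test of the observed truncating prevalence against
#' the background truncating rate: the gene is `altered` when
#' `P(X >= k | n, beta0)` falls below `alpha_b`, `intact` otherwise, and
#' `unknown` when untested (`n = 0` or `tested = FALSE`).
#'
#' @param k tumors carrying a truncating alteration.
#' @param n tumors assayed.
#' @param beta0 background truncating probability per tumor.
#' @param alpha_b significance level.
#' @param tested set `FALSE` for genes not assayed in this cohort.
#' @return List: `status` (`"altered"`/`"intact"`/`"unknown"`), `k`, `n`,
#'   `p` (`NA` when unknown).
#' @export
alteration_status <- function(k, n, beta0 = 0.01, alpha_b = 0.01,
                              tested = TRUE) {
  if (!tested || n == 0) {
    return(list(status = "unknown", k = NA_integer_, n = as.integer(n),
                p = NA_real_))
  }
  stopifnot(k >= 0, k <= n)
  p <- stats::binom.test(k, n, beta0, alternative = "greater")$p.value
  list(status = if (p < alpha_b) "altered" else "intact",
       k = as.integer(k), n = as.integer(n), p = p)
}

#' Per-species evidence bundle for one gene
#'
#' @param gene gene id.
#' @param species named list; each element a list with `sequence`,
#'   `expression`, `copy_number` statuses (each
#'   `"altered"`/`"intact"`/`"unknown"`) and optional `k`, `n` truncating
#'   prevalence.
#' @return A list of class `gene_evidence`.
#' @export
gene_evidence <- function(gene, species) {
  ok <- c("altered", "intact", "unknown")
  for (sp in names(species)) {
    e <- species[[sp]]
    for (ch in c("sequence", "expression", "copy_number")) {
      v <- e[[ch]] %||% "unknown"
      if (!v %in% ok) stop("invalid status '", v, "' for ", sp, "/", ch)
      species[[sp]][[ch]] <- v
    }
    if (!is.null(e$k) && !is.null(e$n) && e$n > 0 && e$k > e$n) {
      stop("prevalence k > n for ", sp)
    }
  }
  structure(list(gene = gene, species = species), class = "gene_evidence")
}

#' Synteny context for one gene
#'
#' @param gene gene id.
#' @param distances named numeric vector: per species, distance in bp to
#'   the nearest altered known-driver locus (`Inf` = unlinked or none).
#' @param instability optional region-instability verdict.
#' @return A list of class `synteny_context`.
#' @export
synteny_context <- function(gene, distances, instability = NA) {
  stopifnot(all(distances >= 0))
  structure(list(gene = gene, distances = distances,
                 instability = instability),
            class = "synteny_context")
}

species_altered <- function(ev_sp) {
  any(unlist(ev_sp[c("sequence", "expression", "copy_number")]) == "altered")
}

species_intact <- function(ev_sp) {
  ch <- unlist(ev_sp[c("sequence", "expression", "copy_number")])
  !any(ch == "altered") && any(ch == "intact")
}

#' Integrate evidence and context into a driver/passenger call
#'
#' Decision rules, applied in order (exactly one fires):
#' \enumerate{
#'   \item altered (any evidence channel) in two or more species ->
#'     `driver_candidate`;
#'   \item altered in exactly one species, within `d_near` of an altered
#'     driver in that species, and intact in at least one species where the
#'     gene is at least `d_far` from every altered driver ->
#'     `passenger_candidate`;
#'   \item otherwise `unresolved`.
#' }
#'
#' @param evidence a [gene_evidence()].
#' @param context a [synteny_context()] with distances for the same species.
#' @param d_near proximity radius for collateral mutagenesis (default 1 Mb).
#' @param d_far distance beyond which a gene counts as isolated from every
#'   altered driver (default 5 Mb).
#' @return List of class `driver_call`: `gene`, `verdict`, `rule`,
#'   `rationale`.
#' @export
integrate_gene_call <- function(evidence, context, d_near = 1e6,
                                d_far = 5e6) {
  sp <- names(evidence$species)
  if (length(sp) < 2) {
    stop("cross-species classification needs evidence for >= 2 species (got ",
         length(sp), ")")
  }
  altered <- vapply(evidence$species, species_altered, logical(1))
  intact <- vapply(evidence$species, species_intact, logical(1))
  dist <- context$distances[sp]
  mk <- function(verdict, rule, rationale) {
    structure(list(gene = evidence$gene, verdict = verdict, rule = rule,
                   rationale = rationale, d_near = d_near, d_far = d_far),
              class = "driver_call")
  }
  if (sum(altered) >= 2) {
    return(mk("driver_candidate", 1L,
              sprintf("rule 1: altered in %d species (%s); recurrence across species marks a driver candidate",
                      sum(altered), paste(sp[altered], collapse = ", "))))
  }
  if (sum(altered) == 1) {
    s_alt <- sp[altered]
    near <- !is.na(dist[s_alt]) && dist[s_alt] <= d_near
    far_ok <- sp[intact & (is.na(dist) | dist >= d_far)]
    if (near && length(far_ok) > 0) {
      return(mk("passenger_candidate", 2L,
                sprintf("rule 2: altered only in %s at %s bp from an altered driver (<= d_near=%g), intact in %s at >= d_far=%g bp from every altered driver; pattern of collateral proximity damage",
                        s_alt, format(dist[s_alt], big.mark = ","), d_near,
                        paste(far_ok, collapse = ", "), d_far)))
    }
  }
  mk("unresolved", 3L,
     sprintf("rule 3: alteration pattern (%s) matches neither cross-species recurrence nor the proximity-passenger configuration",
             paste(sprintf("%s=%s", sp,
                           ifelse(altered, "altered",
                                  ifelse(intact, "intact", "unknown"))),
                   collapse = ", ")))
}

#' @export
print.driver_call <- function(x, ...) {
  cat(sprintf("<%s: %s (%s)>\n", x$gene, x$verdict, x$rationale))
  invisible(x)
}
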