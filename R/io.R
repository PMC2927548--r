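# Shared readers and writers. All in-memory coordinates are 1-based
# inclusive; BED files on disk are 0-based half-open, and the conversion
# lives here and nowhere else.

#' Read paired FASTA + QUAL files into trace reads
#'
#' The QUAL file carries space-separated integer phred scores per record
#' (the classic phred dialect). Records must correspond one-to-one by id
#' and agree in length.
#'
#' @param fasta_path,qual_path file paths.
#' @return List of [trace_read()]s.
#' @export
read_fasta_qual <- function(fasta_path, qual_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  quals <- parse_qual_file(qual_path)
  ids <- names(seqs)
  if (!identical(sort(ids), sort(names(quals)))) {
    stop("FASTA/QUAL id mismatch: ",
         paste(union(setdiff(ids, names(quals)),
                     setdiff(names(quals), ids)), collapse = ", "))
  }
  lapply(ids, function(id) {
    b <- as.character(seqs[[id]])
    q <- quals[[id]]
    if (nchar(b) != length(q)) {
      stop("record ", id, ": sequence length ", nchar(b),
           " != quality length ", length(q))
    }
    orientation <- if (grepl("_R$", id)) "reverse" else "forward"
    trace_read(id, orientation, b, q)
  })
}

parse_qual_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no records in QUAL file ", path)
  ends <- c(hdr[-1] - 1, length(lines))
  out <- list()
  for (i in seq_along(hdr)) {
    id <- sub("^>\\s*", "", lines[hdr[i]])
    id <- sub("\\s.*$", "", id)
    body <- lines[seq(hdr[i] + 1, ends[i])]
    body <- body[nzchar(body)]
    vals <- if (length(body)) {
      as.integer(unlist(strsplit(paste(body, collapse = " "), "\\s+")))
    } else {
      integer(0)
    }
    vals <- vals[!is.na(vals)]
    out[[id]] <- vals
  }
  out
}

#' Write trace reads as paired FASTA + QUAL files
#'
#' @param reads list of [trace_read()]s.
#' @param fasta_path,qual_path output paths.
#' @return Invisibly, the fasta path.
#' @export
write_fasta_qual <- function(reads, fasta_path, qual_path) {
  fa <- character(0)
  qu <- character(0)
  for (r in reads) {
    fa <- c(fa, paste0(">", r$id), r$bases)
    qu <- c(qu, paste0(">", r$id), paste(r$quals, collapse = " "))
  }
  writeLines(fa, fasta_path)
  writeLines(qu, qual_path)
  invisible(fasta_path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path 3+ column BED file (0-based half-open on disk).
#' @return Data frame (`chrom`, `start`, `end`, and `name`, `score`,
#'   `strand` when present), converted to 1-based inclusive coordinates.
#' @export
read_bed <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs >= 3 columns: ", path)
  names(tab)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  for (i in seq_len(min(ncol(tab) - 3, 3))) {
    names(tab)[3 + i] <- extra[i]
  }
  if (any(tab$start > tab$end)) stop("BED interval with start > end in ", path)
  tab$start <- tab$start + 1   # 0-based half-open -> 1-based inclusive
  tab
}

#' Write 1-based inclusive intervals as BED
#'
#' @param intervals data frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_bed <- function(intervals, path) {
  out <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1,   # back to 0-based
                    end = intervals$end)
  for (col in c("name", "score", "strand")) {
    if (col %in% names(intervals)) out[[col]] <- intervals[[col]]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an ortholog table (TSV, 1-based inclusive)
#'
#' @param path TSV with columns `gene`, `genome`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return Validated ortholog map data frame.
#' @export
read_ortholog_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_ortholog_map(tab)
}

#' @rdname read_ortholog_table
#' @param map ortholog map to write.
#' @export
write_ortholog_table <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide Ct table (TSV)
#'
#' @param path TSV with columns `pair_id`, `tissue`, `gene`, `ct1`..`ctk`.
#' @return Data frame.
#' @export
read_ct_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "tissue", "gene")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("Ct table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (length(ct_value_cols(tab)) == 0) stop("Ct table has no ct1..ctk columns")
  tab
}

#' Read an aCGH probe profile (TSV: chrom, pos, log2ratio)
#'
#' @param path TSV path.
#' @return Data frame (`chrom`, `pos`, `log2ratio`).
#' @export
read_cgh_profile <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "log2ratio")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("profile lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab
}

#' @rdname read_cgh_profile
#' @param profile profile data frame to write.
#' @export
write_cgh_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a region string "chrom:start-end"
#'
#' @param spec region string, 1-based inclusive, commas allowed in numbers.
#' @return List (`chrom`, `start`, `end`).
#' @export
parse_region <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", spec))[[1]]
  if (length(m) != 4) stop("malformed region spec '", spec,
                           "'; expected chrom:start-end")
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (start > end) stop("region start exceeds end in '", spec, "'")
  list(chrom = m[2], start = start, end = end)
}

#' Round-trippable run configuration
#'
#' @param config a [pipeline_config()] (or plain named list of stage
#'   parameters).
#' @param path YAML path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   returns a [pipeline_config()].
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$proximity <- unclass(x$proximity)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  prox <- x$proximity %||% list()
  x$proximity <- do.call(proximity_model_config, prox)
  do.call(pipeline_config, x)
}
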