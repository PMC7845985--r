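# Assembly bookkeeping: contig filtering by length/GC, longest-isoform
# deduplication, N50-style assembly metrics and library read statistics.

#' Parse Trinity-style contig identifiers
#'
#' Identifiers have the form \code{c<contig>_g<gene>_i<isoform>}.
#'
#' @param ids character vector of identifiers.
#' @return data.frame with integer columns contig, gene, isoform.
#' @export
parse_contig_id <- function(ids) {
  m <- regmatches(ids, regexec("^c([0-9]+)_g([0-9]+)_i([0-9]+)$", ids))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("unparseable contig id(s): ", paste(ids[bad], collapse = ", "))
  mm <- do.call(rbind, m)
  data.frame(contig = as.integer(mm[, 2]), gene = as.integer(mm[, 3]),
             isoform = as.integer(mm[, 4]))
}

#' Build a contig-record table from sequences
#'
#' Computes per-contig length and GC content. GC is computed over unambiguous
#' bases only: (G + C) / (A + C + G + T), so ambiguity codes inflate neither
#' the numerator nor the denominator.
#'
#' @param seqs a \code{Biostrings::DNAStringSet} with Trinity-style names, or
#'   a named character vector of sequences.
#' @return data.frame: id, length, gc.
#' @export
contig_records <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0,
               rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt, NA_real_)
  data.frame(id = names(seqs), length = Biostrings::width(seqs), gc = gc,
             stringsAsFactors = FALSE)
}

#' Filter contigs on length and GC content
#'
#' Keeps records with \code{length >= min_len} and
#' \code{gc_min <= gc <= gc_max}; all bounds inclusive, input order
#' preserved. The assembly-level filter uses 300 nt and 18-58 percent GC; the
#' reference-transcriptome selection applies a second pass at 27 percent
#' minimum GC.
#'
#' @param records data.frame with columns length and gc (proportions).
#' @param min_len minimum length in nt (default 300).
#' @param gc_min,gc_max inclusive GC bounds as proportions (defaults 0.18,
#'   0.58).
#' @return the retained rows of \code{records}.
#' @export
filter_contigs <- function(records, min_len = 300, gc_min = 0.18,
                           gc_max = 0.58) {
  if (!(gc_min >= 0 && gc_min <= gc_max && gc_max <= 1))
    stop("require 0 <= gc_min <= gc_max <= 1")
  keep <- records$length >= min_len &
    records$gc >= gc_min & records$gc <= gc_max
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Keep the longest isoform of each contig/gene pair
#'
#' One record per (contig, gene): the longest isoform, ties broken by the
#' lowest isoform index. Output ordered by (contig, gene).
#'
#' @param records data.frame with columns id and length; ids must parse as
#'   Trinity-style identifiers.
#' @return the retained rows.
#' @export
dedup_isoforms <- function(records) {
  if (nrow(records) == 0) return(records)
  parsed <- parse_contig_id(records$id)
  ord <- order(parsed$contig, parsed$gene, -records$length, parsed$isoform)
  key <- paste(parsed$contig[ord], parsed$gene[ord], sep = "_")
  records[ord[!duplicated(key)], , drop = FALSE]
}

#' Assembly metrics (N50, mean/min/max length, transcript count)
#'
#' N50 is the largest contig length L such that contigs of length >= L
#' together contain at least half of the total assembly length.
#'
#' @param lengths non-empty vector of positive contig lengths (nt).
#' @return list: n50, mean_length, min_length, max_length, total_transcripts.
#' @export
assembly_metrics <- function(lengths) {
  if (length(lengths) == 0) stop("lengths must be non-empty")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(as.numeric(s))
  n50 <- s[which(csum >= sum(as.numeric(s)) / 2)[1]]
  list(n50 = n50, mean_length = mean(lengths), min_length = min(lengths),
       max_length = max(lengths), total_transcripts = length(lengths))
}

# round half away from zero (printed-table convention; base round() is
# round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-library read statistics
#'
#' Retention percentage (filtered/raw) and mapping percentage
#' (mapped/filtered), each rounded half-up to two decimals to match printed
#' library tables.
#'
#' @param raw,filtered,mapped read counts with
#'   \code{0 <= mapped <= filtered <= raw}, raw > 0.
#' @return list: raw_reads, filtered_reads, mapped_reads, pct_filtered,
#'   pct_mapped.
#' @export
library_stats <- function(raw, filtered, mapped) {
  if (!(raw > 0 && filtered >= 0 && mapped >= 0))
    stop("read counts must be non-negative and raw > 0")
  if (!(mapped <= filtered && filtered <= raw))
    stop("require mapped <= filtered <= raw")
  list(raw_reads = raw, filtered_reads = filtered, mapped_reads = mapped,
       pct_filtered = round_half_up(100 * filtered / raw),
       pct_mapped = if (filtered > 0)
         round_half_up(100 * mapped / filtered) else NA_real_)
}

#' Write a FASTA file (60-character wrapped)
#'
#' @param seqs a \code{Biostrings::DNAStringSet}.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a DNAStringSet
#'
#' @param path FASTA path.
#' @return a \code{Biostrings::DNAStringSet}.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)
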