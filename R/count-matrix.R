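#' Validate a raw count matrix
#'
#' A count matrix is an integer-valued matrix with genes in rows and
#' sequencing libraries in columns. Row names are gene identifiers and column
#' names are library identifiers (in the four-library drought design these are
#' \code{SW}, \code{SD}, \code{TW}, \code{TD}: Susceptible/Tolerant genotype
#' crossed with Watered/Droughted treatment).
#'
#' @param counts matrix of non-negative integer counts with gene row names and
#'   library column names.
#' @return the validated matrix, invisibly coerced to storage mode double
#'   (counts stay integral in value).
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes x libraries)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and library column names")
  if (anyDuplicated(colnames(counts)))
    stop("library ids must be unique")
  if (anyDuplicated(rownames(counts)))
    stop("gene ids must be unique")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  counts
}

#' Library metadata from SW/SD/TW/TD-style identifiers
#'
#' Decodes library ids of the form \code{<genotype><treatment>} where genotype
#' is \code{S} (susceptible) or \code{T} (tolerant) and treatment is \code{W}
#' (watered) or \code{D} (droughted, i.e. water-deficit stressed).
#'
#' @param library_ids character vector of library identifiers.
#' @return data.frame with columns \code{library_id}, \code{genotype},
#'   \code{treatment}.
#' @export
library_metadata <- function(library_ids) {
  ok <- grepl("^[ST][WD]$", library_ids)
  if (!all(ok))
    stop("cannot decode library id(s): ",
         paste(library_ids[!ok], collapse = ", "))
  data.frame(
    library_id = library_ids,
    genotype   = substr(library_ids, 1, 1),
    treatment  = substr(library_ids, 2, 2),
    stringsAsFactors = FALSE
  )
}

#' Read a count matrix from TSV
#'
#' Expects a header line whose first column is \code{gene_id} followed by one
#' column per library.
#'
#' @param path path to a tab-separated file.
#' @return validated count matrix.
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "gene_id")
    stop("first column of a counts TSV must be 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  validate_count_matrix(m)
}

#' Write a count matrix to TSV
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @export
write_count_tsv <- function(counts, path) {
  counts <- validate_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
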