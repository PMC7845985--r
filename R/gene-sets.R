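# Expressed-gene sets, Venn partitions across the four libraries,
# discordant-regulation screening and top-TF selection.

#' Per-library expressed-gene sets
#'
#' A gene counts as expressed ("detected") in a library when its raw count is
#' at least \code{min_reads} (default 1 read, i.e. at least one gene tag).
#'
#' @param counts validated count matrix.
#' @param min_reads detection threshold (default 1).
#' @return list with \code{sets} (named list of gene-id vectors per library),
#'   \code{universe} (all gene ids), \code{in_all} (genes expressed in every
#'   library) and \code{exclusive} (named list: genes expressed only in that
#'   library).
#' @export
expressed_sets <- function(counts, min_reads = 1) {
  counts <- validate_count_matrix(counts)
  detected <- counts >= min_reads
  sets <- lapply(colnames(counts), function(l)
    rownames(counts)[detected[, l]])
  names(sets) <- colnames(counts)
  n_libs <- rowSums(detected)
  exclusive <- lapply(colnames(counts), function(l)
    rownames(counts)[detected[, l] & n_libs == 1])
  names(exclusive) <- colnames(counts)
  list(sets = sets, universe = rownames(counts),
       in_all = rownames(counts)[n_libs == ncol(counts)],
       exclusive = exclusive)
}

#' Venn partition of 2-4 labelled gene sets
#'
#' Counts genes exclusive to every non-empty subset of the labels (the
#' disjoint regions of the Venn diagram). Region names are the member labels
#' joined by \code{&}; the counts sum to the size of the union.
#'
#' @param sets named list of 2-4 character vectors (gene ids).
#' @return named integer vector of region counts, one per non-empty label
#'   subset.
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2 || length(sets) > 4)
    stop("venn_partition needs 2-4 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(names(sets) == ""))
    stop("sets must carry unique non-empty labels")
  labels <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  sig <- apply(member, 1, function(row)
    paste(labels[row], collapse = "&"))
  subsets <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(labels, k, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(subsets)), subsets)
  tab <- table(sig)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Screen for discordantly regulated genes across two contrasts
#'
#' Returns genes called up in the first contrast but down in the second —
#' the pattern used to flag transcription factors induced by drought in the
#' tolerant genotype (TD vs TW) yet repressed in the susceptible one
#' (SD vs SW).
#'
#' @param up_contrast,down_contrast DE result data.frames (from
#'   \code{\link{run_de}}) over the same gene universe.
#' @param annotations optional annotation data.frame (gene_id, description,
#'   tf_family, ...) to join onto the result.
#' @return data.frame of discordant genes with the fold changes and q-values
#'   of both contrasts.
#' @export
discordant_screen <- function(up_contrast, down_contrast,
                              annotations = NULL) {
  if (!setequal(up_contrast$gene_id, down_contrast$gene_id))
    stop("the two contrasts must share the same gene universe")
  down_contrast <- down_contrast[match(up_contrast$gene_id,
                                       down_contrast$gene_id), ]
  hit <- up_contrast$status == "up" & down_contrast$status == "down"
  out <- data.frame(
    gene_id = up_contrast$gene_id[hit],
    fc_up_contrast = up_contrast$fc[hit],
    q_up_contrast = up_contrast$q[hit],
    fc_down_contrast = down_contrast$fc[hit],
    q_down_contrast = down_contrast$q[hit],
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations))
    out <- merge(out, annotations, by = "gene_id", all.x = TRUE,
                 sort = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Select the top differentially expressed transcription factors
#'
#' From one contrast's DE table, keeps TF-annotated genes with fold change
#' strictly above the threshold and q-value below the FDR cut-off, ranked by
#' fold change descending (ties broken by gene id). Used for the
#' highly-expressed-TF shortlist in the droughted tolerant-vs-susceptible
#' comparison (TD vs SD).
#'
#' @param de_table DE result data.frame from \code{\link{run_de}}.
#' @param annotations data.frame with columns gene_id and tf_family (NA for
#'   non-TF genes).
#' @param fc_threshold strict lower bound on fold change (default 1.5).
#' @param fdr_threshold upper bound on q (default 0.001).
#' @return list with \code{genes} (ranked data.frame: gene_id, tf_family, fc,
#'   q) and \code{family_counts} (named integer vector over the 13 families).
#' @export
select_top_tf <- function(de_table, annotations, fc_threshold = 1.5,
                          fdr_threshold = 0.001) {
  ann <- annotations[match(de_table$gene_id, annotations$gene_id), ]
  keep <- !is.na(ann$tf_family) & !is.na(de_table$fc) &
    de_table$fc > fc_threshold & de_table$q < fdr_threshold
  genes <- data.frame(gene_id = de_table$gene_id[keep],
                      tf_family = ann$tf_family[keep],
                      fc = de_table$fc[keep], q = de_table$q[keep],
                      stringsAsFactors = FALSE)
  genes <- genes[order(-genes$fc, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  fam <- stats::setNames(integer(length(TF_FAMILIES)), TF_FAMILIES)
  tab <- table(genes$tf_family)
  fam[names(tab)] <- as.integer(tab)
  list(genes = genes, family_counts = fam)
}
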