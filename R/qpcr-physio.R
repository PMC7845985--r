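# qPCR relative expression (2^-ddCt), RNA-seq vs qPCR concordance,
# electrolyte leakage and Tukey letter groups for treatment comparisons.

#' Relative expression by the 2^-ddCt method
#'
#' Per row, dCt = Ct(target) - Ct(reference gene). Per cell
#' (gene x genotype x day) the replicate-mean dCt is taken; ddCt subtracts
#' the same gene's calibrator-cell mean dCt, and REL = 2^(-ddCt). The
#' calibrator is, by default, the same-genotype day-0 (well-watered) cell, so
#' both genotypes start near REL = 1; a fixed-genotype calibrator can be
#' requested instead.
#'
#' @param plate data.frame with columns gene, genotype, day, replicate,
#'   ct_target, ct_reference.
#' @param calibrator_day calibrator day (default 0).
#' @param calibrator_genotype NULL for same-genotype calibration (default),
#'   or a single genotype label used as calibrator for all rows.
#' @return data.frame per gene x genotype x day: mean_dct, sd_dct, ddct, rel,
#'   n_replicates.
#' @export
ddct_rel <- function(plate, calibrator_day = 0, calibrator_genotype = NULL) {
  need <- c("gene", "genotype", "day", "replicate", "ct_target",
            "ct_reference")
  if (!all(need %in% names(plate)))
    stop("plate must have columns: ", paste(need, collapse = ", "))
  if (any(plate$ct_target <= 0) || any(plate$ct_reference <= 0))
    stop("Ct values must be positive")
  plate$dct <- plate$ct_target - plate$ct_reference
  agg <- stats::aggregate(dct ~ gene + genotype + day, plate,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  cells <- data.frame(gene = agg$gene, genotype = agg$genotype,
                      day = agg$day, mean_dct = agg$dct[, "mean"],
                      sd_dct = agg$dct[, "sd"],
                      n_replicates = agg$dct[, "n"],
                      stringsAsFactors = FALSE)
  cal_geno <- if (is.null(calibrator_genotype)) cells$genotype
              else rep(calibrator_genotype, nrow(cells))
  cal_key <- paste(cells$gene, cal_geno, calibrator_day)
  cell_key <- paste(cells$gene, cells$genotype, cells$day)
  idx <- match(cal_key, cell_key)
  if (anyNA(idx)) {
    missing <- unique(cells$gene[is.na(idx)])
    stop("missing calibrator cell for gene(s): ",
         paste(missing, collapse = ", "))
  }
  cells$ddct <- cells$mean_dct - cells$mean_dct[idx]
  cells$rel <- 2^(-cells$ddct)
  cells[order(cells$gene, cells$genotype, cells$day), , drop = FALSE]
}

#' Concordance between RNA-seq TPM and qPCR relative expression
#'
#' Joins per-gene/condition log2(TPM + 1) values with qPCR REL and reports,
#' per gene, the Spearman rank correlation across conditions and the
#' fraction of conditions where both platforms agree on the direction of
#' change relative to the day-0 baseline of the same genotype.
#'
#' @param tpm_by_condition data.frame: gene, genotype, day, tpm.
#' @param rel_by_condition data.frame: gene, genotype, day, rel (e.g. from
#'   \code{\link{ddct_rel}}).
#' @return list with \code{per_gene} (data.frame: gene, spearman,
#'   direction_agreement, n_conditions) and overall \code{spearman} /
#'   \code{direction_agreement} summaries.
#' @export
compare_tpm_rel <- function(tpm_by_condition, rel_by_condition) {
  merged <- merge(tpm_by_condition, rel_by_condition,
                  by = c("gene", "genotype", "day"))
  if (nrow(merged) == 0) stop("no overlapping gene x condition keys")
  merged$log_tpm <- log2(merged$tpm + 1)
  base_key <- paste(merged$gene, merged$genotype, 0)
  idx <- match(base_key, paste(merged$gene, merged$genotype, merged$day))
  merged$dir_tpm <- sign(merged$log_tpm - merged$log_tpm[idx])
  merged$dir_rel <- sign(merged$rel - merged$rel[idx])
  per_gene <- do.call(rbind, lapply(split(merged, merged$gene), function(d) {
    nonbase <- d$day != 0 & !is.na(d$dir_tpm)
    data.frame(
      gene = d$gene[1],
      spearman = if (nrow(d) > 1)
        stats::cor(d$log_tpm, d$rel, method = "spearman") else NA_real_,
      direction_agreement = if (any(nonbase))
        mean(d$dir_tpm[nonbase] == d$dir_rel[nonbase]) else NA_real_,
      n_conditions = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       spearman = mean(per_gene$spearman, na.rm = TRUE),
       direction_agreement = mean(per_gene$direction_agreement,
                                  na.rm = TRUE))
}

#' Electrolyte leakage percentage
#'
#' EL = 100 * C1 / C2, where C1 is the initial conductivity of leaf-disk
#' bathing solution and C2 the conductivity after autoclaving (total
#' electrolytes). Scale-invariant in the conductivity units. C1 exceeding C2
#' is physically impossible for a valid sample and is flagged with a warning
#' rather than silently accepted.
#'
#' @param c1 initial conductivity (> 0 expected, same units as c2).
#' @param c2 post-autoclave conductivity (> 0).
#' @return leakage percentage(s), in [0, 100] for valid samples.
#' @export
electrolyte_leakage <- function(c1, c2) {
  if (any(c2 <= 0)) stop("post-autoclave conductivity c2 must be positive")
  if (any(c1 < 0)) stop("conductivity c1 must be non-negative")
  if (any(c1 > c2))
    warning("c1 > c2 for ", sum(c1 > c2),
            " sample(s): leakage above 100% flags a measurement anomaly")
  100 * c1 / c2
}

#' Tukey HSD letter groups for treatment means
#'
#' One-way ANOVA followed by Tukey honest-significant-difference all-pairs
#' comparison at level alpha; groups that are not significantly different
#' share a letter. Letters are assigned by the greedy compact-letter-display
#' convention starting from the group with the largest mean.
#'
#' @param values numeric measurements.
#' @param groups group labels (>= 2 groups, >= 2 values each).
#' @param alpha significance level (default 0.05).
#' @return list with \code{letters} (named character vector, ordered by
#'   decreasing group mean), \code{means}, and \code{tukey} (the TukeyHSD
#'   p-value table).
#' @export
tukey_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ g, data = data.frame(values = values,
                                                  g = factor(groups)))
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  gnames <- names(means)
  # significance lookup from the all-pairs table
  sig_between <- function(a, b) {
    key <- c(paste(a, b, sep = "-"), paste(b, a, sep = "-"))
    p <- hsd[rownames(hsd) %in% key, "p adj"]
    length(p) > 0 && p[1] < alpha
  }
  # greedy compact letter display: from each group (means descending) grow
  # the maximal run of mutually non-distinct groups; keep runs not already
  # contained in an earlier letter
  k <- length(gnames)
  membership <- matrix(FALSE, k, 0, dimnames = list(gnames, NULL))
  for (i in seq_len(k)) {
    block <- i
    j <- i + 1
    while (j <= k && all(vapply(block, function(b)
      !sig_between(gnames[b], gnames[j]), logical(1)))) {
      block <- c(block, j)
      j <- j + 1
    }
    contained <- ncol(membership) > 0 && any(apply(
      membership, 2, function(col) all(col[block])))
    if (!contained) {
      newcol <- rep(FALSE, k)
      newcol[block] <- TRUE
      membership <- cbind(membership, newcol)
    }
  }
  letters_out <- apply(membership, 1, function(row)
    paste(letters[which(row)], collapse = ""))
  list(letters = letters_out, means = means,
       tukey = hsd)
}
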