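# Synthetic-data generator for the 2-genotype x 2-watering drought design:
# count matrices with planted DE ground truth, Trinity-style transcript FASTA,
# qPCR Ct plates that invert exactly under 2^-ddCt, and conductivity tables.

#' The four libraries of the drought design
#' @export
DESIGN_LIBRARIES <- c("SW", "SD", "TW", "TD")

#' The four contrasts of the drought design (each read as second vs first)
#' @export
DESIGN_CONTRASTS <- list(
  SD_vs_SW = c("SW", "SD"),
  TD_vs_TW = c("TW", "TD"),
  TW_vs_SW = c("SW", "TW"),
  TD_vs_SD = c("SD", "TD")
)

#' Simulation configuration
#'
#' Defaults emulate the four-library papaya drought experiment: a ~29,070-gene
#' reference transcriptome quantified in four unreplicated libraries with
#' mapped-read totals of order 10^6 reads each. Baseline abundances are
#' log-normal; \code{baseline_log_mean} defaults to
#' \code{log(mean(library_sizes)/n_genes) - baseline_log_sd^2/2} so that the
#' expected library totals equal the configured sizes. DE genes are planted
#' per contrast with fold changes drawn cyclically from \code{fc_grid} after a
#' seeded shuffle, so the truth composition is reproducible. Dispersion 0
#' gives pure Poisson counts (the model the bootstrap assumes); positive
#' values give negative-binomial counts for overdispersion robustness checks.
#'
#' @param n_genes number of genes (> 0).
#' @param library_sizes named vector of expected total reads per library.
#' @param de_fraction proportion of genes planted as DE, in [0, 1].
#' @param fc_grid positive true fold changes assignable to planted DE genes.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline parameters.
#' @param dispersion negative-binomial overdispersion (0 = Poisson).
#' @param tf_fraction proportion of genes receiving a TF-family annotation.
#' @param seed integer seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 29070L,
                       library_sizes = c(SW = 4464197, SD = 4607117,
                                         TW = 5443440, TD = 5583379),
                       de_fraction = 0.10,
                       fc_grid = c(0.25, 0.5, 2, 4),
                       baseline_log_mean = NULL,
                       baseline_log_sd = 1.2,
                       dispersion = 0,
                       tf_fraction = 0.01,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L) stop("n_genes must be a positive integer")
  if (is.null(names(library_sizes)) || anyDuplicated(names(library_sizes)))
    stop("library_sizes must be uniquely named")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
  if (any(fc_grid <= 0)) stop("fc_grid must be positive")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (tf_fraction < 0 || tf_fraction > 1) stop("tf_fraction must be in [0, 1]")
  if (baseline_log_sd < 0) stop("baseline_log_sd must be non-negative")
  if (is.null(baseline_log_mean))
    baseline_log_mean <- log(mean(library_sizes) / n_genes) -
      baseline_log_sd^2 / 2
  structure(list(
    n_genes = n_genes, library_sizes = library_sizes,
    de_fraction = de_fraction, fc_grid = fc_grid,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion = dispersion, tf_fraction = tf_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' The 13 drought-associated transcription-factor families
#' @export
TF_FAMILIES <- c("DREB", "bZIP", "HSF", "MYC", "MYB", "NAC", "AP2",
                 "NFY", "ERF", "WRKY", "C2H2", "bHLH", "ERD")

# Trinity-style gene ids c<contig>_g1_i<isoform>; the count matrix carries the
# representative (longest) isoform id of each gene.
synth_gene_ids <- function(n) sprintf("c%d_g1_i1", seq_len(n))

#' Generate a count matrix with planted ground truth
#'
#' Every gene receives a log-normal baseline abundance (expected count at the
#' mean library size). Planted DE genes are assigned, cyclically, to one of
#' the four design contrasts and to a fold change from \code{fc_grid}: the
#' multiplier is applied to the second (numerator) library of that contrast,
#' so the true fold change table records the multiplier ratio for every
#' contrast (a gene planted in one contrast can induce a secondary, equally
#' real, fold change in another contrast sharing a library). Counts are then
#' Poisson (or negative-binomial for dispersion > 0) around
#' baseline x size-factor x multiplier.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{counts} (validated matrix) and \code{truth}
#'   (data.frame: gene_id, baseline, tf_family, and per contrast
#'   \code{fc_<name>} and \code{de_<name>} columns).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  libs <- names(config$library_sizes)
  gene_id <- synth_gene_ids(n)

  baseline <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  size_factor <- config$library_sizes / mean(config$library_sizes)

  # deterministic planted-DE bookkeeping: seeded shuffle, then cycle through
  # contrasts and the fold-change grid
  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  mult <- matrix(1, n, length(libs), dimnames = list(gene_id, libs))
  contrasts <- DESIGN_CONTRASTS[vapply(DESIGN_CONTRASTS, function(ct)
    all(ct %in% libs), logical(1))]
  if (n_de > 0 && length(contrasts) > 0) {
    ct_cycle <- rep_len(seq_along(contrasts), n_de)
    fc_cycle <- rep_len(config$fc_grid, n_de)
    for (j in seq_len(n_de)) {
      target_lib <- contrasts[[ct_cycle[j]]][2]
      mult[de_idx[j], target_lib] <- fc_cycle[j]
    }
  }

  mu <- baseline * mult %*% diag(size_factor, length(libs))
  colnames(mu) <- libs
  counts <- if (config$dispersion == 0)
    matrix(stats::rpois(length(mu), mu), n, length(libs))
  else
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           n, length(libs))
  dimnames(counts) <- list(gene_id, libs)

  tf_family <- rep(NA_character_, n)
  n_tf <- round(config$tf_fraction * n)
  if (n_tf > 0) {
    tf_idx <- sample.int(n, n_tf)
    tf_family[tf_idx] <- rep_len(TF_FAMILIES, n_tf)
  }

  truth <- data.frame(gene_id = gene_id, baseline = baseline,
                      tf_family = tf_family, stringsAsFactors = FALSE)
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    fc_true <- mult[, ct[2]] / mult[, ct[1]]
    truth[[paste0("fc_", nm)]] <- unname(fc_true)
    truth[[paste0("de_", nm)]] <- unname(fc_true != 1)
  }
  list(counts = validate_count_matrix(counts), truth = truth)
}

# Random DNA of given length and GC proportion (expected; A/T and G/C split
# evenly within their class).
random_dna <- function(len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a Trinity-style transcript FASTA
#'
#' Emits contigs named \code{c<contig>_g<gene>_i<isoform>} with lengths
#' spanning both sides of the 300-nt filter and GC contents spanning the
#' 18/27/58 percent thresholds; a subset of genes carries 2-3 isoforms of
#' unequal length so longest-isoform deduplication is exercised.
#'
#' @param config a \code{sim_config}; \code{n_contigs} contigs are generated.
#' @param n_contigs number of distinct (contig, gene) pairs (default 60).
#' @return a \code{Biostrings::DNAStringSet} with Trinity-style names.
#' @export
generate_transcript_fasta <- function(config, n_contigs = 60L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 7L)
  lens <- sample(c(150:299, 300:2500), n_contigs, replace = TRUE)
  gcs <- stats::runif(n_contigs, 0.10, 0.70)
  ids <- character(0); seqs <- character(0)
  for (i in seq_len(n_contigs)) {
    n_iso <- if (i %% 5 == 0) sample(2:3, 1) else 1L
    iso_lens <- unique(lens[i] + c(0L, sample(50:400, n_iso)))[seq_len(n_iso)]
    for (j in seq_len(n_iso)) {
      ids <- c(ids, sprintf("c%d_g1_i%d", i, j))
      seqs <- c(seqs, random_dna(iso_lens[j], gcs[i]))
    }
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  x
}

#' Generate a qPCR plate from an intended relative-expression profile
#'
#' Builds Ct values such that exact 2^-ddCt recomputation (reference-gene
#' normalisation, same-genotype day-0 calibrator) recovers the intended REL,
#' up to optional additive Gaussian Ct noise. The reference-gene Ct is held
#' at a constant plateau per genotype; the target Ct encodes the profile as
#' \code{ct_target = ct_reference + dct0 - log2(rel)} with a gene-specific
#' day-0 offset \code{dct0}.
#'
#' @param config a \code{sim_config} (used for the seed).
#' @param rel_profile data.frame with columns gene, genotype, day, rel
#'   (rel > 0). Day 0 rows are the calibrator cells; if absent for a
#'   gene x genotype they are added with rel = 1.
#' @param n_replicates technical/biological replicates per cell (default 3).
#' @param noise_sd additive Gaussian Ct noise standard deviation (0 allowed).
#' @return data.frame: gene, genotype, day, replicate, ct_target,
#'   ct_reference.
#' @export
generate_qpcr <- function(config, rel_profile = default_rel_profile(),
                          n_replicates = 3L, noise_sd = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (any(rel_profile$rel <= 0)) stop("rel_profile values must be positive")
  set.seed(config$seed + 13L)
  # ensure a day-0 calibrator cell for every gene x genotype
  key <- unique(rel_profile[, c("gene", "genotype")])
  have0 <- rel_profile$day == 0
  need <- !paste(key$gene, key$genotype) %in%
    paste(rel_profile$gene[have0], rel_profile$genotype[have0])
  if (any(need)) {
    rel_profile <- rbind(rel_profile,
      data.frame(gene = key$gene[need], genotype = key$genotype[need],
                 day = 0, rel = 1))
  }
  genes <- unique(rel_profile$gene)
  dct0 <- stats::setNames(stats::runif(length(genes), 2, 8), genes)
  ct_ref_base <- 20
  rows <- rel_profile[rep(seq_len(nrow(rel_profile)), each = n_replicates), ]
  rows$replicate <- rep(seq_len(n_replicates), nrow(rel_profile))
  rows$ct_reference <- ct_ref_base +
    stats::rnorm(nrow(rows), 0, noise_sd)
  rows$ct_target <- rows$ct_reference + dct0[rows$gene] -
    log2(rows$rel) + stats::rnorm(nrow(rows), 0, noise_sd)
  rownames(rows) <- NULL
  rows[, c("gene", "genotype", "day", "replicate", "ct_target",
           "ct_reference")]
}

#' Default intended REL profile for the six drought-marker genes
#'
#' Six transcription-factor targets (heat-shock factor, MYB, NAC, NF-YA, ERF
#' and WRKY markers) in two genotypes (S susceptible, T tolerant) across days
#' 0/3/7/14 of water withholding. Day-14 endpoints use the study's reported
#' tolerant/susceptible REL pairs (39/14, 39/28, 33/19, 11/7, 21/8, 47/11)
#' with geometric interpolation at days 3 and 7.
#'
#' @return data.frame with columns gene, genotype, day, rel.
#' @export
default_rel_profile <- function() {
  end <- rbind(
    data.frame(gene = "CpHSF",   T = 39, S = 14),
    data.frame(gene = "CpMYB",   T = 39, S = 28),
    data.frame(gene = "CpNAC",   T = 33, S = 19),
    data.frame(gene = "CpNFY-A", T = 11, S = 7),
    data.frame(gene = "CpERF",   T = 21, S = 8),
    data.frame(gene = "CpWRKY",  T = 47, S = 11)
  )
  days <- c(0, 3, 7, 14)
  out <- do.call(rbind, lapply(seq_len(nrow(end)), function(i) {
    do.call(rbind, lapply(c("S", "T"), function(g) {
      data.frame(gene = end$gene[i], genotype = g, day = days,
                 rel = end[[g]][i]^(days / 14), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a conductivity table for electrolyte-leakage computation
#'
#' Samples per genotype x day with initial conductivity c1 and post-autoclave
#' conductivity c2 such that 100*c1/c2 tracks a leakage profile typical of
#' drought stress: below 25 percent while watered, rising to ~32 percent in
#' the tolerant and above 40 percent in the susceptible genotype by day 14.
#'
#' @param config a \code{sim_config} (used for the seed).
#' @param n_replicates samples per genotype x day (default 5).
#' @param noise_sd Gaussian noise on the leakage percentage (default 1.5).
#' @return data.frame: sample, genotype, day, c1, c2.
#' @export
generate_conductivity <- function(config, n_replicates = 5L, noise_sd = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 29L)
  grid <- expand.grid(genotype = c("S", "T"), day = c(0, 3, 7, 14),
                      stringsAsFactors = FALSE)
  el_target <- function(g, d) {
    if (d == 0) 18
    else if (g == "T") 18 + (32 - 18) * d / 14
    else 18 + (44 - 18) * d / 14
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    el <- vapply(seq_len(n_replicates), function(r)
      max(1, el_target(grid$genotype[i], grid$day[i]) +
            stats::rnorm(1, 0, noise_sd)), numeric(1))
    c2 <- stats::runif(n_replicates, 80, 120)
    data.frame(
      sample = sprintf("%s_d%d_r%d", grid$genotype[i], grid$day[i],
                       seq_len(n_replicates)),
      genotype = grid$genotype[i], day = grid$day[i],
      c1 = el * c2 / 100, c2 = c2, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Generate a gene annotation table with TF-family keyword descriptions
#'
#' Genes flagged with a TF family in the truth table receive a free-text
#' description containing that family's keyword (mimicking BLAST-derived
#' functional annotations); the rest receive generic housekeeping
#' descriptions. Transcript lengths are drawn uniformly in 300-3000 nt.
#'
#' @param truth truth data.frame from \code{generate_counts}.
#' @param seed integer seed.
#' @return data.frame: gene_id, description, length.
#' @export
generate_annotations <- function(truth, seed = 1L) {
  set.seed(as.integer(seed) + 31L)
  phrases <- c(
    DREB = "dehydration responsive element binding protein %d",
    bZIP = "bZIP transcription factor %d",
    HSF  = "heat shock factor protein %d",
    MYC  = "N-MYC downregulated-like %d",
    MYB  = "myb domain protein %d",
    NAC  = "NAC domain containing protein %d",
    AP2  = "related to AP2.%d transcriptional factor",
    NFY  = "nuclear factor Y subunit A-%d",
    ERF  = "ethylene response factor %d",
    WRKY = "WRKY DNA-binding protein %d",
    C2H2 = "C2H2-type zinc finger family protein %d",
    bHLH = "basic helix-loop-helix (bHLH) protein %d",
    ERD  = "ERD (early response to dehydration) %d"
  )
  generic <- c("40S ribosomal protein S%d", "ATP synthase subunit %d",
               "photosystem II protein D%d", "ubiquitin-conjugating enzyme %d",
               "aquaporin PIP%d", "unknown protein %d")
  n <- nrow(truth)
  desc <- character(n)
  is_tf <- !is.na(truth$tf_family)
  desc[is_tf] <- sprintf(phrases[truth$tf_family[is_tf]],
                         seq_len(sum(is_tf)))
  desc[!is_tf] <- sprintf(sample(generic, sum(!is_tf), replace = TRUE),
                          seq_len(sum(!is_tf)))
  data.frame(gene_id = truth$gene_id, description = desc,
             length = sample(300:3000, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
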