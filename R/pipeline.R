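# End-to-end orchestration: simulate -> assembly metrics -> bootstrap DE on
# the four contrasts -> expressed sets / Venn -> TF mining -> discordant and
# top-TF screens -> qPCR concordance. One master seed drives simulation and
# bootstrap through derived streams; all tabular outputs are TSV.

#' Pipeline configuration
#'
#' Bundles the simulation settings, bootstrap settings, thresholds and
#' contrast definitions of a full run.
#'
#' @param sim a \code{\link{sim_config}}.
#' @param contrasts named list of 2-vectors \code{c(a, b)} (default the four
#'   design contrasts).
#' @param B bootstrap replicates (default 100).
#' @param fdr_threshold,fc_up,fc_down DE-call thresholds.
#' @param min_len,gc_min,gc_max contig filter thresholds.
#' @param min_reads expressed-set detection threshold.
#' @param seed master seed for the run (simulation and bootstrap use derived
#'   streams).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(),
                            contrasts = DESIGN_CONTRASTS,
                            B = 100L, fdr_threshold = 0.001,
                            fc_up = 1.5, fc_down = 0.5,
                            min_len = 300, gc_min = 0.18, gc_max = 0.58,
                            min_reads = 1, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  for (ct in contrasts) {
    if (length(ct) != 2L || !all(ct %in% names(sim$library_sizes)))
      stop("every contrast must name two configured libraries")
  }
  structure(list(sim = sim, contrasts = contrasts, B = as.integer(B),
                 fdr_threshold = fdr_threshold, fc_up = fc_up,
                 fc_down = fc_down, min_len = min_len, gc_min = gc_min,
                 gc_max = gc_max, min_reads = min_reads,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(df, path, version_comment = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (version_comment)
    writeLines(sprintf("# papayaDE %s",
                       as.character(utils::packageVersion("papayaDE"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates the four-library experiment (or uses supplied counts), computes
#' assembly and library statistics, runs the Poisson-bootstrap DE analysis on
#' every configured contrast, derives expressed-gene sets and Venn regions,
#' mines TF families, screens for discordant regulation (up in TD vs TW, down
#' in SD vs SW), selects the top TF in TD vs SD, and checks qPCR/TPM
#' concordance. With an output directory, every stage's table is written as
#' TSV together with a manifest of seeds and stage status; identical config
#' and seed give byte-identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir optional output directory for TSVs and the manifest.
#' @param counts optional pre-existing count matrix (skips simulation of
#'   counts but keeps the simulated annotation/FASTA stages).
#' @return invisible list: counts, truth, annotations, assembly (metrics
#'   before/after filtering + dedup), de (list of DE tables), sets, venn
#'   (expressed and DE region counts), tf (family counts), discordant,
#'   top_tf, qpcr (REL table and concordance), deg_counts, manifest.
#' @export
run_pipeline <- function(config, outdir = NULL, counts = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, B = config$B,
                   version = as.character(utils::packageVersion("papayaDE")),
                   stages = character(0))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  sim <- config$sim
  sim$seed <- config$seed
  gen <- stage("simulate", generate_counts(sim))
  if (!is.null(counts)) gen$counts <- validate_count_matrix(counts)
  annotations <- stage("annotate",
                       annotate_tf(generate_annotations(gen$truth,
                                                        seed = config$seed)))

  fasta <- stage("fasta", generate_transcript_fasta(sim))
  recs <- contig_records(fasta)
  filtered <- filter_contigs(recs, config$min_len, config$gc_min,
                             config$gc_max)
  deduped <- dedup_isoforms(filtered)
  assembly <- stage("seqstats", list(
    raw = assembly_metrics(recs$length),
    filtered = assembly_metrics(filtered$length),
    reference = if (nrow(deduped))
      assembly_metrics(deduped$length) else NULL,
    n_raw = nrow(recs), n_filtered = nrow(filtered),
    n_reference = nrow(deduped)))

  de <- stage("de", {
    out <- lapply(names(config$contrasts), function(nm)
      run_de(gen$counts, config$contrasts[[nm]], B = config$B,
             seed = config$seed + match(nm, names(config$contrasts)),
             fdr_threshold = config$fdr_threshold,
             fc_up = config$fc_up, fc_down = config$fc_down))
    names(out) <- names(config$contrasts)
    out
  })
  deg_counts <- vapply(de, function(d)
    sum(d$status %in% c("up", "down")), integer(1))

  sets <- stage("sets", expressed_sets(gen$counts, config$min_reads))
  venn <- stage("venn", {
    expressed <- venn_partition(sets$sets)
    de_sets <- lapply(de, function(d)
      d$gene_id[d$status %in% c("up", "down")])
    de_regions <- if (sum(lengths(de_sets) > 0) >= 2)
      venn_partition(de_sets[lengths(de_sets) > 0]) else NULL
    list(expressed = expressed, de = de_regions)
  })

  tf <- stage("tfmine", family_counts(annotations))
  discordant <- stage("screen", {
    if (all(c("TD_vs_TW", "SD_vs_SW") %in% names(de)))
      discordant_screen(de$TD_vs_TW, de$SD_vs_SW, annotations)
    else NULL
  })
  top_tf <- stage("toptf", {
    if ("TD_vs_SD" %in% names(de))
      select_top_tf(de$TD_vs_SD, annotations,
                    fdr_threshold = config$fdr_threshold)
    else NULL
  })

  qpcr <- stage("qpcr", {
    plate <- generate_qpcr(sim, noise_sd = 0.1)
    rel <- ddct_rel(plate)
    profile <- default_rel_profile()
    names(profile)[names(profile) == "rel"] <- "tpm"  # proxy abundance
    conc <- compare_tpm_rel(profile, rel[, c("gene", "genotype", "day",
                                             "rel")])
    list(rel = rel, concordance = conc)
  })
  physio <- stage("physio", {
    cond <- generate_conductivity(sim)
    cond$el <- electrolyte_leakage(cond$c1, cond$c2)
    cond
  })

  result <- list(counts = gen$counts, truth = gen$truth,
                 annotations = annotations, assembly = assembly, de = de,
                 deg_counts = deg_counts, sets = sets, venn = venn, tf = tf,
                 discordant = discordant, top_tf = top_tf, qpcr = qpcr,
                 physio = physio, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_count_tsv(gen$counts, file.path(outdir, "counts.tsv"))
    write_tsv(gen$truth, file.path(outdir, "truth.tsv"))
    write_tsv(annotations, file.path(outdir, "annotations.tsv"))
    for (nm in names(de))
      write_tsv(de[[nm]], file.path(outdir, sprintf("de_%s.tsv", nm)))
    write_tsv(data.frame(region = names(venn$expressed),
                         n = unname(venn$expressed)),
              file.path(outdir, "venn_expressed.tsv"))
    if (!is.null(discordant))
      write_tsv(discordant, file.path(outdir, "discordant.tsv"))
    if (!is.null(top_tf))
      write_tsv(top_tf$genes, file.path(outdir, "top_tf.tsv"))
    write_tsv(qpcr$rel, file.path(outdir, "qpcr_rel.tsv"))
    write_tsv(physio, file.path(outdir, "conductivity_el.tsv"))
    summary_df <- data.frame(
      contrast = names(deg_counts),
      n_deg = unname(deg_counts),
      n_up = vapply(de, function(d) sum(d$status == "up"), integer(1)),
      n_down = vapply(de, function(d) sum(d$status == "down"), integer(1)))
    write_tsv(summary_df, file.path(outdir, "deg_summary.tsv"))
    manifest_df <- data.frame(
      key = c("seed", "B", "version", "stages", "complete"),
      value = c(manifest$seed, manifest$B, manifest$version,
                paste(manifest$stages, collapse = ","), "true"))
    write_tsv(manifest_df, file.path(outdir, "manifest.tsv"),
              version_comment = FALSE)
  }
  invisible(result)
}
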