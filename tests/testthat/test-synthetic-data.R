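# Synthetic-data generator: reproducibility, planted truth bookkeeping,
# FASTA contract, qPCR round-trip and conductivity tables.

test_that("sim_config validates its fields", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(library_sizes = c(SW = 0, SD = 1e6)), "positive")
  expect_error(small_config(de_fraction = 1.2), "\\[0, 1\\]")
  expect_error(small_config(dispersion = -1), "non-negative")
  expect_error(small_config(fc_grid = c(2, -1)), "positive")
})

test_that("count generation is seed-reproducible with aligned truth", {
  cfg <- small_config()
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(rownames(a$counts), a$truth$gene_id)
})

test_that("planted DE bookkeeping is deterministic rounding of de_fraction", {
  cfg <- small_config(n_genes = 2000L, de_fraction = 0.1,
                      library_sizes = c(SW = 1e5, SD = 1e5,
                                        TW = 1e5, TD = 1e5))
  truth <- generate_counts(cfg)$truth
  de_any <- Reduce(`|`, truth[grep("^de_", names(truth))])
  expect_equal(sum(de_any), 200)
  # non-DE genes have true fold change exactly 1 in every contrast
  fc_cols <- truth[grep("^fc_", names(truth))]
  expect_true(all(fc_cols[!de_any, ] == 1))
  # null config flags nothing
  truth0 <- generate_counts(small_config(de_fraction = 0))$truth
  expect_true(all(!unlist(truth0[grep("^de_", names(truth0))])))
})

test_that("non-DE gene means converge to their baseline (Poisson, equal sizes)", {
  cfg <- small_config(n_genes = 50L, de_fraction = 0, dispersion = 0)
  # equal library sizes -> size factors 1, so E[count] = baseline; the
  # standardized Poisson residuals (count - baseline)/sqrt(baseline) across
  # many simulated matrices average to 0 within 3 standard errors
  resid <- unlist(lapply(1:40, function(s) {
    cfg$seed <- s
    sim <- generate_counts(cfg)
    sweep(sweep(sim$counts, 1, sim$truth$baseline, "-"),
          1, sqrt(sim$truth$baseline), "/")
  }))
  expect_lt(abs(mean(resid)), 3 / sqrt(length(resid)))
})

test_that("transcript FASTA honours the Trinity naming and GC contract", {
  cfg <- small_config()
  fa <- generate_transcript_fasta(cfg, n_contigs = 40)
  expect_true(all(grepl("^c[0-9]+_g[0-9]+_i[0-9]+$", names(fa))))
  recs <- contig_records(fa)
  # lengths and GC span the filtering thresholds
  expect_true(any(recs$length < 300) && any(recs$length >= 300))
  expect_true(any(recs$gc < 0.18) || any(recs$gc < 0.27))
  expect_true(any(recs$gc > 0.27 & recs$gc < 0.58))
  # at least one gene has >= 2 isoforms of unequal length
  parsed <- parse_contig_id(recs$id)
  key <- paste(parsed$contig, parsed$gene)
  multi <- names(which(table(key) >= 2))
  expect_gt(length(multi), 0)
  lens <- recs$length[key == multi[1]]
  expect_gt(length(unique(lens)), 1)
  # GC equals an independent character-level recomputation
  seqs <- as.character(fa)
  gc_hand <- vapply(strsplit(seqs, ""), function(ch) {
    acgt <- ch %in% c("A", "C", "G", "T")
    sum(ch %in% c("G", "C")) / sum(acgt)
  }, numeric(1))
  expect_equal(unname(recs$gc), unname(gc_hand))
})

test_that("qPCR plates invert exactly under 2^-ddCt when noise-free", {
  cfg <- small_config()
  profile <- default_rel_profile()
  plate <- generate_qpcr(cfg, profile, n_replicates = 2, noise_sd = 0)
  rel <- ddct_rel(plate)
  merged <- merge(profile, rel, by = c("gene", "genotype", "day"))
  expect_equal(merged$rel.y, merged$rel.x, tolerance = 1e-12)
  # intended REL = 1 everywhere -> all ddCt are 0
  flat <- profile
  flat$rel <- 1
  rel_flat <- ddct_rel(generate_qpcr(cfg, flat, noise_sd = 0))
  expect_equal(rel_flat$ddct, rep(0, nrow(rel_flat)))
  # a single REL = 2 cell is recovered exactly
  one <- data.frame(gene = "gX", genotype = "T", day = c(0, 7),
                    rel = c(1, 2))
  rel_one <- ddct_rel(generate_qpcr(cfg, one, noise_sd = 0))
  expect_equal(rel_one$rel[rel_one$day == 7], 2)
  expect_error(generate_qpcr(cfg, data.frame(gene = "g", genotype = "T",
                                             day = 0, rel = -1)),
               "positive")
})

test_that("noisy qPCR plates recover intended REL within propagated noise", {
  cfg <- small_config()
  profile <- data.frame(gene = "gN", genotype = "T", day = c(0, 14),
                        rel = c(1, 4))
  sd_ct <- 0.1
  n_rep <- 3
  rels <- vapply(1:40, function(s) {
    cfg$seed <- s
    rel <- ddct_rel(generate_qpcr(cfg, profile, n_replicates = n_rep,
                                  noise_sd = sd_ct))
    rel$rel[rel$day == 14]
  }, numeric(1))
  # ddCt noise sd = sd_ct * 2 / sqrt(n_rep) (two Ct's per row, mean of
  # n_rep rows, difference of two cells); log2 REL is ddCt-linear
  sd_ddct <- sd_ct * sqrt(2) * sqrt(2) / sqrt(n_rep)
  expect_lt(abs(mean(log2(rels)) - 2), 3 * sd_ddct / sqrt(length(rels)))
})

test_that("conductivity tables satisfy the c1 <= c2 biological invariant", {
  cond <- generate_conductivity(small_config())
  expect_true(all(cond$c1 > 0) && all(cond$c2 > 0))
  expect_true(all(cond$c1 <= cond$c2))
  el <- electrolyte_leakage(cond$c1, cond$c2)
  expect_true(all(el >= 0 & el <= 100))
  # droughted susceptible leaks more than droughted tolerant by day 14
  d14 <- cond$day == 14
  expect_gt(mean(el[d14 & cond$genotype == "S"]),
            mean(el[d14 & cond$genotype == "T"]))
})
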