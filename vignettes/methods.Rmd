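---
title: "Methods: bootstrap differential expression without replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bootstrap differential expression without replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papayaDE)
```

## The statistical model

papayaDE targets the weakest possible RNA-seq design: one library per
condition. The four-library drought layout (`SW`, `SD`, `TW`, `TD`:
susceptible/tolerant genotype crossed with watered/droughted treatment)
admits four pairwise contrasts — SD vs SW, TD vs TW, TW vs SW, TD vs SD —
none of which has replication, so no dispersion parameter is estimable.

The package's answer is a parametric bootstrap under a Poisson measurement
model. Writing $x_{gl}$ for the observed count of gene $g$ in library $l$:

1. **Pseudo-replication.** Each of $B$ replicates draws a full pseudo-matrix
   $x^*_{gl} \sim \mathrm{Poisson}(x_{gl})$, independently per entry. The
   observed count is the Poisson mean, so an observed zero stays zero:
   absent genes can never acquire bootstrap evidence. Library sizes are
   recomputed from the pseudo-matrix (totals are random, not held fixed),
   matching the entry-wise definition of the resampler.
2. **Per-replicate test.** Within a replicate, a gene is tested between the
   contrast libraries $a$ and $b$ by the conditional binomial exact test:
   given $t = x^*_a + x^*_b$, under $H_0$ of equal relative abundance
   $x^*_a \sim \mathrm{Binomial}(t,\, n_a/(n_a+n_b))$. The two-sided p-value
   follows the method of small probabilities — the sum over all outcomes
   $k \in [0, t]$ whose point probability does not exceed the observed
   one's. $t = 0$ gives $p = 1$. This is the dispersion $\to 0$ limit of the
   negative-binomial exact test for two libraries; the alternative
   convention (doubling the smaller tail) was deliberately not used, and the
   full package behaviour is pinned against a brute-force enumerator.
3. **Aggregation.** The per-gene p-value is the median across the $B$
   replicates; for even $B$ the mean of the two central order statistics.
4. **FDR and calls.** Median p-values are converted per contrast (not pooled
   across contrasts) to Benjamini–Hochberg q-values. With
   $FC = \mathrm{CPM}_b/\mathrm{CPM}_a$, a gene is *up* when $FC > 1.5$
   (strict) and $q < 0.001$, *down* when $FC \le 0.5$ (inclusive) and
   $q < 0.001$; a gene unobserved in both libraries has undefined FC and is
   *undetermined*.

### Assumptions and what the procedure is not

The Poisson assumption ignores biological overdispersion — with one library
per condition there is nothing to estimate it from. The bootstrap therefore
quantifies only counting (shot) noise around the observed values;
between-replicate biological variability is invisible to it, and q-values
should be read as statements about measurement noise, not about population
effects. The generator's `dispersion` knob exists precisely to probe how
hard this assumption bites (negative-binomial counts at user-set
overdispersion), and the test suite exercises it.

## Numerical and design choices

* **Exact-test evaluation.** The inclusion set of the small-probabilities
  rule is a union of two tails (the binomial pmf is unimodal), so the far
  tail cutoff is located by binary search and summed with `pbinom`:
  $O(\log t)$ density evaluations per gene instead of $O(t)$, which is what
  makes $B = 100$ over tens of thousands of genes cheap. Density ties are
  compared with relative tolerance $10^{-10}$; the frozen tie rule is part
  of the definition and shared with the enumerator oracle.
* **Seeding.** One master seed; replicate $r$ uses the $r$-th element of a
  pre-drawn seed stream, so enlarging $B$ extends the stream without
  reshuffling earlier replicates, and pipeline reruns are byte-identical.
* **Fold-change conventions.** $FC$ of "B vs A" is $\mathrm{CPM}_B /
  \mathrm{CPM}_A$; numerator-only zeros give $FC = 0$ (how discordant
  tables report fully silenced genes), denominator-only zeros give
  $FC = \infty$ (still "up" if significant).
* **Contig filtering** applies two stages with inclusive bounds: length
  $\ge 300$ nt with GC in $[18\%, 58\%]$ at the assembly stage, then GC
  $\ge 27\%$ at reference-transcriptome selection; both thresholds appear in
  assembly practice without a single reconciled rule, so the pipeline keeps
  them as successive passes. GC is computed over unambiguous A/C/G/T only,
  so N-runs inflate neither numerator nor denominator. Isoform
  deduplication keeps the longest isoform per (contig, gene), ties broken by
  the lowest isoform index.
* **Percentages** in library tables are rounded half-up to two decimals —
  base `round()`'s round-half-even would not reproduce printed tables.
* **TF mining** is keyword classification of free-text functional
  annotations into the 13 drought-associated families (DREB, bZIP, HSF,
  MYC, MYB, NAC, AP2, NFY, ERF, WRKY, C2H2, bHLH, ERD), first match wins,
  with specific patterns ordered before generic ones (DREB before AP2;
  "N-MYC downregulated" counts as MYC because description-driven mining
  follows the annotation text, not TF canon; bare "zinc finger" falls back
  to C2H2). Zinc-finger subtype ambiguity is inherent to text mining and
  is flagged as a known limitation rather than guessed around.
* **qPCR.** $\Delta Ct = Ct_{target} - Ct_{reference}$ per well,
  replicate-mean per cell, $\Delta\Delta Ct$ against the same-genotype
  day-0 cell, $REL = 2^{-\Delta\Delta Ct}$. The same-genotype day-0
  calibrator makes both genotypes start near $REL = 1$, which is how
  timecourse validation panels are usually normalised; a fixed-genotype
  calibrator is available as an argument. Using replicate-mean
  $\Delta Ct$ (not per-replicate pairing) is the standard convention.
* **Tukey letters.** One-way ANOVA, `TukeyHSD` all-pairs comparison, then a
  greedy compact-letter display grown from the largest mean: from each
  group the maximal run of mutually non-distinct groups becomes a letter
  unless already contained in one. For the interval-structured significance
  patterns Tukey comparisons produce on ordered means this reproduces the
  usual figure annotations.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults are the study conditions of the four-library
drought design: 29,070 genes (the reference-transcriptome size), library
sizes equal to the four mapped-read totals (4.46M/4.61M/5.44M/5.58M),
log-normal baseline abundances with $\sigma_{\log} = 1.2$ (a typical
bulk-RNA-seq spread), and `baseline_log_mean` auto-calibrated to
$\log(\bar N / n_{genes}) - \sigma^2/2$ so expected library totals equal the
configured sizes. Planted DE genes (default fraction 0.10, a realistic
planted load for recovery benchmarking; fold-change grid
$\{0.25, 0.5, 2, 4\}$) are assigned cyclically to contrasts and fold
changes after a seeded shuffle, so the truth table is reproducible and
deterministic in composition: `de_fraction` of 0.1 over 2,000 genes plants
exactly 200. The multiplier acts on the numerator library of the assigned
contrast, which also induces genuine secondary fold changes in other
contrasts sharing that library — the truth table records all of them.

The generator emulates counting noise, library-size imbalance, optional
overdispersion, TF-annotation structure (default `tf_fraction` 0.01,
matching a few-hundred-TF yield on a ~29k transcriptome), Trinity-style
`c<contig>_g<gene>_i<isoform>` FASTA with lengths and GC spanning the
filter thresholds, noise-free-invertible qPCR plates, and leakage-profiled
conductivity tables. It does **not** emulate read-level artefacts
(sequencing error, mapping ambiguity, positional bias), gene–gene
correlation, compositional coupling between planted genes (size factors are
multiplicative, not multinomial thinning), or isoform-level expression.
Green tests on synthetic data therefore demonstrate the correctness and
calibration of the computations under the stated model — not robustness to
everything real libraries contain.

## Problem sizes used in validation

The shipped checks run the bootstrap core at 2,000 genes × 4 libraries of
10⁶ expected reads with $B = 100$: 20 null simulations (no planted genes,
Poisson) for the false-positive fraction at $q < 0.001$, and one planted
run (10% DE at fold change 4) for directional recovery among genes with
baseline mean ≥ 50 counts, evaluated over all four contrasts. Exact-test
equivalence against full enumeration is checked for every conditional total
$t \le 200$. Unit tests use 300–400-gene configurations. These sizes were
chosen as the smallest at which the statistical properties are
well-resolved; the generator scales to the full 29,070-gene default
unchanged.

## Known limitations

* Median-p aggregation has no finite-sample calibration guarantee; the null
  simulations show it behaves conservatively under the Poisson model, which
  is the regime the method assumes.
* Overdispersed data (generator `dispersion` > 0) inflate the false-positive
  fraction — the known cost of a Poisson model on biological replicates-free
  data.
* A negative-binomial per-replicate test at user-fixed dispersion
  (`test = "nb"`) is available for sensitivity studies, but no dispersion
  estimation (TMM, tagwise shrinkage) is attempted: that requires
  replication by definition. The per-replicate test is a pluggable
  strategy, since the original procedure's exact per-replicate test is
  underdetermined for a two-library design.
* Venn semantics for "DE only in library X" depend on which DE sets are
  intersected; the package reports the full region partition and leaves
  interpretation to the analyst.
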