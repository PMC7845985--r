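Package: papayaDE
Title: Replicate-Free RNA-Seq Differential Expression by Poisson Parametric Bootstrap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis for unreplicated RNA-seq designs
    by Poisson parametric bootstrap: pseudo-replicates are drawn per gene and
    library with the observed count as the Poisson mean, a conditional binomial
    exact test is run per pseudo-replicate, and the per-gene median p-value is
    converted to Benjamini-Hochberg q-values. Built around a 2-genotype x
    2-watering drought-stress design (four libraries SW/SD/TW/TD), the package
    also provides de novo assembly bookkeeping (contig filtering by length and
    GC content, longest-isoform deduplication, N50 and library statistics),
    expressed-gene set and Venn partitions, keyword mining of drought-associated
    transcription-factor families, discordant-regulation screens, qPCR
    2^-delta-delta-Ct relative expression with Tukey letter groups, electrolyte
    leakage, and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
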