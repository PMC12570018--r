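Package: icemethylome
Title: Community Methylome Analysis for Nanopore Modified-Base Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bacterial and viral DNA methylation in
    environmental (e.g. sea-ice brine) metagenomes from per-nucleotide
    modified-base pileups (bedMethyl). Provides strand-aware IUPAC motif
    scanning, per-motif methylation profiling with coverage filtering and
    low/medium/high categorisation, de novo motif discovery by k-mer
    enrichment with greedy IUPAC generalisation, differential methylation
    between two sample groups (Kolmogorov-Smirnov with Benjamini-Hochberg
    control, plus per-instance two-proportion tests), restriction-modification
    gene accounting with orphan-methyltransferase detection and a surplus
    Z statistic, prophage-versus-host motif-density comparison and
    methylation-profile host matching, GC-skew replication origin/terminus
    localisation with polynomial methylation-trend fitting, and a seeded
    synthetic-data generator producing complete input bundles with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
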