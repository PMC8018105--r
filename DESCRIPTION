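Package: epirelapse
Title: Paired Primary-Relapse Methylation Array Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired primary and relapse tumor DNA methylation
    profiles from 450K-style arrays: beta/M-value conversion, per-probe
    paired differential methylation with optional empirical-Bayes variance
    moderation, methylation-status comparison across CpG-island epigenomic
    substructures (islands, shores, shelves), decomposition of significant
    probes into hypo- and hypermethylated fractions, intensity-based
    copy-number log-ratio comparison, and unpaired t-tests for
    histomorphology scores. Includes a seeded generator of paired
    primary/relapse array datasets with planted substructure-specific
    methylation effects and chromosome-arm copy-number events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
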