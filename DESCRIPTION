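Package: codonfam
Title: Codon Usage Bias and Gene-Family Expansion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for molecular-evolution analyses of plant gene families:
    coding-sequence screening, codon usage bias statistics (RSCU, effective
    number of codons, codon adaptation index, codon bias index, Fop,
    third-position base composition), ENC-plot analysis against the
    mutation-only expected curve, optimal-codon determination from
    high/low-bias gene partitions via delta-RSCU, parsimony duplication-loss
    reconciliation of gene trees against species trees with per-branch
    gain/loss counts and ancestral family sizes, strand-aware promoter and
    exon-intron structure extraction from GFF3 annotation, and seeded
    synthetic-data generators (codon-usage profiles, CDS sets, gene-family
    histories) so every stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
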