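Package: probioplex
Title: Multiplex PCR Genotyping and Label-Claim Auditing of Probiotic Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design and in-silico evaluation of multiplex PCR genotyping
    panels for probiotic species and sub-species. Builds degenerate IUPAC
    consensus sequences from marker-gene alignments (for example the
    single-copy pgi gene), designs discriminative primer pairs per taxon,
    predicts amplicons by exhaustive IUPAC-aware primer-binding scans,
    partitions assays into gel-resolvable multiplex reactions, and calls
    per-taxon presence from virtual gel band patterns to audit products
    against their label claims. Also includes a 16S rRNA V4 relative
    abundance profiler (pair merging, quality filtering, 100 percent
    identity dereplication, type-strain assignment with collapsing of
    indistinguishable groups), colony-count label-claim auditing, and
    seeded synthetic generators for marker panels, mock communities,
    amplicon reads and mislabeled product fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
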