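Package: mutburden
Title: Background Mutability Models and Outlier Detection for Somatic
    Mutation Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the background somatic mutation burden of human
    protein-coding genes and flags candidate cancer genes as positive
    residual outliers. Enumerates all single-nucleotide substitution
    outcomes in coding sequences to count potential missense, nonsense and
    silent sites; assembles per-gene covariates (nucleotide composition,
    CpG content, nucleotide diversity, conservation index, expression,
    replication timing, chromatin accessibility, SNP density, silent-
    mutation counts); fits stepwise multiple linear regressions for the
    expected number of missense, nonsense and frameshift mutations per
    gene; and converts residuals to Z-scores with a multiplicity-corrected
    significance cutoff. A synthetic-cohort generator with known
    coefficients and injected driver excesses makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
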