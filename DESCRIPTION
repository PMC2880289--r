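Package: mcdisrupt
Title: Multi-Dimensional Integration of Copy Number, Allelic State and
    DNA Methylation to Explain Cancer Gene Expression
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls per-gene disruption status in four genomic dimensions
    (expression, copy number, allelic state, DNA methylation) from
    normalized cancer-versus-reference profiles, decides which expression
    changes are explained by direction-concordant DNA events, derives
    cohort frequency thresholds from a within-sample permutation null,
    and runs the four-step multiple concerted disruption (MCD) gene
    selection funnel.  Includes Fisher gene-set enrichment with
    Benjamini-Hochberg correction, Kaplan-Meier tertile survival
    comparison, a synthetic multi-omics cohort generator with planted
    ground truth, and plain-text readers and writers for all formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
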