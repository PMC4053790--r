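Package: gokaks
Title: Rapidly and Slowly Evolving Gene Ontology Categories from
    Pairwise Ka/Ks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects Gene Ontology categories evolving faster or slower
    than the genome-wide average between two species' one-to-one
    orthologs.  Counts synonymous and non-synonymous sites and
    substitutions on pairwise in-frame codon alignments by
    pathway-averaged codon counting, aggregates them into a per-category
    binomial divergence statistic against the genome-wide expected
    non-synonymous proportion, and calibrates outlier counts with an
    annotation permutation null that moves each gene's full term set
    atomically.  Also provides ortholog coding-sequence quality filters
    (coverage, low-quality fraction, frameshift compensation, premature
    stops), likelihood-ratio-test plumbing for positive-selection scans,
    and a codon-level sequence-pair simulator with plantable category
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
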