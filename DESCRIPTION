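Package: annoweave
Title: Evidence Integration for Genome Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for integrating extrinsic evidence into structural genome
    annotation: longest-ORF detection in spliced transcripts, filtering and
    collapsing of aligned Iso-Seq isoforms to a nonoverlapping representative
    set, refinement of repeat soft-masking over expressed ORFs, construction
    and algebra of RNA-Seq and protein hint sets, combination of predicted
    genes with Iso-Seq ORFs into seed regions, classification of predictions
    by evidence support, annotation summary statistics, and selection of
    single-dose markers for polyploid linkage mapping. Includes a
    deterministic synthetic-data generator that plants genes, repeats,
    isoforms, hints and F1 tetraploid genotype matrices with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
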