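Package: editrec
Title: Recoding Analysis of A-to-I RNA Editing in Protein-Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Maps catalogs of A-to-I RNA-editing sites onto annotated
    transcriptomes, classifies synonymous and nonsynonymous recoding
    events, and tests per-transition enrichment against a codon-resampling
    null model (log2 enrichment ratio with pseudocounts, Fisher exact
    tests, Benjamini-Hochberg correction). Also compares the conservation
    of edited versus editable residues by 22-letter Shannon entropy,
    analyses the codon-usage direction of synonymous events, and provides
    cross-organism enrichment-profile comparisons. Ships a synthetic-data
    generator that emulates the statistical structure of real editing
    datasets so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
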