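Package: hotpepr
Title: Peptide Pattern Recognition and Peptide-Driven Genome Annotation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised division of protein families into subfamilies, each
    defined by a list of conserved hexapeptides with within-group frequencies
    (peptide pattern recognition), and annotation of genes directly in raw
    genome assemblies by six-frame peptide matching with explicit significance
    thresholds (homology to peptide patterns), including fragment merging for
    fungal contigs and independent open-reading-frame hits for bacteria.
    Also provides shared-peptide cluster analysis with Ward linkage,
    positional profiles of conserved peptides along protein sequences, and a
    synthetic-data generator that plants motif families and genes with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
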