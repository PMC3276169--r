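Package: eremosyn
Title: Comparative Genomics of Pre-Whole-Genome-Duplication Yeast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of small fungal genomes of the
    Saccharomyces complex: synteny-block decomposition by ortholog anchor
    chaining against a second genome or a reconstructed ancestral gene
    order, genome statistics tables, sliding-window GC landscapes with
    detection of AT-rich troughs at centromeres and telomeres, point
    centromere identification via the CDEI-CDEII-CDEIII element model,
    telomere tandem-repeat unit inference, cross-species gene
    presence/absence and tandem-duplication conservation, and exhaustive
    minimal rearrangement-scenario search (inversions, reciprocal and
    telomeric translocations, fusion, fission) on small block permutations.
    Includes a seeded genome-evolution simulator that produces
    ancestor/descendant pairs with a ground-truth event log for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
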