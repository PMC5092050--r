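Package: mutenrich
Title: Observed-Versus-Expected Enrichment of Coding Mutation Classes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether classes of somatic coding mutations occur more often
    than a uniform substitution null predicts. Enumerates every theoretical
    single-nucleotide change of a coding sequence as the expected-case null,
    classifies consequences by translation (including localization of the
    premature stop codon introduced by frameshift indels), reads and normalizes
    MAF-style somatic mutation catalogs with HGVS protein/CDS parsing and
    exon-level stratification, and computes fold enrichments, recurrence
    statistics, Fisher's exact tests with Benjamini-Hochberg adjustment,
    tumor-type summaries and primary-versus-metastasis contrasts. Ships a
    TP53 gene model and a seeded catalog simulator with known selection
    weights so every pipeline stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
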