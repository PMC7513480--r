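Package: barcodeval
Title: Evaluation of DNA Barcode Markers: Barcoding Gap, Species
    Identification, Diversity and In Silico PCR-RFLP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate a candidate DNA barcode locus (such as
    nuclear ribosomal ITS2) over a set of species-labelled, aligned
    sequences: Kimura 2-parameter distances with pairwise deletion,
    six standard intra-/inter-specific divergence metrics, barcoding-gap
    histograms and overlap statistics, leave-one-out species
    identification by nearest genetic distance and by best local
    alignment hit, nucleotide polymorphism and neutrality statistics
    (segregating sites, haplotypes, pi, Watterson's theta, Tajima's D),
    in silico restriction digestion with IUPAC-degenerate recognition
    sites and enzyme ranking for haplotype discrimination, and
    neighbor-joining trees with column bootstrap. A synthetic-data
    generator produces species-structured alignments under the Kimura
    model and neutral-coalescent samples for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
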