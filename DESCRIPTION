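Package: plastomics
Title: Comparative Analysis of Quadripartite Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of angiosperm plastid (chloroplast)
    genomes with the canonical quadripartite LSC-IRb-SSC-IRa architecture.
    Reads and writes annotated genomes (GenBank flat file, FASTA), detects the
    inverted-repeat pair and reports gene-junction relationships, computes gene
    censuses and region-length summaries, classifies alignment sites and scans
    sliding windows for mutational hotspots using the (NS+ID)/L mutation-event
    proportion, screens genes for premature internal stop codons and frameshift
    disruptions with Nei-Gojobori (1986) dN/dS estimation and a permutation
    contrast of lineage omegas, builds coding/noncoding/complete alignment data
    sets under three filtering strategies with functional partition subsets,
    and recovers topologies by Jukes-Cantor neighbor joining with bootstrap.
    Includes a seeded simulator of quadripartite plastomes evolved along a
    known tree that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
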