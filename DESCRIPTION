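Package: hexamap
Title: Detection and Genetic Mapping of Homoeologous Exchanges in
    Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and genetically maps homoeologous exchanges (HE),
    segmental deletions and duplications in allopolyploid crops such as
    Brassica napus. Implements read-depth segmentation of whole-genome
    sequencing coverage (1000-bp median bins, circular binary segmentation,
    50-kb merge and length rules, classification at one standard deviation
    around the chromosome mean), rearrangement-aware scoring of SNP-array
    markers in doubled-haploid populations (simple, hemi-SNP 'het' and
    presence-absence 'PA' classes with 1:1 segregation tests), linkage-map
    construction (recombination-fraction grouping at 0.2, seriation
    ordering, Haldane distances), HE calling by reconciling marker-block and
    coverage evidence through a homoeology table, and QTL interval mapping
    by Haley-Knott regression with cofactors. A seeded synthetic-data
    generator produces toy allopolyploid genomes, DH populations, array
    calls, depth tracks and phenotypes with known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
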