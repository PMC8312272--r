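Package: phacmine
Title: Genome Mining of Polyhydroxyalkanoate Synthase (PhaC) Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining microbial genome collections for polyhydroxyalkanoate
    (PHA) synthase (PhaC) genotypes. Curates reference PhaC protein sets (name-based
    exclusions, domain-specific length filters, duplicate removal, class assignment
    from protein names or TIGRFAM identifiers), transfers classes to unclassified
    references by best-protein-hit, detects PhaC loci in nucleotide genomes via a
    translated six-frame local-alignment search with Karlin-Altschul bitscores and
    E-values, calls one representative genotype per genome with explicit tie-break
    rules, joins GOLD-style ecosystem metadata, tabulates class-by-ecosystem relative
    abundances including extreme-environment subtotals, and exports neighbor-joining
    trees with class annotations. A synthetic-data generator produces reference sets,
    genomes with planted marker genes, and ecosystem metadata with a known truth
    manifest so the whole pipeline is testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
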