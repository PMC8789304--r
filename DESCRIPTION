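Package: wgdmirna
Title: Simulation and Analysis of microRNA Retention After Whole-Genome
    Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how microRNA repertoires evolve through rounds of
    whole-genome duplication (WGD). Includes a forward simulator of miRNA
    genomes along a WGD-annotated species tree (auto- or allotetraploidy with
    subgenome-biased fractionation, seed-conserving sequence drift, lognormal
    expression), polycistron clustering under the 50-kb rule with paralog
    multiplicity profiling, Dollo-parsimony reconstruction of ancestral miRNA
    repertoires and subgenome retention tables, chi-square tests for subgenome
    dominance and auto- versus allotetraploidy classification, and comparisons
    of mature-miRNA expression and JC69 precursor divergence across subgenomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
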