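Package: funcdiff
Title: Functional Comparison of Species in Microbial Communities from
    Gene-Ortholog Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares members of microbial communities using only functional
    gene annotation (KEGG Orthology assignments of genomes or metagenome
    assemblies) and a pathway ontology.  Builds KO presence/absence, pathway
    coverage, genus abundance, KO-genus abundance and pathway-genus coverage
    feature matrices with their per-million and complement normalizations;
    clusters organisms and samples by affinity propagation with agglomerative
    merging and exemplar-preference tuning; ranks discriminative pathways by
    coverage standard deviation; selects class-discriminative features with a
    shadow-feature (Boruta-style) random-forest wrapper; and generates
    synthetic communities with planted pathway absences and genus dynamics
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    mclust,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
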