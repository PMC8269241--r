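Package: phagehost
Title: Virus-Host Prediction and Circularity Analysis for Plasmidome-Derived Phage Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ecogenomic analysis of phages recovered from
    plasmidome-style (circular-DNA enriched) metagenome assemblies.
    Classifies scaffolds as circular from terminal direct repeats and
    junction-spanning read pairs, and predicts bacterial hosts for viral
    contigs by three independent lines of evidence: canonical
    tetranucleotide-frequency distance, shared virus-host genomic regions
    (prophage integration or horizontal gene transfer, including
    strain-level whole-virus containment), and CRISPR spacer matching with
    back-validation. Per-method calls are merged into a consensus report
    with lowest-common-ancestor taxonomic assignment and within-viral-cluster
    host consistency. Ships a synthetic community generator that plants
    known virus-host relationships (genus-specific nucleotide composition,
    full and partial prophages, CRISPR arrays, circular read libraries) so
    the whole pipeline is testable end to end, plus curation utilities for
    auxiliary metabolic gene annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
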