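Package: kinomeviz
Title: Annotate the Human Kinome Tree with a Line-Oriented Command Language
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Parses the KR annotation language and deterministically overlays
    text and shape annotations, legends, and kinase-inhibitor binding profiles
    on a schematic human kinome phylogenetic tree. Provides a kinase leaf
    registry (Manning names, synonyms, UniProt and IPI identifiers,
    group/family/subfamily classification, protein sequences) with
    identifier resolution and pairwise-alignment search, coordinate-template
    handling and schematic dendrogram layout generation, deterministic
    PostScript/SVG vector rendering with raster export, conversion of
    tab-separated affinity matrices (Kd/IC50) into per-inhibitor and
    combination annotation documents, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
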