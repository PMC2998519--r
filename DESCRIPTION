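Package: pathrepo
Title: Four-Layer Pathway Repository with Network Construction and Export
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A file-backed data model for metabolic and regulatory networks
    organised in four layers: molecular entities, localized entities bound to
    subcellular compartments, typed interactions over role-tagged
    participants, and pathways as unordered interaction collections.
    Provides schema-validated loading of a JSON repository document with
    lazy, observable materialization of collection-valued data; bidirectional
    navigation between layers; search and filtering; user-defined network
    construction with set algebra; source/sink detection, p-neighbourhood
    expansion and shared-gene pathway distance matrices; deterministic export
    to SBML Level 2 Version 4, XGMML, GraphViz dot and CSV; seeded synthetic
    repository generators; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
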