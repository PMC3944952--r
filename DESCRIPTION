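Package: atlasont
Title: Ontology-Based Harmonization of Human Brain Atlas Labeling Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconciling the labels used by common human brain
    parcellation schemes (Talairach Daemon, Desikan-Killiany/FreeSurfer,
    AAL and NeuroLex) through a structural anatomy ontology.  Provides
    label grammars with abbreviation expansion and laterality extraction,
    semi-automatic term mapping with a curation workflow, taxonomic and
    partonomic reasoning with transitive closure, modeling patterns for
    cytoarchitectural-by-morphological intersection classes, sulcal
    segments and white-matter tract partonomy, connectivity relations with
    pathway inference, cross-atlas label correlation, and a plain-text
    serialization (a Turtle dialect plus TSV tables) with a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
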