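Package: apexloc
Title: Ratiometric Protein Localization from APEX2 Proximity-Labeling TMT
    Proteomics
Version: 0.1.0
Authors@R:
    person("Compartmentalome", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies protein subcellular localization from APEX2
    proximity-labeling tandem-mass-tag (TMT) proteomics using control-anchored
    ROC enrichment cutoffs and cross-comparison voting, as applied to
    cyanobacterial compartmentalomes (cytoplasm, thylakoid lumen, and combined
    periplasm/outer membrane).  Includes ln(x+1)/cyclic-loess normalization and
    enrichment computation, a ground-truthed synthetic-data generator for the
    whole pipeline, signal-peptide physicochemical and structural feature
    computation over N-, H-, and C-regions (GRAVY, isoelectric point, charge,
    z-scale descriptors, auto/cross-correlation, secondary-structure run
    statistics), and two-group significance scanning of those features between
    localization classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    limma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
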