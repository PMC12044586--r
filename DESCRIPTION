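Package: derivmz
Title: Annotation of Chemically Derivatized Metabolite Ions in MALDI
    Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structure-aware annotation of metabolite ions observed in
    matrix-assisted laser desorption/ionization mass spectrometry imaging
    (MALDI-MSI) after on-tissue chemical derivatization with charge-tagging
    matrices such as FMP-10.  Counts derivatizable functional groups
    (phenolic hydroxyls, primary and secondary amines) on SMILES structures,
    enumerates every observable singly charged multi-tag derivative ion
    including charge-reduction losses, matches experimental feature lists
    against a sorted candidate index inside a ppm window with endogeneity
    and tissue filtering, fits a three-parameter quadratic mass
    recalibration curve from known reference masses, and ranks MS2 spectra
    against a reference library by binned cosine similarity.  Includes
    deterministic synthetic-data generators for isomer panels, standards
    panels, feature lists with injected mass-error curves, and MS2
    libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    mzR,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
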