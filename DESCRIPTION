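Package: nanoburden
Title: Internal Dose of Inhaled Nanoplastics from Imaging, Pyrolysis and
    Aerosol Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the internal dose of inhaled polymer nanoparticles
    in a 28-day rat inhalation study. Segments and sizes fluorescent
    nanoparticle agglomerates in 3D confocal stacks and converts object
    volumes to organ burdens via a packing-density mass model;
    back-calculates polymer mass per organ from pyrolysis-GC/MS peak
    areas through external calibration with detection limits and spike
    recovery; derives aerosol concentration and MMAD/GSD from gravimetric
    filters and cascade-impactor stage masses; and fits mono- and
    biphasic first-order lung clearance (deposition fraction, retention
    half-time, overload check). A seeded synthetic-data generator emulates
    every input - ground-truthed confocal stacks, calibration runs,
    impactor runs and burden time courses - so the whole pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    randomForest,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
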