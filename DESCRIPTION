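Package: anfmorph
Title: 3D Morphometry of Inner-Hair-Cell / Auditory-Nerve-Fiber Synaptic
    Regions from Segmented Volume-EM Label Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fiber-wise morphometric analysis of segmented FIB-SEM label
    volumes of the cochlear inner-hair-cell (IHC) / auditory-nerve-fiber
    (ANF) synaptic region. Provides anisotropic label-volume I/O (multi-page
    TIFF and NRRD with a JSON sidecar), per-slice profile extraction with
    crack-contour perimeters and Crofton circularity, longitudinal
    mitochondrial profiling with terminal/pre-terminal partitioning and
    mito-peak alignment, presynaptic-ribbon reconstruction (volume, length,
    multiplicity, hollow cores) with ribbon-centric virtual re-sectioning,
    rule-based afferent fiber classification (synaptic, contact, retracted),
    efferent-synapse scoring against apposition/vesicle/thickening/
    persistence criteria with serial-trace plaque areas, modiolar/pillar
    spatial classification, nonparametric group statistics, and a synthetic
    cochlear phantom generator that plants exactly known ground truth for
    control and noise-exposed (1-day, 1-week) conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
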