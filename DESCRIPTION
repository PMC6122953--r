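Package: perinexus
Title: Quantitative Analysis of Cardiac Junctional Nanodomains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify the nanoscale organization and functional
    consequences of cardiac intercalated-disk junctions: relative
    localization analysis of two-channel 3D single-molecule localization
    data (fiducial-based channel registration, density-based cluster
    detection, voxelized volume overlap, signed edge-to-edge distances and
    perinexal adjacency classification), activation mapping and
    conduction-velocity/anisotropy extraction from optical-mapping movies,
    junctional-resistance quantification from electric cell-substrate
    impedance series, inter-membrane width profiling from digitized
    electron-microscopy membrane traces, and rule-based detection of
    ventricular tachycardia in volume-conducted electrocardiograms. Every
    modality is paired with a seeded synthetic-data generator that stores
    ground truth, so all analyses can be exercised and validated end to end
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    pracma,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
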