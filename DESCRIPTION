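Package: favf
Title: Autofocusing Visual Feedback for Fluorescent Rare-Cell Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional locating, segmentation, depth
    estimation and tracking of fluorescent cells and a micropipette tip
    under a simulated fluorescence microscope, together with a closed-loop
    virtual sorting driver. Implements scalable correlation coefficient
    (SCC) template matching for planar locating, marker-controlled
    watershed separation of overlapping cells, multiple depth from defocus
    (MDFD) with contrast-based symmetry screening, neighborhood-search
    template tracking with template update, and a defocus imaging
    simulator (linear blur growth, Gaussian point spread function,
    energy-conserving rendering) that supplies all test imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
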