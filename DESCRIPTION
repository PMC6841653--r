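Package: ctvsim
Title: Virtual Fluoroscopy Simulation for Coracoid Screw Corridor Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation environment for planning screw fixation of coracoid
    base fractures under virtual fluoroscopy. Renders parallel-beam digitally
    reconstructed radiographs (DRRs) of CT-like volumes at arbitrary rigid
    orientations, places a virtual screw perpendicular to the viewing plane at
    a crosshair, searches for the optimal screw corridor as the maximal
    inscribed cylinder of a bone tunnel (defining the coracoid tunnel view,
    the projection in which a correctly oriented screw appears as a dot),
    scores placements against three geometric criteria (tunnel traversal,
    parallelism to the glenoid plane, cortical breach via an exact anisotropic
    Euclidean distance transform), and provides the paired-design statistics
    of a before/after rater study (exact and asymptotic McNemar tests,
    ICC(A,k) with confidence intervals and reliability bands, exact power of
    the paired-proportions test). Synthetic phantoms with known ground truth
    (capsules, spheres, a scapula analog) stand in for cadaver CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    withr,
    png
Config/testthat/edition: 3
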