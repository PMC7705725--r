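Package: lesionscope
Title: Quantitative Micro-CT Analysis of Brain Lesions and Implanted Electrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of volumetric micro-CT scans of
    rodent brains. Provides masked slice-wise structural similarity (SSIM)
    profiling of the hippocampal formation with single-linkage hierarchical
    clustering for lesion detection, landmark-based rigid alignment of whole
    brains into a shared coordinate frame, a normalized two-dimensional
    anatomical coordinate system for localizing implanted tetrodes against a
    cannula layout, and estimation of pairwise theta-band phase offsets from
    local field potentials using zero-phase equiripple filtering, Hilbert
    phase, and run-period-gated circular statistics. A synthetic cohort
    generator produces brain volumes with a parametric hippocampal cell
    layer, excitotoxic-style lesion cavities anchored to published infusion
    coordinates, electrode artifacts, and theta-band LFP sessions with known
    ground truth, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
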