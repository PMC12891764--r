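Package: aqueflow
Title: Ventricular Morphometry, Aqueductal Resistance and CSF Stroke Volumes
    from MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cerebrospinal-fluid (CSF) dynamics and ventricular
    morphology from magnetic-resonance images: the ventricle-to-brain area
    ratio (Ratio-Area) on a T1-like axial slice, the hydraulic resistance of
    the cerebral aqueduct from a finite-segment Poiseuille model with a 95%
    cumulative-resistance endpoint, and CSF stroke volumes with the
    aqueduct-to-cervical stroke-volume ratio (Ratio-SV) from cine
    phase-contrast velocity series. Includes synthetic phantom generators
    with closed-form ground truth, a nonparametric cohort-statistics
    protocol (3xIQR outlier screening, Wilcoxon rank-sum with effect size,
    Spearman correlation matrices), and a per-subject pipeline with
    cohort-level reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    igraph,
    EBImage,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
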