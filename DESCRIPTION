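Package: zfvision
Title: Analysis of Zebrafish Visual Physiology Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying larval zebrafish visual behavior and retinal
    physiology: detection of hunting (eye-convergence) events from eye-angle
    time series with a noise-adaptive threshold, electroretinogram b-wave
    quantification, normalization and correlation analysis of outer plexiform
    layer fluorescence line-scans, optomotor-response trajectory metrics, and
    the proportion and distribution statistics used to compare genotypes
    (Wilson intervals, two-proportion z-tests, chi-square, Kolmogorov-Smirnov,
    Holm-Sidak adjusted t-tests). Seeded synthetic-data generators emulate each
    recording modality with known ground truth so every stage of the pipeline
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), zoo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'paradigms.R'
    'synthetic.R'
    'hunting.R'
    'erg.R'
    'opl.R'
    'omr.R'
    'stats.R'
    'io.R'
    'pipeline.R'
    'zfvision-package.R'
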