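Package: afmirib
Title: Analysis of AFM-IR Maps and Spectra of Bacterial Inclusion Bodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for atomic force microscopy-based
    infrared spectroscopy (AFM-IR) of epoxy-embedded bacteria. Provides domain
    classes for multi-channel AFM-IR map datasets and point spectra, a
    ground-truthed synthetic phantom generator, spectral processing
    (session-epoxy normalisation, min-max scaling, amide-I band
    quantification, Savitzky-Golay second derivatives), map-level corrections
    (rigid-then-affine drift registration by height-map cross-correlation,
    line-by-line PLL frequency flattening, amplitude ratio maps),
    triangle-threshold inclusion-body segmentation with a pluggable cell
    backend, per-inclusion-body morpho-spectral feature extraction, and a
    statistics layer with a normality/homoscedasticity test-selection tree,
    Tukey/Dunnett/Dunn post hocs, uncapped Bonferroni correction, bootstrap
    confidence intervals and bootstrap-tested correlation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    EBImage,
    signal,
    multcomp,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'affine.R'
    'afmirib-package.R'
    'features.R'
    'io.R'
    'maps.R'
    'methods.R'
    'pipeline.R'
    'qc.R'
    'segment.R'
    'spectra.R'
    'stats.R'
    'synthetic.R'
    'utils.R'
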