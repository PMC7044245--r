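Package: strain4d
Title: Regional Lung Deformation Analysis for 4DCT Under Conventional and
    Oscillatory Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of regional lung deformation from periodic (phase-binned)
    4DCT image sequences during conventional, high-frequency, and
    multi-frequency oscillatory ventilation. Composes per-phase spatial
    transformations through a common reference frame, computes per-voxel
    Jacobian-determinant volume series, intratidal aeration, volumetric strain
    and strain-rate maps with spatial summaries, per-voxel Fourier harmonic
    amplitude/phase maps and a harmonic distortion index, recursive octree and
    supervoxel heterogeneity decompositions, scalar ventilation and
    gas-exchange indices (oxygenation index, ventilatory cost, driving
    pressure, dynamic elastance), Welch cross-spectral respiratory impedance
    estimation with constant-phase model fitting, and nonparametric
    Kruskal-Wallis/Dunn/Benjamini-Hochberg group comparisons. Includes an
    analytic 4D deforming-lung phantom with exact transformations and
    Jacobians, plus ventilator waveform and forced-oscillation record
    synthesis, for validation of every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-grid.R'
    'waveforms.R'
    'phantom.R'
    'impedance-sim.R'
    'transforms.R'
    'regional-metrics.R'
    'harmonics.R'
    'heterogeneity.R'
    'ventgas.R'
    'impedance.R'
    'stats.R'
    'cohort.R'
    'io.R'
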