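Package: glomotopy
Title: Quantifying Retinotopy in Optic Glomeruli from Connectome Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for asking how much retinotopic order survives the
    convergence of visual projection neurons (such as Drosophila LC6) into
    an optic glomerulus, and how downstream neurons could read out spatial
    information. Implements the Retinotopy Index, a rank-inversion statistic
    on distance-ordered neighbour lists of a point mapping between two
    metric spaces, together with its null mappings (full and block
    randomization, rigid transforms, idealized one-dimensional glomerulus
    projections); skeleton geometry (SWC resampling, cross-section
    positions, glomerulus long axis, median and axon-tip positions,
    equal-synapse compartments); connectivity statistics (connectivity
    matrices, a distance-weighted neuron-to-neuron shuffle test, a
    presynapse-based distance metric, target proximity and synapse-density
    profiles); synapse-weighted Gaussian anatomical receptive fields with
    fraction-of-peak contours; calcium-imaging summary statistics
    (sliding-percentile dF/F, percentile normalization, peak responses,
    functional receptive-field maps with FDR control, tuning regression,
    bilateral suppression tests); and a synthetic connectome generator with
    a tunable degree of retinotopy so the whole pipeline is testable
    without any reconstruction data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
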