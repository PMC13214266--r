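Package: fluoQuanta
Title: Optical Quantal Analysis of Neuromodulator Release from Fluorescence Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying presynaptic release properties from
    wide-field fluorescence movies acquired with genetically encoded
    neurotransmitter indicators. Implements the full analysis chain from raw
    image stacks to biophysical parameters: translational registration and
    movement diagnostics, Landweber deconvolution with a measured point
    spread function, pixel-wise photobleaching correction, temporal
    denoising, background subtraction, dF/F0 computation, density-based
    release-site (hotspot) detection, radial single-exponential spread
    fitting, classical optical quantal analysis (quantal size, quantal
    content, release probability), and readily releasable pool size and
    vesicular refilling rate estimation from sensor off-rate-corrected
    cumulative release during long stimulus trains. A synthetic movie
    generator with known release physics, sensor kinetics, optics and noise
    provides ground truth for parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Neuroscience, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'fluoQuanta-package.R'
    'hotspots.R'
    'pool.R'
    'preprocess.R'
    'quantal.R'
    'simulate.R'
    'stats.R'
    'utils.R'
    'workflow.R'
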