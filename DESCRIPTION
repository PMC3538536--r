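Package: sinusoidCT
Title: Simulated Propagation-Based Phase-Contrast Micro-CT and 3D
    Morphometry of Hepatic Sinusoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, seed-deterministic pipeline for studying the
    dilated hepatic sinusoids that characterise cavernous hemangioma of
    the liver with synchrotron in-line phase-contrast micro-CT, entirely
    in silico. Generates tissue phantoms (refractive decrement and
    absorption index volumes with ground-truth lumen and thrombus
    labels), simulates monochromatic parallel-beam acquisition with
    Fresnel free-space propagation, flat/dark fields and Poisson
    counting noise, applies detector-domain corrections (flat/dark
    normalisation, smoothing, ring-artifact suppression, unsharp edge
    enhancement), reconstructs by filtered back projection, segments
    sinusoid lumina and intraluminal thrombi, and measures per-sinusoid
    morphometry: minimum and maximum diameter, surface area, volume and
    thrombus volume fraction, with cohort summaries and ground-truth
    recovery reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'sinusoidCT-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'io.R'
    'morphometry.R'
    'optics.R'
    'phantom.R'
    'pipeline.R'
    'preprocess.R'
    'recon.R'
    'segment.R'
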