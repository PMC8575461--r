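Package: rhodokin
Title: Kinetic Analysis of Branched Rhodopsin Photocycles from Time-Resolved Difference Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decomposition of time-resolved UV-Vis and FTIR
    difference-absorbance data from enzymerhodopsin photocycles. Provides a
    branched four-state photocycle model (dark state D and the K, L, M
    intermediates) propagated under flash or continuous-illumination
    protocols, a synthetic-data generator with Gaussian band spectra, noise
    and baseline drift, preprocessing (baseline correction, N-point
    smoothing, fingerprint-band scaling), SVD plus variable-projection
    global exponential fitting with decay-associated to species-associated
    spectral rotation (target analysis), marker-band trace machinery, and a
    caged-substrate enzyme-turnover model with burst kinetics, light gating,
    dark activity and optional product feedback inhibition.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
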