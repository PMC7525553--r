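Package: srsaxs
Title: Angular Super-Resolution Retrieval for Small-Angle X-Ray Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage angular super-resolution retrieval for 2D small-angle
    X-ray scattering (SAXS) detector images. Subpixel-sampling (SPS)
    multi-frame fusion synthesizes an effective pixel size l/f from frames
    recorded at detector translations of l/f, and Constrained
    Multi-Deconvolution (CMD) jointly deconvolves several exposures taken
    with different engineered beam-profile point-spread functions through a
    weighted, ridge-regularized least-squares objective. Includes a Poisson
    forward model for synthetic scattering data (Lorentzian rings, reciprocal
    background, beamstop, slit-times-Gaussian PSFs), instrument geometry and
    azimuthal integration, the peak-separation criterion delta with
    repeat-based uncertainty, Richardson-Lucy and Farsiu-style baselines, and
    equal-exposure protocol comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
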