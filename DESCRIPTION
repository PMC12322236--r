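Package: slprep
Title: Simulation and Quantification of Spin-Lock T1rho Preparation Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Matrix-propagation simulator and quantification toolkit for
    spin-locked T1rho preparation modules used in quantitative MRI.
    Implements composite (C-SL), balanced (B-SL), triple-refocused (TR-SL)
    and quadruple-refocused (QR-SL) preparation schemes as 3x3 rotation and
    rotating-frame relaxation propagators, closed-form limiting-case oracles,
    mono-exponential T1rho fitting with quantization-error and residual
    metrics, grid sweeps over B0/B1 field inhomogeneities, a digital tube
    phantom with field-map estimation operators, and RF amplitude bookkeeping
    for SAR-proxy comparisons.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
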