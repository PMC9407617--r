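Package: mfleaders
Title: Wavelet-Leaders Multifractal Analysis of Cepstral Signal Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonlinear analysis of physiological audio signals (e.g. infant cry
    episodes) through the real cepstrum and the wavelet-leaders multifractal
    formalism. Computes real cepstra, discrete wavelet transforms with
    biorthogonal filters, wavelet leaders, structure functions, scaling
    exponents, Legendre singularity spectra and leader log-cumulants (c1-c3),
    and compares the resulting descriptors between two labeled groups with
    Student/Welch t-tests. Ships exact synthetic generators (fractional
    Brownian motion by circulant embedding, multifractal random walks,
    deterministic binomial cascades, harmonic cry-like signals) with known
    multifractal ground truth for end-to-end validation, plus a manifest-driven
    batch pipeline with figure output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
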