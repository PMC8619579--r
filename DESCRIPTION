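Package: aculatent
Title: Latent Low-Dimensional Dynamics of Multichannel EEG Under Manual Acupuncture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for probing low-dimensional latent dynamics in
    multichannel (19-electrode, 10-20 system) EEG recorded around manual
    acupuncture stimulation at different manipulation frequencies. Provides a
    condition-labelled synthetic recording generator; FIR band-pass filtering,
    average re-referencing and epoch segmentation; Welch power spectral
    density and sub-band power statistics; participation-ratio effective
    dimensionality of the channel covariance; a variational auto-encoder
    (trained by stochastic gradient descent) for latent-variable extraction;
    latent-subspace geometry (best-fit planes, inter-plane angles, direct
    least-squares elliptic attractor fits); and one-way ANOVA plus
    cross-validated classification of brain state from attractor-axis
    features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    data.table,
    MASS,
    e1071,
    class,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
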