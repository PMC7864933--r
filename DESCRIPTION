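Package: pnspec
Title: Passive Multi-Directional Multi-Sphere Photoneutron Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for passive multi-directional Bonner-sphere photoneutron
    spectrometry around high-energy medical linear accelerators. Implements the
    forward folding of neutron spectra through moderator-sphere response
    functions (the discretized Fredholm relation A = R * phi), a linear
    bias-free artificial neural network unfolder trained by resilient
    backpropagation that maps nine sphere readings to a 25-group spectrum, a
    synthetic compendium of parametric neutron spectra with Poisson
    track-counting noise, and the six-side cube analyses: per-side unfolding,
    mean spectra, thermal/fast peak summaries, fluence-versus-diameter curves,
    field-size trends of the mean energy, and dose-equivalent weighting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
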