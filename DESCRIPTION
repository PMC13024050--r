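Package: phytoaffect
Title: Decoding Environmentally Defined Valence-Arousal Regimes from Plant Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether internal plant signals (extracellular
    bioelectric potential and gas-emission proxies) carry decodable
    information about environmentally defined affective regimes. Provides a
    growth-chamber simulator with heater/fan thermostat dynamics,
    residual-light valence-arousal labelling, sliding-window feature
    extraction, an echo state network with ridge readout alongside a windowed
    linear decoder, forward-chaining time-series cross-validation with
    per-fold standardisation, and circular-shift permutation null controls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
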