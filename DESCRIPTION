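Package: lamprobe
Title: Laminar Analysis of Multichannel Cortical Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analyzing linear-probe extracellular recordings from
    layered cortex: reading and writing flat-binary multichannel voltage
    files with channel geometry, scoring brain states (waking, non-REM and
    REM sleep) from spectral and EMG-proxy traces, detecting DOWN/UP states
    of the non-REM slow oscillation, building a laminar map from multi-unit
    power and current source density landmarks with depth normalization,
    clustering recording sites by gamma-band coherence with an
    interaction-energy gradient descent, decomposing gamma local field
    potentials into independent components, quantifying phase-amplitude and
    spike-phase coupling with Morlet wavelets, classifying single units by
    waveform, optogenetic tagging and spike-gamma coupling profiles, and
    detecting putative monosynaptic connections from cross-correlograms
    with Poisson significance bounds and state-resolved spike transmission
    probabilities. A synthetic-session generator with ground-truth
    annotations supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
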