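Package: ffrtools
Title: Cross-Level Analysis of Frequency-Following Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of frequency-following responses (FFRs)
    recorded at the scalp, the cortical surface, and across laminar depth.
    Provides a two-source forward model for generating trial-level epoched
    recordings to Mandarin tone stimuli, preprocessing (power-line removal,
    zero-phase filtering, artifact rejection, polarity averaging, bootstrap
    significance), inter-trial phase coherence spectrograms, sliding-window
    autocorrelation pitch tracking, hidden-Markov-model tone decoding with
    representational similarity analysis (confusion matrices, MDS,
    Procrustes), scalp-versus-cortex spectrotemporal comparison (Welch power
    spectra, cross-spectral density, wavelet cross-correlation latency),
    laminar current-source-density analysis, and Infomax independent
    component analysis with per-electrode variance attribution for
    cortical/subcortical source labeling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    vegan,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
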