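Package: rhythmsamp
Title: Rhythmic Perceptual Sampling of Tone-Cloud Soundscapes and Its
    Pre-Stimulus EEG Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how listeners sample long, non-rhythmic
    auditory scenes over time and how that sampling relates to the state of
    ongoing brain activity. Generates parametric tone-cloud soundscapes with
    controlled per-epoch evidence, simulates probit observers whose temporal
    weighting carries a rhythmic component coupled to a synthetic pre-stimulus
    EEG oscillation, estimates perceptual weighting profiles by psychophysical
    reverse correlation with permutation z-scoring, compares trivial versus
    rhythmic weight models by Bayesian model evidence, bootstrap exceedance
    probability and WAIC, computes single-trial Morlet time-frequency power
    and phase, links pre-stimulus power and phase to behavior (signal
    detection measures, phase opposition sum) and to binned re-estimates of
    the perceptual weights, and provides group-level cluster-based permutation
    inference with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
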