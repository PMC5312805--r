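Package: cimspeech
Title: Causal Inference Modelling of Audiovisual Speech Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates trial-level percepts for audiovisual syllable pairings
    under a Bayesian causal-inference observer model of multisensory speech
    perception (CIMS) and its matched forced-fusion baseline. Syllable
    categories live in a two-dimensional representational space (auditory and
    visual feature axes); each trial encodes the auditory and visual cues with
    modality-specific anisotropic Gaussian noise, fuses them by reliability
    weighting, infers the posterior probability that both cues share a common
    cause, combines the fused and auditory-only representations accordingly,
    and categorizes the result. Includes Monte-Carlo confusion matrices over
    stimulus grids, calibration of the unpublished free parameters to
    behavioral confusion data, generation of synthetic multi-subject
    behavioral datasets, and model-versus-behavior comparison including the
    Fisher r-to-z comparison of correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
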