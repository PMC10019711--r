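Package: awaredyn
Title: Dynamics of Perceptual Awareness Under Informational Masking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for studying the dynamics of auditory perceptual awareness
    in the multi-tone informational-masking paradigm. Generates the random
    multi-tone masker / regular target stimuli of three factorial detection
    experiments (with an ERB-based protected region around the target),
    quantifies masker uncertainty (entropy), masker-target temporal similarity
    and spectro-temporal density, simulates detection-time behaviour from a
    gamma shared-frailty proportional-hazards generative model, and analyses
    detection dynamics with survival machinery: trial categorisation, d-prime,
    mixed-effect summaries, Cox proportional-hazards models with gamma frailty,
    estimated marginal means with Tukey-adjusted pairwise contrasts and compact
    letter displays, Cox-Snell diagnostics, hazard-rate and cumulative
    detection curves, and a leaky evidence-accumulation first-passage
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
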