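Package: fnmesEEG
Title: Analysis of EEG and Behavioural Effects of Facial Neuromuscular
    Electrical Stimulation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how facial neuromuscular electrical
    stimulation (fNMES) of the smiling muscles alters emotion perception
    and its neural correlates. Provides a synthetic-data generator for
    pseudo-randomised trial designs, EEG epochs with planted N170 and
    beta-band coupling effects, stimulation artifacts, binary emotion
    categorisation choices and facial action-unit traces; deterministic
    epoch preprocessing (zero-phase filtering, baseline correction,
    amplitude-threshold rejection, average reference, neighbour
    interpolation); double-subtraction mass-univariate ERP statistics
    with false-discovery-rate control and trial-level N170 extraction;
    time-frequency magnitude coherence between electrode regions of
    interest; Monte-Carlo cluster-based sign-flip permutation tests with
    mask integration and repeated-measures ANOVA; and behavioural choice
    models with log-odds effect-size conversion, points of subjective
    equality, simulation-based power analysis and stimulation-safety
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, TimeCourse, Electrophysiology
RoxygenNote: 7.3.3
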