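Package: emoattn
Title: Multimodal Psychophysiology of Emotion-Attention Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline linking rapid affective-picture
    processing to subsequent attention. Provides a synthetic multimodal
    cohort generator (event-related EEG, skin conductance, reaction time),
    EEG preprocessing (band-pass filtering, average re-referencing,
    epoching, baseline correction, amplitude-based artifact rejection),
    P300 and late-positive-potential mean-amplitude extraction, phasic
    skin-conductance max-change scoring, neutral-referenced difference
    scores with sign-based facilitated/impeded stratification, the
    associated inferential toolkit (t tests with Cohen's d, Wilcoxon
    signed-rank with r, Friedman test, repeated-measures ANOVA with
    Greenhouse-Geisser correction and partial eta squared, Bonferroni
    correction), and cross-validated support-vector classification of
    attentional direction from unimodal and multimodal physiological
    features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    signal,
    e1071,
    pROC,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
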