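Package: avspan
Title: Audiovisual Digit-Span Experiments: Design, Scoring and Ordinal Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for rhythmic/auditory-support digit-span experiments:
    constrained generation of target/distractor digit sequences, pseudo-randomized
    trial schedules and per-trial stimulus timelines; three serial-recall outcome
    scores (positional per-digit accuracy with optimal dummy insertion, Levenshtein
    edit distance, and a distractor-intrusion score); an audiovisual-dominance
    pre-test pipeline (reaction-time cleaning and 2-means clustering); a
    cumulative-link (proportional-odds) model engine with participant-level random
    intercepts and slopes fitted by Laplace approximation or adaptive Gauss-Hermite
    quadrature; a staged multilevel model-selection ladder; nonparametric
    condition comparisons (Kruskal-Wallis, paired Wilcoxon, subgroup contrasts);
    and a synthetic-study generator with planted effects for power and
    parameter-recovery analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
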