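# avspan

Tools for audiovisual digit-span experiments: does a synchronous tone (and
does rhythmic presentation) help people remember visually presented digits
while ignoring just-noticeable distractor digits?

The package is written for researchers running or re-analysing this kind of
working-memory/attention paradigm. It covers the full analysis path on both
real answer tables and synthetic data:

- **Design generation** — digit sequences of 5 targets plus 5 distractors
  (blanks allowed) with recognizable patterns excluded, the pseudo-randomized
  120-trial schedule (30 sequences x 4 conditions; adjacent trials never
  share a condition, at least two other sequences before a repeat), timed
  stimulus timelines (200 ms digits, 1.25 s / 0.8 Hz target grid, five
  induction events in rhythmic conditions, 7 s answer window), and the
  108-trial dominance pre-test schedule.
- **Scoring** — three outcome scores for a recalled digit string:
  *PerDigit* (positional accuracy after optimal dummy-digit insertion,
  in [0, 1]), *Levenshtein* (unit-cost edit distance), and *Distraction*
  (answer trigrams plus prefix/suffix matched against the full presented
  stream minus matches against the targets, scaled by answer length,
  in [-1, 1]; negative = target-driven recall).
- **Dominance pre-test** — reaction-time cleaning (practice, errors,
  RT > 1500 ms), per-modality means, and 2-means clustering into
  auditory- vs visually-dominant participants.
- **Ordinal modelling** — a cumulative-link (proportional-odds) engine,
  `P(Y <= k) = logistic(theta_k - x'beta - z'u_j)`, with participant random
  intercepts and order slopes fitted by Laplace approximation or adaptive
  Gauss-Hermite quadrature, likelihood-ratio/AIC comparison, odds-ratio
  calculus, and the automated X0–X5 model-building ladder.
- **Nonparametric pipeline** — Kruskal-Wallis omnibus across the four
  conditions, paired Wilcoxon post-hocs (paired on participant x sequence),
  subgroup contrasts, and noise-sensitivity clustering.
- **Synthetic studies** — `simulate_study()` generates a full 41 x 120
  dataset (plus pre-test logs and covariates) with planted effects, so power
  and parameter-recovery analyses need no external data.

## Worked example

```r
library(avspan)

# the canonical scoring examples
per_digit_score(c(1, 9, 4, 3, 6), c(1, 9, 4, 6))
#> [1] 0.8
distraction_score(c(1, 9, 4, 3, 6), c(1, 2, 9, 2, 3, 4, 3, 6, 2),
                  c(1, 9, 4, 3, 6))
#> [1] -0.8

# a synthetic study, scored and modelled
b  <- simulate_study(sim_config(), seed = 11)
sc <- score_study(b)
round(tapply(sc$per_digit, sc$condition, mean), 3)
#>        C_1-NoSupp C_2-VisRhythmSupp       C_3-AudSupp  C_4-AVRhythmSupp
#>             0.527             0.540             0.617             0.604

cc <- conditions()
sc$audio  <- cc$audio_support[match(sc$condition, cc$code)]
sc$rhythm <- cc$rhythmic[match(sc$condition, cc$code)]
sc$OrderS <- (sc$Order - 60) / 60
sc$PerDigitBin <- ordinal_response(sc$per_digit, "per_digit", "binned")
f <- cumlink(PerDigitBin ~ audio + rhythm + OrderS + (1 | Participant), sc)
f
#> Cumulative link mixed model (logit)
#> logLik -7334.09  AIC 14686.18  n 4920  params 9  converged
#> Coefficients:
#>  audioTRUE rhythmTRUE     OrderS
#>    0.63971   -0.00188    0.31207
#> Random effects (Participant) std.dev.: (Intercept) 0.8447
```

The audio indicator carries a clear positive log-odds (tones help recall),
the rhythm indicator is null, and participants differ substantially
(random-intercept SD ~0.84) — the structure the simulator plants and the
pattern the pipeline is built to detect. `posthoc_matrix(sc, "per_digit")`
shows the same story nonparametrically: the audio contrasts (C1 vs C3,
C2 vs C4) are significant, the rhythm contrasts (C1 vs C2, C3 vs C4)
are not.

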