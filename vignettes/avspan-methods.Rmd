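---
title: "Methods: design, scoring and ordinal modelling of audiovisual digit-span data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, scoring and ordinal modelling of audiovisual digit-span data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avspan)
```

This vignette explains what the package computes and why its defaults are
what they are: the experimental design it generates, the three recall
scores, the dominance pre-test, the cumulative-link mixed model engine, the
model-selection ladder, and the synthetic-data generator that ties the test
suite together. It states no empirical claim that the test suite does not
itself compute.

## The paradigm

A participant watches a stream of ten encircled digits: five black
*targets* to be remembered in order, interleaved with five just-noticeably
gray *distractors* (which may be empty circles — blanks). Four conditions
cross two supports: a 500 Hz, 50 ms tone synchronous with each target
(auditory support, conditions 3 and 4) and presentation of targets on an
exact 1.25 s (0.8 Hz) beat preceded by five induction stimuli (rhythmic
support, conditions 2 and 4). After the stream, the participant has 7 s to
recall the targets orally. Each of 30 digit sequences appears once per
condition, giving 120 trials, pseudo-randomized so that consecutive trials
never share a condition and a sequence never returns within two trials.

## Design generation

`generate_sequence()` rejection-samples five targets uniform on 1–9 until
consecutive targets differ and the pattern-exclusion predicate fails.
The exclusion rule is a predicate, not a list: arithmetic progressions of
any constant step, strict two-value alternations, and "parity ladders"
(a monotone run with constant step over four digits entered by a short step,
e.g. 1-2-4-6-8). Published examples of excluded patterns are all covered;
an explicit blacklist argument accommodates stricter local choices. The five
distractors are spread over the five gaps following the targets by drawing
uniformly from all 5-tuples in $\{0,1,2\}^5$ summing to 5 — the
maximum-entropy choice given that only the total (5) and the per-gap bound
(0–2) are fixed. Each distractor is uniform over $\{1,\dots,9,\text{blank}\}$,
blank with probability 0.1 (configurable): the blank is treated as a tenth
symbol of the distractor alphabet since no rate is prescribed.

`build_schedule()` satisfies the two schedule constraints by randomized
greedy construction with restarts; the retry cap (2000) converts the
vanishingly rare exhaustion into an explicit error rather than a silent
constraint violation. `render_timeline()` lays events on integer
milliseconds with half-open $[{\rm onset}, {\rm onset}+{\rm duration})$
intervals. In rhythmic conditions target onsets sit exactly on the
1250 ms grid; in non-rhythmic conditions each target is jittered uniformly
in its own 1250 ms window, subject to fitting that window's distractors
after it, via a uniform partition of the window's slack (a stick-breaking
construction, which makes all feasible packings equally likely). Distractors
always land uniformly in the residual interval of their gap. Breaks and
instruction text are deliberately not timing events. Induction is visual
(empty circles, 200 ms) when only rhythm is present and auditory (tone
bursts) when audio support is present, so the induction never introduces the
other condition's modality.

The dominance pre-test schedule (108 trials, six stimulus types) puts two of
each type in the first 12 practice slots and balances the remaining 96 at
16 each, with no more than four identical stimuli in a row.

## The three outcome scores

*PerDigit* measures positional accuracy. When answer and target lengths
differ, dummy symbols are inserted into the shorter string so as to
maximize positional agreement, and the score is that maximum divided by the
longer length. The maximization is a dynamic program over (short-string
index, long-string position) — equivalent to choosing an order-preserving
placement of the shorter string's symbols — and the test suite checks it
against brute-force enumeration of all placements.

*Levenshtein* is the standard unit-cost edit distance, validated against
naive recursion and `utils::adist`, and property-tested for the metric
axioms.

*Distraction* asks whether recall is target-driven or stream-driven. All
$n-2$ consecutive triples of the $n$-digit answer are tested as contiguous
substrings of (a) the target sequence and (b) the full presented stream
(blanks removed); the first two digits are additionally tested as a
*prefix* and the last two as a *suffix* of each. The score is
$(\#\text{stream matches} - \#\text{target matches})/n \in [-1, 1]$.
The edge cases are prefix/suffix tests rather than substring tests: with
substring semantics the first published worked example would count 2
stream matches instead of the printed 1; the prefix/suffix reading
reproduces both published examples exactly, so it is the implemented rule.
For $n = 2$ the prefix and suffix pairs coincide and are both counted
(2 groups); a one-digit answer scores 0 — the group construction needs at
least a pair, and 0 is the neutral value. Answers longer than the stream
are legal; the denominator stays the answer length.

Transcripts are normalized by keeping the characters 1–9 in order; a "0"
is outside the stimulus alphabet and is dropped with a warning.

## Dominance pre-test

Cleaning removes the 12 practice trials, wrong responses, and reaction
times above 1500 ms; participants left with an empty modality are excluded
with a warning, and cleaning is idempotent. Profiles are the per-modality
arithmetic mean RTs. Classification is 2-means (Lloyd's algorithm, best of
20 restarts) on the raw (Au, Vi, AV) means — no standardization, since the
three coordinates share units and scale. Cluster meaning is assigned by the
centroid contrast $\overline{Vi} - \overline{Au}$: the cluster with the
smaller contrast (relatively faster visual responses) is visually dominant.
This encodes the "shortest reaction time" criterion as a formula; distance
ties break to the lower cluster index via the k-means implementation.

## Cumulative-link (mixed) models

The engine fits the proportional-odds model
$$P(Y_{ij} \le k) = \mathrm{logistic}\!\left(\theta_k - x_{ij}'\beta -
z_{ij}' u_j\right),$$
with strictly increasing thresholds $\theta_1 < \dots < \theta_{K-1}$ and
participant-level random effects $u_j \sim N(0, \Sigma)$ — an intercept, or
a correlated intercept and order slope, written in the formula as
`(1 | Participant)` or `(1 + Order | Participant)`. Only the logit link is
provided: the analyses this package supports are reported as odds ratios.

Numerical choices, all of which the test suite exercises:

- Thresholds are parameterized as $\theta_1$ free and log increments, so
  monotonicity is structural, never a constraint to check.
- Fixed-effect columns are standardized internally (centre/scale) for
  optimizer conditioning and back-transformed, with the delta-method
  Jacobian applied to the covariance; estimates are invariant to the
  rescaling to near machine precision.
- Fixed-effects models maximize the exact likelihood by BFGS with the
  analytic gradient, then a Newton polish drives the gradient max-norm
  below 1e-8; two-category fits agree with `glm` logistic regression to
  1e-6 and general fits with `MASS::polr` to 1e-4.
- Mixed models maximize the Laplace-approximate marginal likelihood: the
  random effects are scaled as $u_j = \Lambda v_j$ (Cholesky
  parameterization, diagonal bounded at zero so a variance can pin at the
  boundary and is then reported, not errored); conditional modes $\hat v_j$
  come from damped per-group Newton iterations (tolerance 1e-10, vectorized
  across groups) and the objective subtracts half the log-determinant of
  each group's curvature. Outer optimization is `nlminb` with warm-started
  modes; relative tolerance 1e-8, at most 200 outer iterations.
- For random-intercept models, adaptive Gauss–Hermite quadrature
  (`method = "agq"`, nodes from the Golub–Welsch eigenvalue construction,
  centred at the conditional mode with curvature-based scaling) provides a
  higher-order check; Laplace and 15-node quadrature log-likelihoods agree
  within 0.5 on study-scale fits, and the mixed likelihood collapses onto
  the fixed-effects likelihood (within 0.1) when the planted heterogeneity
  is zero.
- Standard errors come from the finite-difference Hessian of the objective
  at the optimum; when the full Hessian is singular (variance at the
  boundary), the threshold/slope block is inverted and the variance rows
  are flagged as missing rather than fabricated.

`lr_test()` is the naive $\chi^2$ likelihood-ratio test with the parameter
count difference as degrees of freedom — also for comparisons involving a
variance component, matching how such model ladders are conventionally
reported; the conservative boundary-mixture correction would halve those
p-values' tails, a direction that only makes the reported retention
decisions stricter. `odds_ratio()` exponentiates a coefficient and raises
it to the number of units, and composes interaction settings as products of
factor ORs raised to their variable values.

Ordinal questionnaire covariates (task difficulty, perceived supports) are
modelled as numeric per-unit effects, which is what makes "OR per unit,
raised to the scale range" arithmetic meaningful.

## The model ladder

`run_ladder()` automates the staged build-up: X0 (random intercept +
order), X1 (+ sequence and condition), X2 (+ person-level main effects
retained at LR $p < 0.05$), X3 (+ condition:covariate interactions,
retained the same way; sequence interactions optional because 29 extra
contrasts per covariate are rarely informative at these sizes), X4
(correlated random order slope, order:covariate terms, and probes of
order² and order:condition that are kept only if they improve the fit),
X5 (backward simplification, repeatedly removing the least-harmful term
whose removal is not significant). The retention criterion is the LR test
at $\alpha = 0.05$ throughout — the simplest defensible reading of
"removing those that made no significant improvement". Non-convergent
stages are flagged and the ladder continues from the last converged stage.

Response binning: by default every distinct observed score value is an
ordered category; the fixed-width scheme bins per-digit accuracy to the
nearest fifth (the six canonical values of five-digit answers) and the
distraction score into 0.2-wide bins, since most answers are five digits
long and the fractional off-grid values are length artefacts.

## The synthetic-data generator

`simulate_study()` is first-class, tested code, and its defaults *are* the
study conditions: 41 participants, 30 sequences, 120 trials each, identical
sequences across participants in independently pseudo-randomized orders.
Each target is encoded with probability
$\mathrm{logistic}(b_j + a_j\,\text{audio} + r_j\,\text{rhythm} +
s_j\,(\text{order}-60)/60)$, where $b_j$ (mean 0.4, SD 0.7), $a_j$
(mean 0.3, SD 0.3), $r_j$ (mean 0, SD 0) and $s_j$ (mean 0.25, SD 0.2) are
participant traits; each non-blank distractor intrudes with the
participant's intrusion rate (logit mean of 0.15, SD 0.3), *reduced* by the
audio gain under auditory support — audio helps reject distractors, the
mechanism the distraction score measures. Recalled items keep presentation
order (no transposition model: the scores do not require one and none is
prescribed), with 2% deletions and 5% uniform substitutions. The planted
effect sizes are directionally anchored to the findings the pipeline must
be able to detect (positive audio effect, null rhythm effect, learning over
order) and sized so that the study-scale design has high but not trivial
power; they are not calibrated to any fitted human-data coefficients.

Questionnaire covariates are deterministic-plus-noise functions of the
traits (task difficulty falls with encoding ability, perceived sound
support rises with the audio gain, tiredness falls with the learning
slope), so subgroup analyses have real structure to find. Pre-test RTs are
shift-plus-lognormal (shift 200 ms, dominant-modality log-mean log 150,
non-dominant log 220, log-SD 0.25), audiovisual log-mean equal to the
unimodal minimum minus a 0.15 facilitation, 3% errors and 1% slow lapses
to exercise the cleaning stage.

What the generator does *not* emulate: serial-position curves,
transposition gradients, diffusion-style RT distributions, or any
fitted-to-human effect sizes. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes at the study's scale — not that
the human data contain that structure.

## Problem sizes and checks in the test suite

The suite validates the scoring algorithms against brute-force oracles
(1,000 random pairs for the alignment DP, exhaustive recursion for edit
distances up to length 6), scans 2,500 generated sequences and 100
schedules for invariant violations, verifies engine correctness against
logistic regression, `polr`, quadrature and zero-variance limits, checks LR
calibration on 250 null replicates, and runs the study-scale recovery block:
50 bundles at 41 x 120 with planted audio log-OR 0.3 and null rhythm, in
which the mixed model must detect audio in at least 80% of replicates, flag
rhythm at the nominal 5% rate, and the nonparametric contrasts must show
the audio-but-not-rhythm pattern. Smaller sizes are used where a property
is size-independent (e.g. the ladder runs on 24 participants x 32 trials).

## Interfaces and limitations

All artifacts serialize to plain text (CSV for tables, JSON for sequences,
fits and manifests; 1-based orders and indices; UTF-8, "." decimal), and a
study bundle round-trips through `write_bundle()`/`read_bundle()` with a
seed-bearing manifest. There is no shell command-line layer: the exported
functions, the serialization layer and `scripts/acceptance.R` are the
interface; every pipeline stage is one function call.

Known limitations: logit link only; at most one random-effect term (one
grouping factor, intercept plus at most one slope); adaptive quadrature is
restricted to random-intercept models; Wald and LR inference rely on
asymptotics that are adequate at 4,920 observations but optimistic for
very small pilot designs; and the stimulus timelines are schedules, not a
presentation engine — no audio or video is rendered.
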