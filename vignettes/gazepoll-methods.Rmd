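---
title: "Gaze-bias election prediction and facial morphometrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-bias election prediction and facial morphometrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazepoll)
```

## The scientific setting

Preferential-looking experiments present a subject with two images side by
side for a fixed window and record fixation-level gaze events. When the
images are photographs of two candidates who actually contested a U.S.
election, a striking regularity has been reported in macaques: the monkeys
look longer at the eventual **loser**. gazepoll packages that analysis as a
reusable pipeline:

1. **Ingestion** (`read_fixation_table()`, `read_election_table()`,
   `read_landmark_table()`, `read_layout_table()`): fixation events,
   election metadata, rater-level facial landmarks, and per-session screen
   layouts, all as plain CSV with validated schemas.
2. **Gaze scoring** (`tally_trials()`, `cast_votes()`,
   `session_accuracy()`): fixations are assigned to the left or right
   image's rectangle, each trial yields a per-side tally, and a *vote rule*
   converts the tally into a predicted winner — the less-looked-at
   candidate. Accuracy is summarized per session and tested against chance.
3. **Facial morphometrics** (`compute_metrics()`, `aggregate_raters()`,
   `group_contrast()`): nine pixel landmarks give jaw width, cheekbone
   width, face height, and lower face height, normalized by inter-pupillary
   distance (IPD), plus three ratios — jaw prominence (jaw/cheekbone), FWHR
   (cheekbone/face height), and lower face prominence (LFP).
4. **Election analysis** (`correlate()`, `partial_correlate()`,
   `fit_joint_model()`, `classify_state_lean()`, `stratified_summary()`):
   relating gaze and morphometrics to two-party vote share.
5. **Synthetic data** (`sim_config()`, `simulate_study()`,
   `analytic_pair_accuracy()`): a fully parameterized generator emulating
   the study design, with analytic oracles for calibration.

## Gaze model and vote rules

A trial shows one race for 2.5 s. Every fixation whose coordinates fall in a
side's rectangle (0-based pixels, half-open on the max edges, so a point at
exactly `x_max` is outside) counts for that side; fixations outside both
rectangles are ignored. Three vote rules are implemented, all oriented by
the empirical loser-directed bias — the *less*-looked-at candidate is
predicted to win:

* `fixation_count` — fewer in-box fixations;
* `dwell_time` — smaller summed fixation duration (fixations straddling the
  stimulus offset contribute their truncated duration);
* `first_fixation` — the side *not* fixated first. This direction is forced
  by consistency with the loser bias; the alternatives give similar
  accuracy but the sign convention must be fixed somewhere, and it is fixed
  here.

**Tie policy.** Equal tallies (including trials with no in-box fixation at
all) are ties and earn half credit, keeping every race in the denominator
and pinning chance at exactly 0.5. Session accuracy is therefore
`(correct + 0.5 * ties) / races`. Accuracies are aggregated per *session*
(one presentation of one office's full race set by one monkey on one day);
the default design yields 12 such session blocks (3 monkeys x 2 days x 2
offices), and the summary reports mean, SEM, and a two-sided one-sample t
test against 0.5. With zero variance across sessions the t statistic is
undefined and the p-value is reported as `NA` rather than fabricated.

**Rank tests.** Loser-vs-winner contrasts pair values within a race
(Wilcoxon signed rank, zero differences dropped); gender contrasts are
unpaired (Wilcoxon rank sum). Both use the exact null distribution for up
to 12 untied observations and the tie-corrected normal approximation above
that; the tests are checked against brute-force enumeration of the exact
null in the test suite.

## Morphometric model

Landmark semantics are fixed so data producers can match them: *zygion* =
widest cheekbone point, *gonion* = widest jaw point, *face top* = mid-brow
midline point, *lower face top* = upper-lip midline point, *chin bottom* =
chin midline point. All distances are Euclidean point-to-point (robust to
slight head tilt) and normalized by IPD, making every metric invariant to
translation, uniform scaling, and mirroring.

Two conventions deserve flags. First, FWHR here is cheekbone width over
*total* face height; the classical definition uses upper-face height, which
is not among the measurements this pipeline ingests. Second, multiple raters
are averaged at the *metric* level (not the landmark level), and inter-rater
concordance is the per-feature Pearson correlation across candidates,
averaged over rater pairs and then over features — the concordance statistic
is deliberately simple and swappable, since reasonable alternatives (ICC
variants) exist. Concordance is undefined (NA) below 2 raters or 3
candidates.

## Election analysis choices

* Vote shares are **two-party normalized** at ingestion (each candidate's
  share divided by the pair's sum, times 100), so pairs sum to 100. Whether
  published headline correlations used raw or two-party shares is ambiguous;
  normalization is the explicit choice here and the raw column is preserved.
* Correlations: Pearson (or Spearman on request) with Fisher-z 95%
  confidence intervals; for Spearman the same interval is a large-sample
  approximation.
* Partial correlation residualizes on a **single control** (correlating the
  two residual vectors, t-based p on n − 3 df); multi-control adjustment is
  out of scope.
* The joint model is ordinary least squares of vote share on an intercept,
  jaw prominence, and competence, reporting unadjusted R².
* State lean: a race's state is *swing* iff the absolute reference
  presidential margin is strictly below 10 points (margin signed, positive =
  Republican); `red`/`blue` at or beyond ±10. The three labels partition all
  finite margins; +9 is swing, +10 is red.
* Stratified summaries use a rank-sum contrast for two groups and one-way
  ANOVA with Tukey's HSD for three or more; raw p-values are reported
  across families (no global FDR), with Tukey adjustment only within an
  ANOVA family.
* The "incumbent robustness" analysis is the same correlation restricted to
  races containing an incumbent — a subset filter, not a separate estimator.

## The synthetic-data generator

The generator's defaults *are* the emulated study conditions: 124
gubernatorial plus 149 senatorial races (273 pairs, 546 candidates), a fixed
gender composition of 66 mixed-gender, 201 male-male, and 6 female-female
pairs, office-specific incumbent rates (74/124 and 120/149), and 3 monkeys
each viewing the full stimulus set on 2 days (each office set once per day,
order and sides shuffled). A Bernoulli gender mode (`gender_composition =
"bernoulli"`) exists for sampling experiments; the fixed mode is the default
because the stimulus-set composition is part of the design, not noise.

**Faces.** Each candidate carries a latent masculinity, normal with
gender-specific means (defaults ±0.5, SD 1). The four raw measurements (IPD
units) are linear in masculinity with Gaussian noise; default loadings make
males wider-jawed, narrower-cheekboned, shorter-faced, and
longer-lower-faced, so all five derived masculinity cues (jaw prominence,
jaw width, cheekbone width, FWHR, LFP) separate the sexes at realistic
effect sizes (d roughly 0.8–1). Raters re-measure each width/height with
additive noise (SD 0.035 IPD, a few pixels at IPD 60 — ordinary
hand-landmarking error); with two raters this yields an emergent
concordance near 0.78. Landmark tables are produced by
`landmarks_from_metrics()`, the exact inverse of `compute_metrics()` on a
symmetric untilted template (round trip < 1e-9 relative error).

**Votes.** Competence is linear in jaw prominence (slope 2.4 on the
rating scale, noise SD 1, implying a jaw-competence correlation near 0.15).
A race's first-candidate share is
`50 + 0.5 * (beta_jaw dJ + beta_competence dC + beta_incumbent dI + beta_age dAge) + noise`,
clipped to (0, 100), the pair summing to 100. Default betas (68 per unit of
jaw-prominence ratio, 5.4 per competence SD, 3 points for incumbency, 0.2
per year of age, noise SD 7.2) were assembled from the population-moment
algebra below to give a candidate-level jaw/vote-share correlation near
0.27, unique-variance partial correlations near 0.25 (jaw) and 0.31
(competence), and a two-predictor R² above 15% — the regime the analysis
stage is meant to detect. Clipping events are counted in the truth sidecar;
they are rare (≈5 SD from the boundary) at the default noise scale.

**Gaze.** Per trial the in-box fixation count is Poisson (mean 6 — about
as many fixations as a 2.5 s window accommodates at a 250 ms mean dwell).
Each fixation independently lands on the left with probability

```
plogis(side_bias + alloc_direct_loser * (loseL - loseR)
       + alloc_jaw * (jawR - jawL)
       + alloc_female * (femL - femR)
       + alloc_age * (ageL - ageR) / 10)
```

Durations are Gamma (shape 2) scaled to the mean dwell, laid out
sequentially with fixed 30 ms gaps (a stand-in for saccade time, not a
modeling claim). When a drawn sequence would overrun the window, durations
are compressed to fit (reserving 1 ms per event against integer rounding),
so the drawn count is always realized — this is what keeps the analytic
accuracy oracle exact. A trial whose Poisson draw is zero still happened;
the generator emits one fixation in the gap between the images so the trial
remains representable in the event format, and it scores as a tie under
every rule — exactly how the oracle scores a zero-fixation trial. Fixation
positions are box centers plus Gaussian jitter clamped inside the box
(cosmetic; side assignment is by construction).

The default allocation route is **emergent**: `alloc_direct_loser = 0`, with
the loser bias arising because prominent jaws win races (`beta_jaw > 0`)
while monkeys avert gaze from prominent jaws (`alloc_jaw > 0`), plus female-
and older-directed biases (`alloc_female`, `alloc_age > 0`). A direct loser
coefficient exists for calibration work.

**Analytic oracle.** `analytic_pair_accuracy()` computes the exact expected
value of (correct + ½·tie) for one race under the fixation-count rule by
summing the Poisson count distribution (truncated at cumulative mass
1 − 1e-12, the residual scored as chance) against the binomial allocation
law, averaged over the two side assignments. It is validated against its own
brute-force Monte Carlo in the tests and drives
`calibrate_loser_allocation()` (monotone root finding for a target expected
accuracy). `expected_jaw_vote_r()` gives the closed-form (delta-method)
population jaw/vote-share correlation implied by a configuration — the
jaw/cheekbone ratio is linearized around the population mean measurements —
and drives `calibrate_jaw_effect()`. The delta-method bias at the calibrated
default is about 0.001 in r, negligible against the sampling SE at the
study's n.

**Randomness.** One integer seed; the roster and gaze substreams derive
their seeds from it deterministically, and identical configurations produce
byte-identical output files.

## What the generator does and does not emulate

It reproduces the design arithmetic (pair counts, gender composition,
office sizes, session structure), the statistical couplings the analysis
targets (dimorphic metrics, jaw-competence-vote structure, loser/female/age
gaze biases), and schema-exact files. It does **not** claim distributional
fidelity for fixation counts or dwell times (Poisson/Gamma/logistic are
modeling conveniences), does not model saccade kinematics, pupillometry,
inter-trial gaze, or reward effects, and its faces are parameter vectors,
not photographs. Passing tests therefore demonstrate that the pipeline's
inference machinery is correct and calibrated under a plausible generative
model — not that any particular empirical effect size is reproduced from
real recordings.

## Numerical and degenerate-input policy

* Times are integer milliseconds from stimulus onset; fixations straddling
  the 2.5 s offset are truncated at read time, later ones dropped; tied
  onsets keep file order with a warning.
* A gaze-bias index with both counts zero is `NA` and propagates as such.
* Degenerate statistical inputs (constant vectors, collinear predictors,
  residual variance ≈ 0 against a control) raise classed errors rather than
  returning fabricated values; "all differences zero" in the paired test
  returns p = 1 with a flag.
* Correlation CIs are Fisher-z; the partial-correlation interval uses an
  effective n reduced by the single control.

## Problem sizes used by the test and acceptance runs

Simulation-backed checks use: 200 session blocks of the full 273-race set
for null calibration; 12 session blocks for the calibrated-accuracy check;
300–400 replicate rosters for the two confidence-interval coverage
properties (the 93% pass proportion is retained from a nominal 95% coverage
level, and the larger replicate counts keep the Monte-Carlo error on the
estimated proportion small relative to that 2-point margin); 100 replicate
500-race rosters in the acceptance script's recovery section; and 50,000
Monte-Carlo trials per setting when validating the analytic oracle. These
sizes make every stochastic assertion sharp at desk scale.

## Known limitations

* The evaluation of accuracy is per session block; per-monkey aggregation is
  available by grouping but is not the default.
* The competence rating is one-dimensional and linear in jaw prominence by
  construction; real competence judgments have structure this ignores.
* `expected_jaw_vote_r()` ignores vote-share clipping (rare at default
  noise) and uses a first-order expansion of the width ratio.
* Spearman confidence intervals reuse the Pearson Fisher-z form.
* The pipeline ingests fixation *events*; parsing vendor raw-sample formats
  and online saccade detection are out of scope, as are photograph handling
  and rating collection.
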