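---
title: "Decoding and conjunction RSA for concurrently planned actions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and conjunction RSA for concurrently planned actions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When people prepare several rule-based actions at once and later select one of
them, how is each plan held in working memory? A useful distinction is between
the *constituent* codes of a plan — the abstract rule, the stimulus location,
the motor response — and a *conjunctive* code (an "event file") that binds
them into one integrated representation unique to that specific action.
`conjrsa` implements an EEG analysis chain built to separate these codes at
the single-trial level and to ask how prioritization and output selection act
on them.

The task model is a rule-selection paradigm: on each trial two bar stimuli
appear at corners of a 2×2 matrix, a shared spatial rule (`vertical`,
`horizontal`, `diagonal`) is cued, and each rule maps the four stimulus
corners bijectively onto four response keys. The two resulting action plans
share the rule but have independent stimuli; colour indicates which plan is
more likely to be tested (70% vs 30%). After a preparation delay, a go cue
selects one plan; responses must beat an adaptive deadline (starting at
1200 ms, stepping by 11.8/23.5/35.3 ms after errors and after runs of five
correct trials). A rule × stimulus combination (with its implied response) is
an *action constellation*; 12 exist per plan. Trials where both plans demand
the same response (25% by design) are generated for fidelity and excluded
from every analysis.

## The analysis chain

1. **Spectral features** (`band_power()`, `build_features()`). Each epoch
   (−200…2200 ms, 250 Hz, 20 scalp channels) is convolved with complex Morlet
   wavelets at 35 log-spaced frequencies from 1 to 35 Hz. The cycle count
   rises from 3 to 10 (log-spaced, mirroring the frequency grid) so that the
   relative bandwidth stays approximately constant; the Gaussian envelope SD
   is σ = n/(2πf). Instantaneous power |conv|² is averaged into delta (1–3),
   theta (4–7), alpha (8–12), beta (13–30) and gamma (31–35 Hz) bands, and
   the 5 band × 20 electrode values at each sample are z-scored across
   electrodes within band, removing anything that drives all electrodes
   uniformly. This yields 100 features per trial and 4-ms sample.

2. **Decoding** (`fit_predict_cv()`, `decode_both_plans()`). At every decoded
   sample an independent 12-way linear discriminant classifier is trained per
   action plan (labels: that plan's constellation), with the pooled
   covariance shrunk toward a scaled identity,
   Σ(λ) = (1−λ)S + λ·mean(diag(S))·I. λ is tuned on a small grid by
   cross-validated accuracy; trials are partitioned into 4 stratified folds
   with near-equal counts of every constellation, all trials (including
   error trials) serve as training data, and out-of-fold class probabilities
   are averaged over repeated randomized fold assignments (8 by default).
   The result is, per trial and time, a 12-vector of classification
   probabilities whose graded confusions carry the similarity structure of
   the underlying neural patterns.

3. **RSA by regression** (`model_vectors()`, `rsa_regress()`,
   `score_timecourse()`). For each trial's true constellation, four
   indicator model vectors over the 12 classes are built: rule-match (four
   1s), stimulus-match (three 1s), response-match (three 1s) and the
   conjunction (one-hot at the true constellation). The logit-transformed
   probabilities are regressed on all four simultaneously, plus an intercept
   and two nuisance regressors (per-constellation mean RT and accuracy,
   z-scored across the 12 cells), so each model's *t*-value reflects the
   unique variance it explains. That *t*-value is the single-trial RSA score
   of the corresponding representation.

4. **Group statistics** (`cluster_permutation()`, `phase_scores()`,
   `behavior_model()`, `behavior_summary()`). Scores are analysed over time
   with trial-level models and cluster-based permutation (clusters of
   consecutive suprathreshold samples, summed-*t* mass, max-mass permutation
   null with condition labels shuffled within subject, positive and negative
   tails tested separately, two-tailed p), averaged within the a priori
   phase windows (encoding 0–750, preparation 750–1500, test 1500–2200 ms),
   and related to trial-to-trial RT (linear mixed model, error trials
   excluded) and accuracy (multilevel logistic regression) with subject
   random intercepts and a random slope on the headline predictor.

## The synthetic-data generator

Every stage is testable without recorded EEG because `simulate_epochs()`
plants the codes the chain is designed to detect. Each feature (shared rule;
stimulus, response, conjunction of each plan) is a stationary unit-norm
random spatial loading per level, amplitude-modulated by trial phase and
carried by a band-limited oscillation (rule→theta, stimulus→alpha,
response→beta, conjunction→theta+beta by default; arbitrary but
configurable). Signals sit in white noise plus a faint per-trial random
oscillatory background in the five bands. During the test phase only,
amplitudes are multiplied by tested/untested gains that may differ by
priority — the generative analogue of output gating. Behavior is simulated
from the design (RT normal by tested priority, truncated at the adaptive
cutoff; priority-dependent error rates split into swap vs other errors) and
is conditionally independent of the EEG given the design, except through an
optional coupling coefficient that shifts RT with the tested plan's
trial-to-trial conjunction amplitude — enabling controlled recovery tests of
the brain–behavior models.

Default behavioral parameters are the empirical condition means of the task
(RT 371/428 ms for high/low tested priority, error rates .11/.22, swap
shares .74/.81 of committed errors, cutoff start 1200 ms). Signal amplitudes
default to values that put 12-way decoding accuracy near 0.10–0.15 — the
realistic regime for this kind of EEG decoding, only modestly above the 1/12
chance level. This choice matters: far stronger planted codes drive the
classifier posteriors onto the logit clipping bound, which degenerates the
RSA regression (see *Numerical choices*).

What the generator does **not** emulate: volume conduction and realistic
channel covariance, 1/f spectra, eye-movement artifacts beyond simple blink
pulses on the EOG channels, non-stationary code topographies, and
autocorrelated behavior. Passing tests therefore demonstrate that the chain
recovers what it is designed to recover under its own generative
assumptions — not that real EEG satisfies those assumptions.

## Numerical choices and degenerate inputs

- **Logit clipping.** Probabilities are clipped to [1e−6, 1−1e−6] before the
  logit. For probabilities inside [1e−4, 1−1e−4] the clipping is inert (no
  *t*-value moves by more than 1e−6).
- **Degenerate profiles.** The per-trial regression has 12 observations and
  ~5 residual degrees of freedom, so its *t*-values are heavy-tailed by
  construction. When a profile is fit (nearly) perfectly — in practice when
  many probabilities collapse onto the clipping bound and tie — the residual
  scale is floored (the *t* stays finite, and a uniform profile still gives
  exactly 0) and the cell is flagged; `score_timecourse()` masks flagged
  cells along with values more than 5 SD from the per-sample mean, and
  reports the masked fraction (≈1% or less in the intended SNR regime).
- **Covariance shrinkage.** A jitter of 1e−8 times the mean variance is
  always added to the shrunk covariance so that λ = 0 remains well defined
  when features outnumber training trials. Tuning ties resolve to the
  strongest shrinkage.
- **Wavelet edges.** Decomposition runs on reflect-padded epochs (1 s by
  default); decompose longer segments upstream when available. Kernels are
  truncated at ±4σ and unit-energy normalized.
- **Band gaps.** Three of the 35 log-spaced bin centres (3.16, 7.29,
  12.30 Hz) fall between the printed integer band edges and belong to no
  band; they are left unused rather than silently reassigned.
- **Fold balance.** Each constellation's trials are dealt round-robin into
  the folds from a randomly rotated start, so class counts per fold differ
  by at most one and every class reaches every training set; a constellation
  with fewer than two trials raises a stratification error.
- **Cutoff floor.** The adaptive deadline is floored at 100 ms so the state
  stays positive under arbitrarily long correct streaks.

## Design choices that were genuinely open

- **Rule geometry.** Only the horizontal rule's mapping is fixed by the task
  description; we take horizontal = left/right reflection, vertical =
  top/bottom reflection, diagonal = both. This affects label bookkeeping
  only, not the pipeline.
- **Penalty form.** "Penalized LDA" is realized as shrinkage-regularized LDA
  with grid {0, .01, .1, .3, .5, 1}; the penalty form and grid are config
  choices (`decoder_spec()`).
- **Cycle progression.** The 3→10 cycle count progression is log-spaced; a
  linear option exists (`wavelet_spec(cycle_spacing = "linear")`).
- **Per-plan regressions.** RSA scores are computed per action plan with
  that plan's own model matrix (the shared rule thus appears once per plan);
  a joint regression across plans was considered and rejected as the default
  because the two plans' profiles live on separate probability simplexes.
- **Permutation statistic.** Inside the permutation loop the per-time
  statistic is the two-stage estimate (per-subject OLS coefficient, then a
  one-sample *t* across subjects); full mixed models per time sample and
  permutation are available (`timecourse_model(method = "lmer")`) but are
  three orders of magnitude slower and in our calibrations agree in the
  strong-effect regime. Random slopes default to the headline predictor
  only. Mixed-model convergence failures fall back to dropping the slope,
  then to the two-stage estimate, with a logged message.
- **Cutoff state.** A single adaptive staircase is maintained across trials
  (as described for the task), not one per priority condition; because
  simulated errors are exogenous Bernoulli draws rather than deadline-driven,
  the simulated cutoff does not reproduce the large empirical cutoff gap
  between priority conditions, and simulated cutoff trajectories drift
  slowly upward at the default error rates.

## Problem sizes used in the shipped checks

The shipped tests and `scripts/acceptance.R` run the chain at desk scale,
chosen once: 6 simulated subjects × 144 trials for the specificity and
output-gating runs (decoding every 20th or 10th 4-ms sample), 500 null
simulations × 200 permutations for the false-positive calibration of the
cluster test, and 20 subjects × 300 trials for the brain–behavior coupling
recovery. The single-code runs plant exactly one code on the high-priority
plan — the stimulus at amplitude 0.6 (all phases), or the conjunction at
0.9/1.0 (preparation/test) with test-phase tested/untested gains 1.8/0.3 —
yielding decoding accuracies near 0.11–0.19. Planting a code on one plan
only matters: a code carried by the *other* plan shares the rule, so
cross-plan confusions legitimately feed the rule model — a property of the
paradigm, not an artifact. Specificity is judged against a matched
all-silent run with the same seeds (the scores' intrinsic null level; see
below) rather than against literal zero, and the onset of the output-gating
interaction cluster is asserted with a 150 ms allowance, about one temporal
σ of the theta-range wavelets (σ_t ≈ 146 ms at 6 Hz), because spectral
estimation smooths planted amplitude steps.

## Known limitations

- Synthetic validation only: no import of recorded EEG beyond the package's
  own flat-binary/TSV containers (EDF/SET readers are out of scope here).
- The RSA *t*-scores have a small method-intrinsic positive bias
  (~0.01–0.08 in mean *t*) even when nothing is decodable: probability
  tails interact with the ~5-df *t* ratio. It is present in an all-silent
  generator run, which is why the shipped checks compare planted runs
  against a matched null run instead of against zero; empirical studies
  using this score should consider the same null-referencing.
- Response-aligned re-epoching, cross-temporal generalization, and
  distance-based RSA variants are not implemented.
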