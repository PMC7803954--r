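---
title: "Decoding speaker identity from fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding speaker identity from fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`voicelight` analyses event-related speaker-identification fMRI: it maps
where local multivoxel patterns allow a classifier to tell three learned
speakers apart, and whether that neural decodability tracks each
participant's behavioural identification accuracy. This vignette documents
the models, the tunable parameters, the synthetic-data generator that stands
in for scanner data, and the numerical and design choices that were
genuinely open.

## The experimental design being modelled

One scanning session is four runs of 36 trials: a fully crossed 12 words x
3 speakers factor, each combination heard exactly once per run, in
pseudo-random order with at most two consecutive trials of the same speaker.
The subject presses one of three buttons within a 5-s answer window;
inter-stimulus intervals follow an exponential law truncated to [3, 5] s.
The repetition time is 0.955 s and 366 volumes are acquired per run. A
learning phase before scanning presents the same crossing twice (72 trials).
`design_spec()` carries all of these as defaults.

Two timing choices are ours:

- **ISI law.** "Exponential, between 3 and 5 s" is implemented as Exp(rate)
  truncated to the bounds by inverse-CDF sampling, with rate 1 s^-1 as the
  default knob. Any truncated exponential satisfies both stated facts; the
  rate only shifts how front-loaded the interval distribution is.
- **Trial spacing.** In the scanner the next stimulus follows the *response*
  by the ISI, so faster subjects finish earlier. Our generator instead
  reserves the full answer window in every trial
  (onset + duration + 5 s + ISI). This keeps event tables independent of the
  simulated responses — responses can be re-simulated without moving
  onsets — at the cost of slightly longer, but still run-fitting, sessions.
  The self-paced schedule is matched in expectation, not trial by trial.

## Behavioural model

Conditional on answering, a trial is correct with probability `ability`;
errors are routed by a row-stochastic kernel whose default sends 70% of the
errors on speakers 2 and 3 to each other (and splits speaker-1 errors
evenly), reproducing the empirical pattern that the two perceptually similar
voices are mutually confusable. Responses are missed with probability
`miss_rate` (default 0.05), independent of correctness, and reaction times
are lognormal (default meanlog 0.19, sdlog 0.37 — mean about 1.3 s, sd about
0.5 s) truncated at the answer window by inverse-CDF sampling. The default
ability 0.624 corresponds to a mean percent correct of 62.4%.

The confusion matrix is the 3 x 3 presented-by-answered table of answered
trials as percentages summing to 100: a perfect responder in a balanced
design shows 33.33% per diagonal cell, a uniform random one 11.11%
everywhere. Missed trials have no answer cell; they are excluded and
reported separately, and `percent_correct()` offers both the excluding and
the counting-as-error denominator.

## BOLD phantom

`simulate_bold()` is a forward version of the first-level model: per voxel,
the signal is the sum over trials of the HRF-convolved stimulus boxcar times
a trial amplitude, plus drift and white Gaussian noise. The amplitude is a
common sound-evoked baseline inside the sound-responsive mask plus, inside
designated informative regions, a speaker-specific multivoxel pattern
(iid Gaussian voxel weights, drawn once per subject and reused across runs)
scaled by a subject-level effect size. Drift is a random combination of
cosines with periods above the 128-s high-pass cutoff, so the GLM's filter
can remove it exactly — which makes filter efficacy a testable property
rather than an assumption.

What the phantom does *not* emulate: anatomical geometry (all subjects share
one small grid, so the spatial-normalization step of a real pipeline is the
identity), physiological noise and motion (noise is white), and acoustic
stimulus properties. Passing tests therefore demonstrate the correctness and
calibration of the *analysis*, not robustness to structured scanner noise.

At the cohort level, abilities are uniform on [0.35, 0.95] — a deliberately
wide spread, emulating a sample recruited for variable voice-recognition
skill — and the neural effect is `(1 - c) * g + c * ability` with `g` an
independent uniform draw on the same range. The coupling `c` is the
generator's scientific dial: `c = 0` is an exact null for the
brain-behaviour correlation analysis, `c = 1` a deterministic monotone
association.

## Single-trial GLM

Each run gets one design matrix: 36 HRF-convolved trial boxcars ("least
squares all" — every trial its own column, not the iterative
one-trial-vs-rest variant), one zero-duration stick regressor at the
response instants (omitted entirely for trials without a response; the
alternative of modelling the window end seemed less defensible and is
flagged here), any supplied nuisance columns, an orthonormal discrete-cosine
basis for periods above 128 s, and a constant. Regressors are built at the
HRF microtime resolution (0.1 s) and sampled at volume onsets. The canonical
HRF is the conventional double gamma (peak 6 s, undershoot 16 s, unit
dispersions, peak:undershoot 6), normalized to unit peak so betas are in
signal units.

Estimation is ordinary least squares per voxel. The phantom's noise is white
by default, so OLS is efficient there; an AR(1) prewhitening option
(`ar1 = TRUE`) is available for serially correlated data. Rank-deficient
designs are fitted on the retained pivot columns and flagged with the
dropped names rather than failing silently.

## Searchlight decoding

The classifier is a soft-margin SVM (C = 1) with one-vs-one multiclass
reduction: one binary SVM per speaker pair, final label by majority vote.
Numerical choices:

- **Kernel.** Linear by default (standard searchlight practice, and the
  natural reading of the design); an RBF kernel is available through
  `classifier_spec()`.
- **Tie-break.** A 1-1-1 vote cycle is resolved to the lexicographically
  smallest label — deterministic and documented, and exercised by a
  constructed-cycle test.
- **Sphere boundary.** At 12 mm radius and 2-mm voxels, strict inequality
  gives 895 in-sphere voxels and non-strict 925. The default is exclusive
  (matching "about 900"); both are exposed.
- **Feature preprocessing.** None by default; optional per-feature
  standardization is estimated on training folds only.
- **Clipped spheres.** Spheres reduced below 10 voxels by the mask edge are
  still classified but flagged on the returned map.

Cross-validation is leave-one-run-out (4 folds) or leave-one-word-out
(12 folds; training never sees the tested word, so above-chance accuracy
implies speaker information that generalizes across phonetic content).
Accuracy is pooled over folds — predictions are collected across folds and
compared to the pooled truth — rather than averaging per-fold rates; the two
coincide for balanced folds, and pooling is well defined when a clipped fold
has fewer trials. The identity accuracy = trace(confusion counts) / total is
asserted on every call.

## Group inference

Per-subject maps are processed in the order: subtract chance (1/3), smooth,
test. Smoothing is a separable Gaussian (FWHM 8 mm by default) with the
kernel renormalized over in-mask voxels, so constants are preserved and no
signal bleeds across the mask boundary.

The one-sample test flips the sign of each subject's whole map at random
(5000 permutations by default, identity always included), recomputes the
voxelwise t, and records the image-wide maximum; the FWE-corrected p at a
voxel is the fraction of permutations whose maximum reaches that voxel's
observed t. This controls family-wise error exactly under the symmetric-null
exchangeability assumption, and including the identity guarantees
p >= 1/n_permutations. The covariate analysis permutes the single covariate
across subjects (simple permutation, not residual-based schemes — exact for
a one-covariate-plus-intercept model under exchangeability), corrects on the
slope t, and reports the squared Spearman correlation per voxel
descriptively. Tests are one-sided by default (above-chance accuracy,
positive brain-behaviour slope), matching the directional hypotheses;
two-sided variants are a flag away.

The explicit sound-responsive mask is applied *before* the permutation
maximum is computed (pass it as the `mask` argument), which can only shrink
the null of the maximum and hence lower corrected p-values;
`apply_explicit_mask()` itself is a pure support restriction and recomputes
nothing. Variance smoothing (pseudo-t) and cluster-mass or TFCE inference
are not implemented — plain voxelwise t only — which is a known fidelity gap
relative to full SnPM-style toolboxes.

Peak tables use 26-connectivity clusters above a statistic threshold, an
extent threshold in mm^3, and greedy local-maxima selection in descending
order with a minimum pairwise separation of 8 mm.

## Confusion-matrix correlations

Spearman rank correlation between two confusion matrices uses all nine
cells by default. With nine cells, an observed rho of about 0.5 paired with
a one-tailed p near 0.08 is what the exact permutation distribution on nine
ranks produces; restricting to the six off-diagonal cells is available via
`cells = "offdiag6"` for analyses that regard the diagonal as
performance-driven rather than similarity-driven. For nine or fewer cells
the one-tailed p is exact (full enumeration of permutations); beyond that
the t approximation is used.

## Problem sizes used in the tests and the acceptance script

The shipped tests run the statistical machinery at scales chosen for a
laptop: phantoms of 4^3 to 6^3 voxels, permutation calibration on 10^3
grids with 12 subjects and 500 permutations over 200 simulated datasets,
and the cohort-recovery experiment on a 4^3 grid with a 2^3-voxel
informative region, 40 subjects and 20 seeds per coupling level. For that
reduced grid the phantom noise is set to sigma = 8 (an SNR calculation, so
that ROI decoding accuracy spans roughly 0.65-0.95 across the ability range
instead of saturating at 1.0 — a saturated map carries no between-subject
variance and no correlation is estimable). The acceptance script uses 16
subjects, the full four-run design, and 1000 permutations, and completes in
about a minute; all sizes are recorded in its JSON output.

Two behaviours of the synthetic setting deserve a note when comparing with
real data. First, leave-one-word-out accuracy is *not* below
leave-one-run-out in the phantom default, because the generator injects no
word-correlated nuisance; the LOWO drop appears exactly when such structure
is added (this is exercised in the test suite). Second, decoding accuracies
are far above the near-chance levels typical of real single-trial fMRI,
because the phantom's informative voxels are, by construction, all
informative.

## Known limitations

- Identity spatial normalization; no anatomy, no atlas labelling.
- White noise default; AR(1) prewhitening is an option, richer noise models
  are not.
- No variance smoothing / pseudo-t; no cluster-mass or TFCE inference.
- The behavioural model draws reaction times independently of correctness.
- The response regressor is omitted for missing-response trials.
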