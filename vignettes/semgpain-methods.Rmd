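---
title: "Modelling pain intensity from facial sEMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pain intensity from facial sEMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patients who cannot self-report pain - sedated or ventilated intensive-care
patients most prominently - are assessed through behavioural cues, of which
facial expression is the strongest. Surface electromyography (sEMG) over
facial muscles can register expression-related muscle activity that is
invisible to observers, which makes it a candidate signal for automatic pain
monitoring. `semgpain` implements a complete analysis pipeline for that
question: given multi-channel facial sEMG recorded while a controlled pain
stimulus (contact heat, or transcutaneous electrical stimulation stepped up
every three seconds) rises from imperceptible to intolerable, how well can
the momentary pain intensity be predicted from muscle activity alone?

The pipeline follows a fixed design: five target muscles (corrugator
supercilii `cor`, orbicularis oculi `orb`, levator labii superioris `lev`,
zygomaticus major `zyg`, risorius `ris`) are recorded at 1000 Hz together
with a frontalis channel used purely as a noise reference. Each test
carries three self-report anchors: stimulus start `t1`, first perceived
pain `t2` (pain threshold) and intolerable pain `t3` (pain tolerance).

## Period labelling

Pain intensity ground truth is ordinal, derived from the anchors by halving
both anchored intervals at integer seconds:

* `P0 = [t1 - 30, t1)` - pre-stimulus baseline,
* `P1 = [t1, t1 + floor((t2 - t1)/2)]`, `P2 = (t1split, t2)` - below
  threshold,
* `P3 = [t2, t2 + floor((t3 - t2)/2)]`, `P4 = (t2split, t3]` - above
  threshold.

The published definition of the second split point is typographically
garbled in its source table; by symmetry with the first split and from how
P3/P4 are used downstream it is implemented as `t2 + floor((t3 - t2)/2)`.
Rows (1-s feature windows) are assigned by window-start time; windows are
aligned to the recording start because no alignment convention is stated
anywhere. P0 is excluded from all statistics and modelling (it is
contaminated by talking, which was only prohibited during stimulation), but
it is included in the per-test standardization so that "no pain" activity
anchors each test's z-scores.

## Preprocessing and features

The chain is fixed and ordered: (1) 20-Hz Butterworth high-pass (order 4,
applied forward-backward so event anchors stay phase-aligned; the order is
our choice, standard for sEMG movement-artifact removal), (2) adaptive
noise cancellation of each muscle channel against the high-pass-filtered
frontalis reference - a normalized LMS filter (32 taps, step 0.1, both
configurable), which removes the 50-Hz mains component and the
electrical-stimulation pulse artifacts that the reference shares with the
muscle channels, (3) non-overlapping 1-s windows reduced to RMS and
waveform length (WL) per muscle, giving the ten features
`corrms ... riswl`, (4) a Hampel filter (half-window K = 3, threshold t = 3
robust SDs, edges truncated) on each 1-Hz feature series to remove residual
high-amplitude artifact spikes, and (5) per-test z-scoring (population SD,
P0 included; a zero-variance feature is set to 0 with a warning rather than
propagating NaN).

The adaptive-cancellation algorithm is not specified beyond being an
adaptive reference-channel scheme; NLMS is the classical choice and is
stated as an assumption. Swapping steps 4 and 5 changes results on spiky
data, and the suite regression-tests the order.

## The synthetic cohort

No recordings were published for this design, so the package ships a
generator whose defaults *are* the study conditions: 31 subjects, four
tests each (two heat, two electrical, alternating sides), four tests
excluded at random, 124 - 4 = 120 analyzed tests. Durations are truncated
normals per stimulus type (heat `t2 - t1 ~ N(70, 38^2)`,
`t3 - t2 ~ N(40, 32^2)`; electrical `N(48, 28^2)`, `N(36, 28^2)`; floor
8 s so every period holds at least two 1-s rows), calibrated so the 120
analyzed tests average about 110 s (SD about 42 s).

Each muscle channel is an amplitude-modulated band-limited (20-450 Hz)
Gaussian carrier: `x(t) = a(t) * w(t)` with
`a(t) = noise_floor * (1 + g * f(t) * u(t))`. The shape `f` is a linear
ramp from `t1` to `t3` for the corrugator and from `t2` to `t3` for the
other muscles (they activate only once pain is perceived, the corrugator
tracks the stimulus throughout). Three multiplicative structures sit on
top:

* **Expressiveness.** `g` is a per-muscle base gain (corrugator strongest)
  times a per-subject log-normal expressiveness factor (log-SD 0.9) with a
  20% low-expressive mixture at one-quarter scale, times a mild per-test
  jitter. This is what produces subjects ranging from nearly random to well
  predicted.
* **Expression fluctuation.** `u(t)` is a slow mean-one log-normal process
  (Ornstein-Uhlenbeck on the log scale, correlation time 10 s, log-SD
  1.25). Facial expression is episodic - muscles flare and relax even under
  a monotone stimulus - and without this term the ramp would be almost
  perfectly recoverable after z-scoring at any gain, which no real cohort
  shows.
* **Spectral shift.** The carrier is a mixture of a low (20-150 Hz) and a
  high (150-450 Hz) band whose high-band weight grows with activation.
  Contracting muscle shifts sEMG power upward in frequency, so WL (which
  responds to amplitude times mean frequency) carries strictly more pain
  information than RMS (amplitude only). This reproduces the empirical
  pattern that waveform-length features dominate both the period
  correlations and the selected model.

Artifacts: talking bursts on the lower-face channels before `t1`
(per-second Bernoulli bursts), shared 50-Hz interference, slow drift,
sparse high-amplitude biphasic spikes (Poisson 0.02/s), and - in electrical
tests only - 100-Hz pulse bursts every 3 s with stepwise-growing amplitude,
injected coherently into the frontalis reference so cancellation can remove
them. The reference channel carries its own EMG noise but no
pain-modulated envelope, and no spikes (a spiky reference would let the
canceller inject spikes into clean channels, at odds with its role).

**Calibration.** Duration parameters were set by Monte Carlo against the
110/42-s summary; the envelope parameters (`gain_scale = 0.045`,
expressiveness log-SD 0.9, fluctuation log-SD 1.25, spectral shift gain
0.55) were fixed once so that the full pipeline lands near the reference
performance levels (nested-CV aggregate c-index about 0.63, final LOSO mean
about 0.64, per-subject spread roughly 0.5-0.8, corwl-vs-period Spearman
near 0.33) and were not revisited afterwards. What passing these checks
shows is that the pipeline reproduces the *statistical signature* of the
study on data with the assumed generative structure - not that the
generator reproduces facial physiology. In particular the generator has no
motor-unit structure, no electrode crosstalk, no habituation across tests
and no stimulus dose-response model; those are out of scope.

## Statistics

Subject-level feature medians are computed per period P1-P4, pooling each
subject's heat and electrical tests (the design intends one general model,
not per-stimulus models). Period pairs are compared with two-sided Wilcoxon
signed-rank tests on those medians (zero differences dropped; exact
distribution up to 25 nonzero pairs, normal approximation with continuity
correction beyond; two-sided because the reported grids contain p-values
near 1, which one-sided tests would rarely produce). Raw p-values are
reported without multiple-testing correction, matching the descriptive role
of the grid. Feature relevance and redundancy are summarized by Spearman
correlations among the ten features and against the ordinal period index.

Feature screening defaults to the fixed candidate set
`{corrms, corwl, levwl, orbwl}` - the corrugator pair plus the two
waveform-length features of the muscles that react at threshold. An
automatic mode (rank by |rho| against the period, greedily drop features
correlated above 0.80 with a better-ranked keeper, cap at four) is provided
for new data.

## The ordinal model

A k-nearest-neighbour classifier predicts the period label P1-P4 from the
standardized features (Euclidean distance; voting ties resolve to the lower
ordinal label, then smaller mean neighbour distance - the first rule
already decides). Performance is the concordance index: the fraction of
row pairs with different true labels that the predictions order correctly,
ties credited one half. It generalizes AUC to ordinal outcomes and is
insensitive to class imbalance; 0.5 is chance.

Model selection is nested leave-subject-out cross-validation: the outer
loop holds out one subject entirely (within-subject dependence would
otherwise leak), the inner loop scores every non-empty subset of the four
candidate features crossed with every odd `k` in 1-31 by inner
leave-subject-out c-index, and the inner argmax (ties: smaller subset, then
smaller k) is refit and scored on the held-out subject. The aggregate is
the unweighted mean of per-subject fold c-indices (per-subject averaging,
matching a per-subject performance profile with a mean line, rather than
pooled pairs). The final model is the modal selected subset across folds
with its modal k, evaluated by plain leave-subject-out CV.

Significance is a permutation test: labels are permuted within each test
(preserving each test's label distribution and the subject/test structure
the CV relies on - the permutation granularity is our choice, as only
"randomized labels" is specified), the entire nested CV is re-run per
permutation, and the add-one p-value `(1 + #{null >= observed}) / (1 + B)`
is reported. The canonical B is 1000; 200 is the desk-scale default and
already bounds p below 0.005 when the observed statistic beats every null.

### Numerical and implementation notes

* The nested search and permutation loop run in compiled code on
  precomputed per-subset nearest-neighbour tables (top 256 per row among
  other-subject rows, ordered by distance then row index); fold exclusions
  are applied while walking a list, with an exact full-scan fallback if a
  fold exhausts it. The compiled path is verified against a plain-R nested
  CV assembled from the exported `knn_predict()` and `c_index()`.
* The c-index is computed from the label-by-prediction contingency table,
  which makes the 10,000-row chance-level check instantaneous.
* Degenerate cases are defined, not accidental: folds whose held-out
  subject has fewer than two distinct labels are skipped with a warning;
  an all-zero-difference Wilcoxon returns p = 1; zero-variance features
  standardize to 0; a zero-variance noise reference disables cancellation
  with a warning; a test with an empty pain period is excluded from
  modelling with a message.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full default cohort
(31 x 4 - 4 = 120 tests, about 110 s each) for the headline estimates:
five replicate cohorts for the duration, meta and final-model levels, and
200 within-test permutations on one replicate for significance. The
supporting property checks use scaled-down cohorts chosen for their
purpose: twenty 12-subject/2-test cohorts for the feature-ranking Monte
Carlo, ten 8-subject null cohorts (zero gains) for the no-information
checks, and fabricated feature-space tables (noise features with a known
ordinal coupling) for the model-machinery oracles, where signal synthesis
would add nothing. The threshold-contrast (P2 vs P3) check runs on the
default-scale replicates because that contrast is a full-cohort property;
at a quarter of the sample size its power drops below a useful assertion
level.

## Known limitations

* The generator's envelopes are piecewise-linear with multiplicative
  log-normal fluctuation - the simplest shapes consistent with the
  described median profiles; real expression dynamics are richer.
* Carrier bandwidth (20-450 Hz) and the low/high split at 150 Hz are
  conventional choices; the acquisition chain they stand in for is not
  modelled.
* Inter-muscle correlation arises only through shared expressiveness and
  shared artifacts; electrode crosstalk between neighbouring muscles is
  not simulated, so the feature inter-correlation matrix is flatter than
  a real monopolar montage would give.
* With two features and k up to 31 the kNN model is deliberately small;
  no alternative learners are in scope.
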