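---
title: "Identity confounding in reach-to-grasp classification: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identity confounding in reach-to-grasp classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Repeated-measures classification studies — many movements recorded from each
child, a diagnostic label per child — are vulnerable to *identity
confounding*: when records of the same individual land in both the training
and the test set (record-wise cross-validation), a classifier can solve the
easy task of recognizing *who* moved instead of the hard task of recognizing
*which group* they belong to. Movement is a strong biometric: individuals
show kinematic signatures that are consistent within and different between
persons. Because every signature is perfectly associated with one diagnostic
label in the sample, identity recognition masquerades as diagnostic
classification and record-wise accuracies can reach ceiling without any
group-discriminating information in the data.

`reachcv` implements the full diagnostic toolkit around this problem for
reach-to-grasp kinematics: feature extraction from 3D hand-marker
trajectories, record-wise / subject-wise / hybrid cross-validation with
nested hyper-parameter tuning, subject-level aggregation of record
posteriors, and subject-block permutation nulls — plus a hierarchical
synthetic movement generator so that every claim is testable without
clinical data (which are not publicly deposited for studies of this kind).

## Kinematic feature model

A trial is the 100 Hz trajectory of 8 hand markers during a reach towards a
bottle placed 44 cm from the midline. Processing follows standard motion
analysis:

1. marker gaps up to 100 ms are filled by cubic interpolation; trials with
   more than 10% incomplete frames or any longer gap are discarded as poor
   reconstructions (the exclusion log enumerates them);
2. positions pass a 2nd-order 6 Hz low-pass Butterworth filter, applied
   forward and backward (zero phase). Edges use odd-reflection padding with
   steady-state initialization, so constants pass through exactly;
3. wrist speed is the magnitude of the 3D position derivative (central
   differences, one-sided at the ends); acceleration and jerk are the first
   and second derivatives of speed; grip aperture is the thumb to index-tip
   distance; wrist height is the vertical wrist coordinate;
4. movement onset/offset: speed must exceed 20 mm/s for at least 50 ms
   (onset) and fall back below for at least 50 ms (offset). The rule anchors
   on the suprathreshold run containing the global speed peak rather than
   the first sustained run: zero-phase filter edge transients and one-sided
   end derivatives occasionally push rest-period speed briefly above
   threshold, and the first-run rule then returns pathological bounds
   (onset at frame 0, offset a few frames later). Anchoring on the peak run
   gives identical results on clean data and is robust under measurement
   noise. Threshold and sustain time are configurable;
5. each of the five variables is linearly interpolated at 10%, 20%, ..., 100%
   of movement duration — ten deciles, not eleven grid points including 0%,
   reading "at intervals of 10%" as deciles — and concatenated (velocity,
   acceleration, jerk, aperture, height) into a 50-element feature vector.

## The synthetic generator

The generator emulates the hierarchical structure the analyses assume, not
biomechanics. The wrist transport is a *minimum-jerk reach with a landmark
time-warp*: along-track position is `d * pbeta(tau, a, b)` with
`a = 1 + 4*pf`, `b = 5 - 4*pf`, so tangential speed is
`(d/T) * dbeta(tau, a, b)`, bell-shaped with its peak at fraction `pf` of
movement duration. At `pf = 0.5` this is exactly the minimum-jerk profile
with peak speed `15 d / (8 T)` at mid-movement — a closed form the tests use
as a free oracle. Grip aperture and wrist height follow beta-shaped arcs;
the marker cloud rides rigidly on the wrist path with the thumb/index-tip
separation driven by the aperture curve; i.i.d. Gaussian jitter (0.5 mm,
an optical-capture error magnitude) is added per frame, and 0.3 s of
stationary rest pads each side so onset/offset detection is genuinely
exercised.

The hierarchy has three layers:

* **subject signatures** — Gaussian random effects on duration (SD 0.10 s),
  amplitude (20 mm), peak-speed fraction (0.03), peak aperture (6 mm), rest
  aperture (3 mm), height arc (8 mm) and aperture-peak fraction (0.02).
  `subject_sd` scales all of them (default 1);
* **trial variation** — the same SDs scaled by `trial_sd` (default 0.1, i.e.
  a 10:1 between:within SD ratio, the identity-signature regime in which
  record-wise classifiers reach ceiling from identity information alone);
* **group effect** — the ASD-like group's peak-velocity landmark occurs
  `group_timing_shift` later as a fraction of duration (default +0.05, a
  deliberately small effect concentrated in landmark timing; it can be given
  per intention to emulate effects concentrated in pass/pour movements).

Intention effects (pour: +0.03 s duration, +2 mm aperture, -0.01 peak
fraction; pass: -0.02 s, +1 mm, +0.01) are deliberately *subtle* — fractions
of the between-subject SDs. This calibration reproduces the qualitative
regime of the motivating study design: prospective intention is decodable
from the reach only modestly above chance, while subject identity is
decodable near ceiling. An early draft with duration offsets of ±0.1 s made
intention the dominant within-subject variance source, which contradicts
that regime; the offsets were reduced accordingly (and the rest-aperture
signature added) before the acceptance checks were frozen.

What the generator does **not** emulate: finger articulation, within-trial
submovements and corrections, heteroscedastic or autocorrelated capture
noise, age/IQ covariates, and any feature of real ASD kinematics beyond a
timing shift. Passing tests therefore show that the *pipeline* behaves
correctly under the assumed hierarchical structure — they are not evidence
about real clinical data.

## Classifiers and cross-validation

Three families: Gaussian-kernel SVM (`e1071`/libsvm), L1-regularized
logistic regression (`glmnet`; the linear, lasso-shrunk reading of
"SVM-LASSO"), and random forest (`ranger`, 500 trees). Features are z-scored
with training-fold statistics only; the SVM posterior score is the
logistic-squashed signed margin (glmnet and ranger report model
probabilities), oriented so 1 = ASD. A subject's group is the sign of the
mean posterior of its held-out records, with an exact tie going to TD —
deterministic and conservative toward non-diagnosis.

Fold schemes carry the structural constraints of the design:

* *record-wise k-fold* (k = 10 or 40): each fold holds exactly 40/k records
  of every subject, drawn at random within subject;
* *intention-balanced record-wise*: one movement per subject per intention
  per fold (600-record intention task);
* *subject-wise*: all records of a subject share one fold; default
  leave-one-subject-out, optionally group-balanced k-fold;
* *hybrid*: leave-one-subject-out outer testing with record-wise inner
  tuning — the regime that reveals whether record-wise tuning generalizes
  to unseen individuals.

Hyper-parameters are tuned recursively on all but one fold of the training
set and tested on the remaining fold, the inner splitter reusing the outer
scheme's remaining folds. For leave-one-subject-out outer folds the inner
splitter is a group-balanced 5-fold subject-wise split: inner LOSO would
multiply cost by ~40 for no statistical gain, and subject-disjointness — the
property that matters — is preserved. Grids: SVM-G cost {0.1, 1, 10, 100} x
gamma 10^-3..10 (5 points); lasso lambda 10^-3..10 (7 points); RF mtry
{sqrt(p), p/3}. Ties resolve to the smoothest model (smallest cost, then
smallest gamma). Two deliberately smaller specifications exist:
`model_spec_compact()` (cost {1, 10} x gamma {0.02, 0.2}, bracketing the 1/p
heuristic; it contains the argmax of the full grid on this problem class)
for headline tuned runs, and `model_spec_reduced()` (a single point, cost 1,
gamma 1/p) wherever a model is re-fit hundreds of times — permutation nulls
and the 40-class identity analysis, where tuning is immaterial.

## Permutation nulls and the confounding diagnosis

Significance uses permutation statistics with the add-one estimator
`p = (1 + #[null >= observed]) / (1 + n_perm)` (100 permutations by
default). Two relabelling schemes:

* **subject-block**: diagnostic labels are shuffled across subjects as
  units. This *preserves* the identity-label confound while destroying the
  label-feature relationship. A record-wise null centred above 0.5
  therefore diagnoses identity confounding (the classifier still recognizes
  individuals and reads off their permuted labels); the flag is a one-sample
  t test of the null mean against 0.5 at alpha = 0.05;
* **record-level**: labels shuffled across individual records, breaking
  both associations — the matched null for intention tasks.

Genuine group information is claimed only when the observed accuracy exceeds
its scheme-matched null (p <= 0.05 subject-wise).

## Problem sizes and numerical choices

All stochastic checks run at sizes chosen for a single CPU; they are the
package's own study designs and are stated here once:

* headline dissociation: the full 40 x 40 design (1600 movements);
* permutation-null geometry in the test suite: 20 subjects x 20 records;
  the acceptance script uses the full design with 100 permutations;
* the leave-one-subject-out permutation null scores a fresh random 20 of the
  40 outer folds per permutation (training always on all 39 remaining
  subjects). Per-fold held-out correctness is exchangeable across folds, so
  the reported null mean is unchanged in expectation while the libsvm refit
  count halves;
* type-I error of the subject-wise permutation test: 50 replicate null
  datasets of 10 subjects x 8 records, 50 permutations each, alpha 0.05,
  bound alpha + 2 SE;
* timing-shift recovery: 100 subjects per group x 2 trials. With 20
  subjects per group the between-subject SD (0.03) puts the Monte-Carlo SE
  of the group-mean difference at the edge of the ±0.01 recovery band; 100
  per group is the design that actually identifies a 0.05 shift at that
  precision.

Other numerical choices: derivative-of-speed (not triple filtering) for
jerk; linear interpolation on the decile grid; standardization guards
(zero-variance features get unit scale); degenerate generator draws are
clamped (duration >= 0.3 s, peak fraction in [0.2, 0.8], apertures
positive); `pooled_t` returns signed infinity with a warning when the pooled
variance is zero with a nonzero mean difference; sign tests discard ties and
return p = 1 when everything ties.

## Known limitations

* The generator's identity signature lives in seven scalar parameters; real
  signatures are higher-dimensional, so the generator likely *understates*
  how easily real individuals are recognized.
* SVM posterior scores are squashed margins, not calibrated probabilities;
  only their order and the 0.5 threshold matter for subject aggregation.
* The exclusion criterion for poor marker reconstruction (>10% incomplete
  frames or a gap >100 ms) is this package's operationalization; published
  studies rarely state theirs.
* Learning-curve record-wise training pools include the test subjects'
  remaining records (all but 4 per subject) — the reading under which
  record-wise curves are flat at ceiling; a stricter reading would exclude
  them and reproduce the subject-wise curve instead.
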