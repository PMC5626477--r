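---
title: "Simulating and analysing covert connectivity neurofeedback"
author: "covertnf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing covert connectivity neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Covert connectivity-based neurofeedback reinforces desired brain-network
states without telling participants what is being trained. A scanner
session streams BOLD signal from three small regions of interest — two
training targets that are under-connected in the clinical group, and a
control region that is over-coupled to target 1 — and every TR (2 s) a
decision is made: if the two targets just moved in the same direction
while the control moved in the opposite direction, a reward is delivered
(a puzzle piece of a hidden picture plus a positive sound; 25 pieces
complete a board). Over training days this selectively reinforces a
differentiated network state: coupled targets, decoupled control.

`covertnf` implements the decision engine, the offline connectivity and
learning statistics, the voxelwise change maps with cluster-size
permutation correction, and the brain–behaviour analyses — together with
a seeded synthetic cohort generator so that every stage is testable
without access-restricted human data.

## The two-point decision rule

For ROI mean signals $m_r(t)$, the increments
$\Delta_r(t) = m_r(t) - m_r(t-1)$ determine firing:

$$\text{fired}(t) \iff
\operatorname{sign}\Delta_{T1} = \operatorname{sign}\Delta_{T2}
= -\operatorname{sign}\Delta_{C}, \quad \Delta_r(t) \neq 0\ \forall r.$$

The original statement of the rule uses signs of increment *ratios*
($\Delta_{T1}/\Delta_{T2} > 0$ and $\Delta_{T1}/\Delta_C < 0$), which is
undefined when an increment is exactly zero. We compare signs directly
(algebraically equivalent for nonzero increments, no 0/0) and adopt the
conservative tie rule that an exactly zero increment never fires; zero
increments have measure zero for continuous signals, so this only
matters for degenerate inputs. Under independent continuous increments
exactly 2 of the 8 equiprobable sign triples fire, giving the analytic
chance rate of 1/4 that both the test suite and the acceptance script
verify by simulation.

`kpointAgreementScore()` generalises the rule to sliding windows of
length $k \in \{2,\dots,6\}$ (stride 1): a window counts when its
within-window Pearson correlation is positive between the targets and
negative between target 1 and the control. No window semantics are
prescribed anywhere for $k > 2$; sliding windows with sign tests on
within-window correlations are our design choice, chosen so that $k = 2$
reduces exactly to the deployed rule. The chance level is 1/4 for every
$k$: conditionally on the target-1 window, the two correlation signs are
independent with probability 1/2 each.

## Connectivity measures

Per run we report the three pairwise Pearson correlations, their Fisher
transforms $z = \operatorname{atanh} r$, and the composite difference
measure

$$\text{composite} = r_{T1,T2} - \tfrac12\,(r_{T1,C} + r_{T2,C}),$$

which increases when the targets couple and the controls decouple — the
exact state the feedback rewards. Day-level aggregation and the
permutation contrasts operate on the raw correlation scale by default
(the convention of the ROI-level analyses we mirror); every aggregation
also carries the Fisher-z columns so contrasts can be run on the z scale
by passing `measure = "z_t1t2"` etc. The voxelwise maps always work on
the z scale.

`validateProxy()` checks that the two-point score is a usable proxy for
offline correlation: across runs spanning programmed coupling levels the
fired fraction should be monotone in true coupling and strongly
correlated with the offline Pearson estimate. The proxy score is the
fired *fraction* (not count), making it invariant to run length. Because
pooling convention is unreported in the original validation, the report
includes both the pooled-across-runs correlation and per-subject
correlations.

## Learning statistics

Day contrasts are paired within subject: the statistic is the mean
within-subject change (day B − day A), and the null is built by
independently exchanging each subject's two day labels — equivalently
flipping the sign of that subject's change — with add-one smoothing, so
p-values are never exactly zero and floor at $1/(n_{\text{iter}}+1)$.
Two-tailed by default (`tail = "one"` available); the source analyses do
not state a tail convention, and two-tailed is conservative. Contrasts
are shuffled pairwise per contrast rather than jointly across all four
days (the other unreported choice); with paired sign flips the two are
equivalent for any single contrast.

`subsetRobustness()` re-runs the contrast on every subset of 10
participants (19 448 subsets for a cohort of 17). A single sign-flip
matrix, drawn independently of the data, is shared across subsets: each
subset's p-value is still a valid permutation p, and the enumeration
vectorises. `groupInteraction()` is Welch's unequal-variance t-test via
`stats::t.test`, with the degenerate both-groups-constant case resolved
by convention (t = 0, p = 1 for equal means). `retentionAnalysis()`
computes per-subject retention fractions
$(\text{followup} - \text{day1})/(\text{day4} - \text{day1})$, excluding
(with a warning) subjects whose trained change is exactly zero, and
correlates retention with elapsed weeks using the same permutation
machinery.

## Voxelwise change maps and cluster correction

Per run, every voxel's correlation with the mean seed-ROI series is
Fisher-transformed; with a reference ROI the map is the differential
$z_{\text{seed}} - z_{\text{ref}}$. Maps are averaged over runs within
day, the day-1 average is subtracted from the day-4 average, and a
one-sample t-test across subjects flags consistent change. Correlations
of magnitude 1 (a voxel against itself inside the seed) are capped at
$\operatorname{atanh}(0.999999)$; seed/reference voxels are flagged and
excluded from peak reporting, since their values are self-correlations
by construction. Constant voxel series yield `NA` and are excluded
voxelwise, with counts reported.

Cluster correction follows the paired-permutation logic: exchanging a
subject's day labels negates that subject's change map exactly, so the
null is generated by per-subject sign flips (the test suite asserts
this equivalence on fixtures). Sign flips leave each voxel's sum of
squares invariant, so permuted t maps come from one matrix product —
exact, not approximate. Clusters use faces-only 6-connectivity (the most
conservative standard neighbourhood; the connectivity level was not
specified originally), implemented in C++ because labelling runs inside
the permutation loop.

Five voxelwise thresholds (p = 0.05, 0.01, 0.005, 0.001, 0.0005) each
get a null distribution of maximum cluster sizes, and the union mask
keeps voxels surviving at any threshold. Calibrating each threshold
marginally at $\alpha$ lets the union familywise error reach
0.10–0.15 on pure noise, because the strict-threshold nulls are nearly
independent. The default (`jointCalibration = TRUE`) therefore tightens
the shared per-threshold level until the permutation probability that
*any* threshold yields a surviving null cluster is at most $\alpha$ — a
max-statistic correction across the threshold family — so the union
mask itself controls the familywise error. `jointCalibration = FALSE`
restores marginal control per threshold.

## The synthetic cohort generator

The generator defines the study conditions and is itself first-class,
tested code. ROI-level signals are latent multivariate Gaussian
innovations with a programmed inter-ROI correlation matrix, passed
through an AR(1) filter with a coefficient shared across ROIs — shared
coefficients mean the stationary cross-correlations equal the innovation
correlations, so programmed values survive filtering — rescaled to unit
variance, plus an additive slow sinusoidal drift per ROI (random
frequency 0.5–2 cycles/run, random phase). Defaults:

* 17 ASD-like subjects (10 TD-like); days day1–day4 plus a follow-up;
  2 rest + 4 feedback + 2 rest runs per day; 270 TRs per run at 2 s.
* ASD-like baseline pairwise correlations (0.10, 0.25, 0.10) for
  (target1–target2, target1–control, target2–control): weakly coupled
  targets, over-coupled control. Programmed day-4 deltas
  (+0.11, −0.13, −0.03), i.e. a composite change of 0.19, ramping over
  days as 0, 0.4, 0.75, 1 with 0.9 retained at follow-up. The TD-like
  arm starts well connected (0.50, 0.05, 0.05) and is programmed flat,
  emulating orthogonal training.
* AR(1) coefficient 0.3 (BOLD-like smoothness at TR = 2 s), drift
  amplitude 0.2 in units of the unit signal SD, unit innovation SD.
  Signals are z-scored latents in arbitrary units; no attempt is made
  to mimic scanner intensity scales.

Independent per-ROI drift attenuates empirical correlations by the
factor $1/(1 + A^2/2)$ (≈ 0.98 at the default amplitude); the programmed
0.2 recovery experiments measure ≈ 0.196 for exactly this reason, and
the acceptance tolerance (±0.03) accommodates it. Requested day
matrices are validated for positive semidefiniteness; invalid requests
fail naming the offending day, or, with `repairPsd = TRUE`, are
repaired by eigenvalue clipping (off by default) and recorded in the
output's `repairedDays` attribute.

The voxel-grid generator places three spherical ROIs (radius 4 mm) on a
24³ grid of 3.2 mm voxels (the acquisition geometry of the emulated
study) with a centered affine. Each ROI sits inside a larger coherent
"network" sphere (`networkRadiusMm`, default 6 mm, 27 voxels): network
voxels are `voxelLoading` (0.9) times their latent network signal plus
independent noise, background voxels are pure noise, and the three
latents follow a per-day coupling trajectory. The network radius
exceeding the ROI radius reflects that training-induced changes spread
over networks larger than the feedback ROI. The default 24³ grid cannot
contain the real training coordinates (they span > 100 mm);
`talairachCenters()` provides them for larger grids
(e.g. `gridShape = c(48, 48, 48)`).

The behavioural generator links per-subject SRS change (pre − post, so
positive = symptom reduction) linearly to connectivity change with
Gaussian noise, generates BRIEF change as pure noise (the non-social
control scale), and can inject outliers guaranteed to exceed 3 SD of a
synthetic reference test–retest sample — large and *negative*, matching
the direction observed in practice. The reference distribution stands
in for an independent test–retest dataset that is not publicly
available; it is plain Gaussian and labelled synthetic.

What the generator does **not** emulate: hemodynamic response
convolution, motion or physiological artifacts, scanner drift
nonstationarity, spatial autocorrelation of noise, or heterogeneous
per-subject training efficacy. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the stated
generative model — not that real data meet that model.

## Brain–behaviour analyses

Change scores use the post-training rest on the last day minus the
first day's pre-training rest (the scope is configurable). Outliers are
flagged outside mean ± 3 SD of the reference change distribution (the
multiplier is configurable); `brainBehaviorCorrelation()` always
reports the analysis both with and without flagged outliers, and the
partial correlations residualise both variables on the covariates
(baseline behaviour, baseline rest, or the control scale's change) —
equal to the closed-form partial-correlation identity for one
covariate, which the tests assert to 1e−10. Permutation p-values
(subject-label shuffling, seeded) are used throughout; whether outlier
exclusion also applied to the baseline-controlled analyses is ambiguous
in the source, so callers choose the flags they pass.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen as: 1 000 random runs for the decision-oracle equivalence; 10⁶
decisions for the chance rate; 250 runs over five coupling levels for
proxy validity; 1 000 null cohorts (17 subjects, 2 feedback runs/day,
60 TRs, 500 permutation iterations) for contrast calibration; 100
cohorts at full run length (270 TRs, 4 runs/day) for the 0.2-composite
recovery; 50 pure-noise replicates (24³, 500 permutations, 5 and 17
subjects) for the cluster familywise error; and 20 planted-effect
replicates (10 subjects, 2 runs/day, 135 TRs) for peak recovery. The
acceptance script reproduces the same quantities at somewhat smaller
replicate counts and reseeds every stage from `--seed`.

Other numerical conventions: permutation p-values use add-one
smoothing; all RNG consumption is localised (`withSeed`) so generators
never perturb the caller's RNG state; child seeds are derived
deterministically per subject/day/run so any subset of a voxel cohort
regenerates identically; Fisher z of |r| = 1 is capped as above; and
`subsetRobustness()` refuses enumerations beyond 10⁶ subsets unless
asked to sample.

## Limitations

The pipeline ingests preprocessed signals; despiking, motion
correction, nuisance regression and registration are out of scope. The
TSV/NIfTI readers cover the package's own artifacts, not arbitrary BIDS
layouts. Day-contrast inference assumes exchangeability of the two day
labels within subject; the voxel correction assumes the paired-design
sign-flip equivalence, which holds exactly for day-difference maps but
not for unpaired designs. Reported p-values for the small family of
planned day contrasts are uncorrected, matching the convention of the
analyses this package mirrors.
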