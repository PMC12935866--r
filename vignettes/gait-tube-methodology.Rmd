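---
title: "Phase-dependent gait-tube analysis of COM-velocity variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-dependent gait-tube analysis of COM-velocity variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaittube)
```

## The model

During steady-state treadmill walking, the body's center of mass (COM)
traces a nearly periodic loop in velocity space.  How tightly that loop is
reproduced from stride to stride is a continuous, phase-dependent measure
of gait stability: a healthy walker lets the COM velocity vary
substantially (especially vertically), whereas constrained, "stiffened"
gait — as described in populations such as peripheral artery disease
(PAD) — collapses that variability.

`gaittube` quantifies this as follows.  Each subject's COM position is the
frame-wise mean of the five pelvis markers (sacrum, bilateral ASIS,
bilateral PSIS), low-pass filtered and differentiated to velocity
$v(t) \in \mathbb{R}^3$ in the anatomical axes AP/ML/VT (mm/s).  Heel
strikes detected from the vertical ground reaction force cut the record
into gait cycles, each time-normalized to $T$ points spanning 0–100% of
the cycle.  Stacking $S$ strides gives the core tensor
$v_{s}(t_j),\ s = 1..S,\ j = 1..T$.

At every normalized instant the $3\times 3$ stride-to-stride covariance

$$\Sigma_j = \frac{1}{S-1}\sum_{s=1}^S
  (v_s(t_j) - \bar v(t_j))(v_s(t_j) - \bar v(t_j))^\top$$

defines a variability ellipsoid with semi-axes $k\sqrt{\lambda_i}$
(eigenvalues $\lambda_i$ of $\Sigma_j$) and volume

$$V_j = \tfrac{4}{3}\pi k^3 \sqrt{\det \Sigma_j}
  \quad [\mathrm{mm^3/s^3}].$$

The square roots of the diagonal of $\Sigma_j$ are the direction-specific
variability waveforms; their cycle means are the AP/ML/VT variabilities,
and their sum is the *total variability* (mm/s).  Projecting each
ellipsoid onto the plane spanned by the Frenet–Serret normal and binormal
of the mean velocity trajectory, and smoothing the projected covariances
with a circular moving average, yields the "gait tube": the mean loop with
variability cross-sections that retain anatomical context.

Group inference uses three complementary layers:

* **Cycle-averaged scalars** (ellipsoid volume, directional SDs, total
  variability) compared with Wilcoxon rank-sum tests;
* **Waveforms** ($V_j$ over the cycle) compared with a permutation form
  of one-dimensional statistical parametric mapping (SPM): point-wise
  two-sample $t$, family-wise control via the permutation distribution of
  $\max_j |t_j|$, suprathreshold-cluster p-values, and aggregation over
  the eight clinical gait phases (Initial Contact 0–2%, Loading Response
  2–12%, Mid Stance 12–31%, Terminal Stance 31–50%, Pre-Swing 50–62%,
  Initial Swing 62–75%, Mid Swing 75–87%, Terminal Swing 87–100%);
* **Coordination**: within-group Pearson correlation between ellipsoid
  volume and total variability, with the two independent correlations
  compared by Fisher's r-to-z test,
  $z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)\big/
  \sqrt{1/(n_1-3) + 1/(n_2-3)}$.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `T` | 101 | points/cycle | conventional 0,1,…,100% sampling of the gait cycle |
| `cutoff`, `order` | 6 Hz, 4 | — | standard gait kinematics low-pass; zero-phase (forward–backward Butterworth) so events are not shifted |
| `threshold` | 20 N | N | common vertical-GRF heel-strike threshold; refractory interval 0.4× the median candidate spacing suppresses loading-edge chatter |
| `k` | 1 | — | one-SD ellipsoid. With $k=1$ the product of typical cycle-mean SDs (≈75, 52, 94 mm/s for the control-like preset) yields volumes of order $10^6\ \mathrm{mm^3/s^3}$, the scale on which such volumes are reported; a 95% confidence scaling ($k \approx 2.8$) would inflate volumes ~22-fold. Exposed as a parameter. |
| `window` | 5 | % of cycle | tube smoothing; 0 disables. Applied only to the visualization layer (projected 2×2 covariances and the trajectory used for frames), never to the covariance that feeds volumes and SDs |
| `alpha` | 0.05 | — | significance level everywhere |
| `n_perm` | 10000 | — | SPM permutation budget; full enumeration is used automatically when the number of label arrangements is smaller |
| sanity bounds | [0.5, 1.5]× median | — | cycles with outlying durations are dropped and logged |
| gap fill | ≤ 5 frames | — | marker gaps linearly interpolated; longer gaps are a data-quality error |

Cycles are defined heel strike → next heel strike of the same limb; the
synthetic GRF carries one pulse train, which corresponds to a single-limb
(right-side) convention.

## The synthetic cohort generator

No gait recordings ship with the package; every downstream stage is
exercised by `generate_trial()` / `generate_cohort()`, which draw trials
with a *known* phase-dependent covariance structure:

* **Mean templates.** VT velocity is a two-lobed sinusoid per stride
  (amplitude 160 mm/s), AP a zero-mean biphasic fluctuation (120 mm/s,
  lab/treadmill frame — belt speed is metadata, not added to AP), ML a
  one-lobed alternating waveform (70 mm/s).  Phase offsets keep the 3D
  loop non-planar so Frenet frames are well defined.
* **Stride-level noise.** Within stride $s$, axis $a$:
  $e_{s,a}(u) = \mathrm{env}_a(u)\,[z^{(0)}_{s,a}\cos 2\pi u +
  z^{(1)}_{s,a}\sin 2\pi u]$ with $(z^{(0)}, z^{(1)})$ drawn from
  N(0, R).  Because $\cos^2 + \sin^2 = 1$, the pointwise stride-to-stride
  SD equals the envelope exactly while staying smooth inside a stride —
  the simplest construction that produces a phase-dependent covariance
  and is analytically recoverable.
* **Presets.**  The control-like profile has cycle-mean SD envelopes
  75.07 / 51.58 / 93.60 mm/s (AP/ML/VT) and the PAD-like profile
  49.99 / 39.70 / 40.29 mm/s, matching the magnitudes reported for such
  cohorts; envelopes are smooth circular bumps with the VT bump centered
  at 15% of the cycle so the peak group difference falls in the 10–20%
  (weight-acceptance) window.  Stride periods are 1.20 s (control-like)
  and 1.30 s (PAD-like) at 60 Hz; body weights 820/870 N; stance fraction
  0.62.
* **Cohorts.** Per-subject envelope jitter is multiplicative,
  $1 + \mathrm{cv}\cdot N(0,1)$ per axis with cv = 0.15; subject seeds
  derive deterministically from the cohort seed.
* **Markers and GRF.** Five pelvis markers are rigid offsets of one
  pelvis origin, so COM averaging is exact by construction; the vertical
  GRF is a stance-shaped pulse (zero in swing, ≈ body-weight sinusoidal
  plateau in stance) whose rising edges are the ground-truth heel
  strikes.  A trial with $n$ complete cycles carries $n+1$ heel strikes,
  plus one stride of lead-in/tail so filter transients never reach the
  analyzed cycles.

**What the generator does *not* emulate.**  Real gait has stride-period
jitter, non-Gaussian and temporally correlated noise, soft-tissue marker
artifact, drift, and — importantly — between-subject differences in the
*coupling* of metrics.  In the generator, subject heterogeneity scales all
of a subject's variability together, so ellipsoid volume and total
variability are strongly correlated in *both* synthetic groups (r ≈ 0.96
or higher).  The generator therefore does not reproduce the decoupling of
volume from total variability reported in PAD cohorts (weak r in
patients); the Fisher r-to-z machinery is exercised and verified on its
own closed form, not on a synthetic reproduction of that clinical
observation.  Passing tests demonstrate correctness of the estimators and
inference on data whose truth is known — not that real PAD gait looks
like the presets.

## Numerical choices

* **Differentiation**: central differences in the interior, three-point
  one-sided at the ends (second order throughout; linear signals are
  differentiated exactly).
* **Filtering**: the zero-phase pass reflects the signal about its
  endpoints before filtering so start-up transients settle inside the
  padding; DC signals pass through unchanged to ~1e-6.
* **Interpolation**: cubic splines for cycle time-normalization (linear
  fallback below 4 samples); endpoints of each cycle are preserved
  exactly.
* **Eigen/determinant**: ellipsoids use the symmetric eigendecomposition;
  eigenvalues in $[-\mathrm{tol}, 0)$ are clamped to 0, more negative
  values are an error.  The volume waveform uses a closed-form 3×3
  determinant (identical analytically, cheaper over 101 points).
* **Frenet frames**: built on the lightly smoothed mean trajectory with
  circular differences (the loop is cycle-periodic); near-zero-curvature
  points are flagged and inherit the nearest well-defined frame,
  re-orthogonalized; straight lines get a constant fallback frame; normal
  signs are made continuous by aligning each triad with its predecessor.
* **Permutation SPM**: the observed labelling is always one of the
  permutations, the critical threshold is the $\lceil(1-\alpha)M\rceil$
  order statistic of the max-|t| distribution, and degenerate (zero
  pooled variance) points get $t = 0$.  With full enumeration the result
  is deterministic and seed-independent.
* **Rank-sum**: exact enumeration when the pooled sample is ≤ 12 without
  ties; otherwise normal approximation with tie and continuity
  corrections.

## Design decisions

* **Permutation instead of random-field theory for SPM.**  The
  permutation (max-statistic) variant is assumption-light and exactly
  testable by simulation; its family-wise error under the null is
  verified directly in the test suite (1000 replicate null cohorts of
  10 + 10 smooth waveforms, 500 permutations each).
* **Pooled-variance two-sided t** by default (Welch available via
  `var_equal = FALSE`); group direction lives in interpretation, not in
  the test.
* **Phase p-values** are the minimum cluster p among clusters overlapping
  the phase (1.0 when none) — phase-level summaries of the single
  cycle-wide inference, not re-thresholded per-phase tests.
* **Ellipsoids from unsmoothed covariance.**  Smoothing is a
  visualization layer on the tube; volumes, SDs and all statistics come
  from the raw per-point covariance.
* **One 3D ellipsoid plus three directional SDs.**  "Direction-specific"
  variability is reported both as the integrated ellipsoid (volume) and
  as per-axis SD waveforms, covering both readings of the term.
* **Correlation unit of analysis**: one point per subject (cycle-mean
  volume vs cycle-mean total variability), the only reading consistent
  with n−3 denominators in the Fisher comparison at cohort sizes such as
  132 and 52.
* **Fisher comparison uses the standard formula.**  The package computes
  $z$ from the inputs; it does not special-case any particular published
  value.
* **Group tubes** are built from the grand-mean trajectory (mean of
  subject mean loops) with the subject-averaged covariance series —
  per-participant normalization first, then group averaging.

## Problem sizes used by the checks

The stochastic suites use sizes chosen to make Monte-Carlo error small
relative to the tolerances while staying comfortably reproducible:
parameter recovery at 500 strides (3 SE bands of the cycle-mean SDs); the
group-ordering check on 100 replicate cohort draws at the study's group
sizes (132 vs 52 subjects) with 25 strides per subject; SPM null
calibration on 1000 replicate null cohorts (10 + 10 subjects, T = 101,
500 permutations); the localization experiment on 30 + 30 subjects with a
VT-SD difference confined to 10–31% of the cycle, injected at the stride
level so the check isolates the inference machinery.

## Known limitations

* **Localization through the full marker chain is filter-limited.**  The
  6 Hz zero-phase low-pass smears a sharp-edged variability difference by
  roughly ±4% of a 1.2 s cycle, so marker-level effects localize to about
  that precision; the SPM layer itself localizes stride-level effects to
  ±1 point.
* The low-pass also slightly attenuates very sharp envelope features
  (≈1–2% SD underestimate at the narrow VT bump) — a property of any
  filtered measurement chain, visible here because the truth is known.
* Single-limb cycle convention; no bilateral merging, no toe-off events,
  no kinematic-model COM (segmental sums), no margin-of-stability or
  Lyapunov analyses.
* C3D ingest is not provided; trials enter via the documented CSV layout.
* Preferred walking speeds are metadata only; analyses are of
  time-normalized velocity variability, not speed.
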