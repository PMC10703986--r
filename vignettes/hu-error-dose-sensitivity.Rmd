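---
title: "From HU errors to isocentre dose: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From HU errors to isocentre dose: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctDoseSens)
```

## The problem

MRI-only radiotherapy workflows replace the planning CT with a synthetic
CT (sCT) generated from MRI. Any error in the synthetic Hounsfield units
(HU) propagates through the dose calculation and can change the dose
delivered to the target. This package quantifies that propagation for a
prostate geometry: it injects controlled HU errors into CT-like volumes,
evaluates the resulting dose at the treatment isocentre (the centre of
the prostate), and attributes the dose change to the error's
characteristics with two complementary tools:

* **Spearman rank correlation (SCC)** between one error factor and the
  isocentre dose, holding everything else fixed — does the factor act
  monotonically, and in which direction?
* **Morris elementary-effects screening**, a randomised one-at-a-time
  global sensitivity analysis — which factors matter most, and do they
  act linearly or interact?

Two experiments mirror the two ways sCT errors are usually described.
Experiment 1 screens a localized spherical artefact by its *intensity*
(−250 to +250 HU), *distance* from the isocentre (0 to 100 mm, displaced
along one beam's axis) and *diameter* (2 to 50 mm). Experiment 2 screens
organ-wise mean HU shifts: bladder, prostate and remaining soft tissue
within ±100 HU, bone within ±500 HU, and rectum within −1000 to +200 HU —
the wider bone and rectum ranges reflect how hard those tissues are for
sCT methods to predict, rectal gas (−1000 HU) especially.

## The Morris screening method

For K factors mapped to the normalised cube $[0,1]^K$, a trajectory
starts at a random point of a $p$-level grid and moves one factor at a
time by the unit step $\Delta = p / (2(p-1))$, each factor exactly once
per trajectory in random order. With $R$ trajectories the model $f_j$
(the isocentre dose of patient $j$) is evaluated $N = R(K+1)$ times, and
each transition yields one elementary effect

$$EE_{i,j}^r = \frac{f_j(X_1,\ldots,X_i+\Delta_i,\ldots,X_K) -
f_j(X_1,\ldots,X_i,\ldots,X_K)}{\Delta_i}.$$

Per factor and patient the package reports $\mu$ (mean of the $R$
effects), $\mu^*$ (mean of their absolute values, which prevents
opposite-signed effects from cancelling), $\sigma$ (their sample
standard deviation), and the distance $D = \sqrt{{\mu^*}^2 + \sigma^2}$
used to rank factors. Factors with $\sigma > \mu^*$ are flagged
nonlinear-or-interacting; factors with both $\mu^*$ and $\sigma$ below
5% of the largest $D$ (configurable) are negligible.

Numerical choices worth stating:

* $p = 4$ levels and $\Delta = 2/3$, the standard Morris/Campolongo
  defaults.
* Effects are computed in *normalised* factor space so that factors in
  different units (HU vs mm) are comparable on a single $\mu^*$–$\sigma$
  plot; `denormaliseDesign()` exposes the physical values.
* $\sigma$ is the sample (n−1) standard deviation, and the signed step
  appears in the denominator, so forward and backward moves across the
  same pair of points give identical effects — a linear model therefore
  has $\sigma = 0$ to machine precision, which the test suite asserts.
* When a random base point cannot move by $+\Delta$ (or $-\Delta$)
  without leaving $[0,1]$, the move's sign is flipped rather than the
  base point resampled. For $p = 4$, $\Delta = 2/3$ the flipped move is
  always feasible; the resulting coverage is the same and the design
  stays a deterministic function of its seed.
* Coordinates are snapped back to the level grid after each move so that
  "differ in exactly one coordinate" is exact, not within float noise.
* One master seed; patient $j$'s design uses `seed + j`, so patients are
  screened on independent designs, and the whole pipeline is
  reproducible bit-for-bit from the manifest.

Cohort aggregation is the unweighted mean and standard deviation of
$\mu^*$ and $\sigma$ across patients; the cohort ranking uses the
distance of the mean $(\mu^*, \sigma)$ point.

## The dose model

Full treatment-planning dose engines (fluence optimisation, scatter
kernels) are out of scope; the analysis needs a dose functional that
responds *physically* — monotonically, through radiological depth — to
HU changes. The engine is therefore a primary-fluence model: for dose
point $v$ and beam $b$ with source $s_b$,

$$\text{dose}(v) \;=\; c \sum_b w_b \,
e^{-\mu_w \,\mathrm{WEPL}(s_b, v)} \left(\frac{\mathrm{SAD}}{\lVert v -
s_b\rVert}\right)^2 ,$$

restricted to a cylindrical field aperture (default radius 40 mm) around
each beam axis. WEPL is the water-equivalent path length: the line
integral of relative electron density along the ray, sampled uniformly
at no more than half the smallest voxel dimension (halving the step
changes the isocentre dose by well under 0.1%). HU map to density by a
piecewise-linear calibration anchored at air (−1000 HU → 0) and water
(0 HU → 1), with control points (1000, 1.6) and (3000, 2.1); the curve
is configurable because clinical calibrations vary. $\mu_w$ defaults to
0.0049 mm⁻¹, a broad-beam 6 MV value; SAD to 1000 mm; weights are equal.

The single global constant $c$ is fixed per patient on the *unperturbed*
volume so that the isocentre dose equals the prescription (39 fractions
× 2 Gy = 78 Gy) exactly, and is then reused unchanged on every perturbed
copy — the analogue of copying planned beam parameters onto modified
CTs. All reported dose *changes* are therefore relative to a 78 Gy
baseline by construction; absolute Gy magnitudes of the engine are not
claims about any clinical system.

**Beam arrangement.** The seven coplanar beams are equally spaced and
offset by half the beam spacing (25.7°, 77.1°, …, 334.3°, gantry 0° =
anterior), which places one field directly posterior. With a single
central ray per beam this is not cosmetic: organs only influence the
isocentre dose if some beam's source-to-isocentre ray crosses them
upstream of the isocentre. A 0°-start arrangement leaves the rectum
untouched by every upstream ray segment, which would force the rectum
factor to exactly zero — an artefact of the simplified engine, not of
the anatomy. The half-spacing offset ensures bladder, rectum, bone
(femoral heads and sacrum), prostate and soft tissue all intersect at
least one upstream ray. The dose grid (default 3 mm isotropic) is
aligned so the isocentre falls exactly on a node, making the
grid-interpolated isocentre dose equal the point evaluation.

## The synthetic cohort

No patient data ship with the package; a parametric pelvic phantom
stands in for the study cohort. The body is an elliptic cylinder of soft
tissue (110 × 95 mm semi-axes); inside it sit two femoral heads, a
sacrum, two pubic bones, a bladder anterior–superior to a prostate
spheroid, and a rectum (vertical cylinder) posterior to it, with an
optional −1000 HU gas pocket (probability 0.3 per patient — gas presence
is genuinely uncertain in practice). Tissue HU are Gaussian per voxel
(soft 35 ± 10, bone 700 ± 150, bladder 10 ± 8, rectum −20 ± 15, prostate
40 ± 5 HU), truncated at ±4 sd so each tissue's histogram stays in its
nominal band; these follow standard CT literature values, not any
cohort's statistics. Outside the body is air at −1000 HU. The prostate
centre sits 15 mm anterior of the body axis, leaving >100 mm of tissue
posterior to the isocentre so the full 0–100 mm artefact displacement
track stays inside the body.

Inter-patient variability is multiplicative ±10% jitter on every organ
radius and additive jitter on tissue means (±10 HU for soft tissues,
±100 HU for bone); the body outline is left fixed so jittered organs can
never escape it. The default grid is 128 × 128 × 64 at 2 × 2 × 2.5 mm —
the same physical extent as a 256 × 256 × 128 clinical grid at half the
in-plane resolution, chosen so a full two-experiment screening of a
cohort runs in minutes on one core; the full-size grid is available
through `phantomSpec()`.

What the phantom does *not* emulate: real CT texture and noise
correlation, atlas-accurate anatomy, organ motion, couch and
positioning effects, and metal artefacts. Passing tests on this cohort
demonstrate that the methodology — error injection, dose response,
screening and ranking — behaves correctly and reproduces the expected
qualitative structure; they do not certify quantitative sensitivities
of any real patient population.

## What the pipeline reproduces — and what it cannot

On the synthetic cohort the Spearman sweeps reproduce the expected sign
pattern: increasing artefact HU lowers the isocentre dose (more
attenuation upstream of the target), increasing the diameter of a
+200 HU artefact lowers it further, and moving the artefact away from
the isocentre along a beam axis restores the dose. The organ screening
ranks errors in the remaining soft tissue (the largest volume crossed by
every beam) as most influential and bladder errors as among the least —
the bladder is small, its offset bounded at ±100 HU, and few rays cross
it. The absolute SCC magnitudes and Gy differences of a clinical
IMRT engine on real patients are *not* reproduction targets: they depend
on the private cohort and on planning-system specifics. Evaluation
counts, however, are exact: R = 50 trajectories over K = 3 factors is
200 evaluations per patient (7800 for 39 patients); R = 40 over K = 5 is
240 (9360).

The sweep grids follow the stated protocol: intensity in 25 HU steps
with a 50 mm artefact centred on the isocentre; distance in 10 mm steps
at +200 HU and 50 mm diameter; size at +200 HU fixed 30 mm from the
isocentre (about the rectum's position), with a 2 mm step — the size
step is not stated in the protocol and 2 mm is this package's choice.
Zero intensity is included in the sweep as the natural identity point.
A constant dose across a sweep leaves the SCC undefined and it is
reported as `NA`, never coerced to 0.

## Degenerate inputs and tie-breaks

* An artefact sphere so small it contains no voxel centre modifies no
  voxel (membership is voxel-centre-in-sphere, chosen over
  partial-volume weighting for determinism); the dose is then exactly
  the baseline.
* Artefact spheres entirely outside the body are rejected as misuse — a
  perturbation that cannot affect tissue signals a configuration error.
* HU are clamped at −1000 after shifting (a −1000 HU rectal shift on
  already-negative voxels would otherwise go below air); no upper clamp
  is needed within the factor ranges.
* Factor ranking ties break by first occurrence (stable, deterministic).
* Organ-shift composition order is irrelevant because masks are pairwise
  disjoint; the test suite asserts commutativity.

## Problem sizes used by the shipped checks

The test suite and the acceptance script screen 5 phantom patients with
R = 10 trajectories per experiment and run the three Spearman sweeps per
patient — the scale at which the qualitative claims above are stable
across seeds — and verify design arithmetic at the full R = 50 / R = 40,
39-patient scale, where only the (cheap) designs are materialised. Unit
tests use a coarser 64 × 64 × 32 phantom with identical world-space
geometry.
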