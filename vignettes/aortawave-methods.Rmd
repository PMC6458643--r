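---
title: "Shape and wave haemodynamics of the repaired aorta: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape and wave haemodynamics of the repaired aorta: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortawave)
```

## The scientific problem

After surgical repair of aortic coarctation, many patients remain
hypertensive despite an anatomically adequate repair. Two aspects of the
residual vascular phenotype are commonly implicated: the *shape* of the
reconstructed arch (the acutely angulated "gothic" arch versus the rounded
"Romanesque" one) and its *calibre* (residual isthmus narrowing, transverse
arch hypoplasia, ascending dilation). Because a curved vessel and a narrowed
vessel load the ventricle through different mechanisms, this package keeps
the two strictly separate: curvature is analysed as the registered 3D
centreline coordinates, calibre as the radius profile along the centreline,
and each gets its own principal component analysis (PCA). Central
haemodynamics — central systolic pressure, total arterial compliance and
wave reflection — are derived non-invasively from ascending-aortic flow and
area waveforms plus cuff pressures, and the association between shape
components and haemodynamic load is tested statistically. Finally, a 1D
pulse-wave model driven by a time-varying elastance heart checks whether the
calibre patterns statistically associated with wave reflection also generate
larger reflections in silico.

No patient data ship with the package. Every stage is exercised on a
synthetic cohort whose ground truth is known exactly, which is what makes
each derivation testable.

## Shape model

Centrelines (ordered 3D points with the maximal-inscribed-sphere radius at
each point) are processed in a fixed sequence:

1. resample to 100 points equally spaced in arc length (correspondence
   across subjects is by arc-length index, not anatomical landmarks);
2. scale each centreline to the population mean arc length (a uniform
   similarity about the centroid; radii untouched);
3. rigidly register (rotation + translation only, reflections forbidden
   because anatomy has a fixed chirality) to a reference built by
   generalised Procrustes alignment — iterate register-to-mean /
   recompute-mean to a fixed point, then orient the converged mean so its
   best-fit plane matches the average best-fit plane of the aligned
   population, with deterministic in-plane axes so the reference does not
   depend on input order;
4. separately, scale each radius profile to the population mean radius.

PCA is a mean-centred SVD of the subject-by-feature matrix: 300 features
(x, y, z × 100) for curvature, 100 for radius. No per-feature variance
scaling is applied, so components are displacement fields (or calibre
profiles) in millimetres. Component signs are fixed by making the
largest-magnitude loading positive; subject weights are reported in SD
units, and reconstruction uses the display convention that a weight of ±1
means ±2 SD (the convention used to visualise extreme "proto-aortas").
The first five components are retained throughout the pipeline.

Two points were genuinely open and were decided as follows. First, whether
the radius PCA should be run on radii from the length-normalised geometry
or on mean-radius-scaled profiles: the package uses mean-radius-scaled
profiles on the resampled grid, because calibre and length normalisation
are logically independent. Second, for synthetic-recovery experiments the
PCA is fitted on the generator output directly (which is emitted in a
common frame and at a common scale): per-subject mean-radius scaling on a
cohort *without* scale variation injects a spurious base-profile component
correlated with the mode weights (each mode shifts the subject's mean
radius), which measurably rotates the fitted components while providing no
benefit. On real cohorts, where body size varies, the normalisation is
essential and is always applied by `run_study()`.

The clinical geometry indices read diameters as twice the centreline
radius at landmark positions (coarctation index = isthmus/diaphragm
diameter; arch index = transverse arch/diaphragm diameter). On image data
these would be measured on multiplanar reformats; the centreline radius is
the package's documented substitute, since image handling is out of scope.

## Central haemodynamics

**Pressure from area.** The exponential single-stiffness-parameter tube law
`P = P_d exp(alpha (A/A_d - 1))` is anchored at the diastolic point
(`A_d = min A`, `P(A_d) = DBP`), resting on the conservation of diastolic
and mean pressure along the arterial tree. The time-mean of the synthesised
curve is strictly increasing in `alpha`, so `alpha` is found by bracketed
root finding (bracket `[1e-3, 1e3]`, tolerance 1e-6 mmHg on the mean) to
match cuff MBP; central SBP is the curve's peak. The synthetic generator
implements the exact inverse mapping, so the calibration is validated as an
exact round trip (recovery to ~1e-13 in the tests).

**Total arterial compliance.** The 2-element windkessel ODE
`dP/dt = Q/C - P/(RC)` with `R = MBP/CO` is solved in its periodic steady
state exactly in the frequency domain (`P_k = R Q_k / (1 + i w_k R C)`),
which removes any transient dependence on initial pressure and makes
`mean(P) = R mean(Q)` an identity. `C` is tuned by bracketed root finding
so the model pulse pressure equals the measured central pulse pressure
(pulse pressure is strictly decreasing in `C`).

**Wave intensity.** In the flow–area formulation the separated increments
are `dI± = ±(dQ ± c dA)² / (4c)` with the wave speed `c` estimated as the
slope of the QA loop over the early-systolic window (default: from the
first sample above 5% of the flow pulse to 60% of peak flow, which
precedes the return of reflections). The identity `dI+ + dI- = dQ·dA`
holds algebraically and is asserted to 1e-12 relative in the tests. Wave
areas are sums of increments over the dominant compression windows: the
contiguous run around the extremum of the separated intensity in which the
corresponding forward/backward *area* (or pressure, for the P–U
formulation) increment indicates compression. On densely sampled simulated
signals the raw compression discriminator flickers in sign near zero, so
the window boundaries are found on a lightly smoothed (moving average,
~1/128 of the cycle) copy of the discriminator while the raw increments
are summed — without this the contiguous run can collapse to a few
samples.

Units: wave areas are reported in the increment-sum convention (label
cm^5), matching the "area under the wave" usage this field reports; the
physically strict unit of the time-derivative formulation is cm^5/s³, and
`wave_areas(..., convention = "timederiv")` rescales by `1/dt²` for users
who want it. The absolute magnitudes are convention-dependent and are
treated as such; only ratios and recovery errors are asserted.

## The synthetic cohort

The generator is first-class, tested code; its defaults *are* the study
conditions.

* **Base geometry**: an analytic "candy-cane" arch — a smooth curvature
  profile (gentle limb curvature plus a Gaussian arch bump integrating to a
  total turn of pi) with a small out-of-plane bow; total length 250 mm,
  matching an adult sinotubular-junction-to-diaphragm aorta. The base
  radius profile tapers from a 12.5 mm ascending radius to a 9 mm
  descending plateau with a mild fixed isthmus waist, giving a mean
  coarctation index near 0.91 and arch index near 1.05 — the calibre
  geometry of a typical post-repair cohort.
* **Modes**: named spatial profiles (arch angulation, ascending/descending
  sweep, out-of-plane bow; ascending dilation, isthmus narrowing,
  transverse-arch calibre, taper tilt), orthonormalised in construction
  order; per-mode weights are Normal(0, SD²) with the SDs chosen so the
  default curvature variance shares fall steeply (dominant first mode),
  as observed in post-repair populations. Subjects whose perturbed radius
  becomes non-positive are rejected and redrawn — clipping would corrupt
  mode orthogonality — and the redraw count is logged.
* **Waveforms**: a forward area pulse (half-cosine rise, plateau, slow
  fall over 0.42 s — the flat-topped distension of a real ascending
  aorta) plus a delayed, scaled reflection under linear wave theory
  (`dQ_f = c dA_f`, `dQ_b = -c dA_b`), sampled at 9.6 ms to mirror a
  high-temporal-resolution phase-contrast acquisition. The truth table
  carries the exact component-wise FCW/BCW areas; for non-overlapping
  pulses their ratio is Γ² exactly, the key oracle for the separation
  code.
* **Couplings with known effect sizes**: the gothic-arch label is drawn
  from a logistic rule on the arch-angulation weight (slope 1.5 per SD,
  intercept -1.4, prevalence ≈ 23%), and each subject's reflection
  coefficient is a logistic-linear function of its radius-mode weights, so
  the association stage has true positives (radius→BCW) and true negatives
  (curvature→BCW) by construction.
* **Covariates** (brachial pressures, BSA, LVMi, LVEF) are drawn at
  adult post-repair means; they are plausibility context, not targets.

What the generator does *not* emulate: imaging noise and segmentation
artefacts, subject-specific wave shapes beyond the two-wave linear model,
pressure-dependent wall stiffness, or any curvature→haemodynamics coupling.
Passing tests therefore demonstrate correctness of the estimators under the
stated model, not robustness to real CMR data quality.

## The 1D pulse-wave model

The solver integrates the 1D mass and momentum equations with the tube law
`P = P_ext + beta (sqrt(A) - sqrt(A0)) / A0`, `beta = 2 rho c0² sqrt(A0)`,
and Poiseuille-approximation friction `K_f = 22 pi nu`, using the two-step
(Richtmyer) Lax–Wendroff scheme in conservative form with geometric source
terms for tapered vessels (CGS units internally, mmHg at the interfaces;
CFL safety factor 0.9 with the time step derived from the reference wave
speeds). Boundaries couple through Riemann invariants
`W± = u ± 4(c - c0)`:

* **Inlet**: either a prescribed flow or a time-varying elastance
  ventricle (double-Hill normalised elastance, exponents 1.32/21.9,
  characteristic times 0.269T/0.452T) with an ideal valve plus quadratic
  Bernoulli loss, filling from a constant-pressure source through a mitral
  resistance.
* **Junctions**: conservation of flow and continuity of *static* pressure
  (total-pressure continuity differs at second order at these Mach
  numbers), solved by Newton iteration with an analytic Jacobian.
* **Terminals**: RCR windkessel (semi-implicit compliance update), pure
  resistance, or closed end.

One numerical choice deserves emphasis: boundary and junction nodes update
their *area* by a conservative half-cell finite-volume step using the
boundary flux solved from the characteristic coupling. A pure
characteristic overwrite of the boundary area — the common shortcut — loses
volume at first order in `dx` wherever the vessel tapers, which summed over
a branched tree produced per-beat volume errors of several percent; the
conservative closure telescopes with the interior scheme and brings the
per-beat volume balance to round-off (~1e-13 of stroke volume), verified
per beat in the tests. Other validated physics: pulse foot speed within 3%
of the tube-law wave speed, reflection at a step radius change within 0.02
of the transmission-line coefficient `(Z2-Z1)/(Z1+Z2)`, closed-end
reflection of unit magnitude within 5%, a matched terminal reflecting
< 0.1% in energy terms, and grid convergence of root pulse pressure under
simultaneous `dx`/`dt` halving within 1%.

The default tree is a ten-segment thoracic aorta (matched to the 100-point
radius-profile grid) with the three head-and-neck branches and RCR
terminals tuned to a mean pressure near 90 mmHg at ~5 l/min, with run-off
split ~65% lower body / 35% head and arms. The reference tree of the
clinical literature is not tabulated publicly, so these values are
documented defaults, and all solver-facing claims are property-based
(physics invariants), not numeric matches to any published figure.

**Proto-aorta experiment.** For selected radius components, `±1` display
weights (±2 SD) are imposed on the aortic segments, the elastance-heart
simulation is run to a periodic state, and root wave reflection is
quantified by conventional pressure–velocity wave intensity with the local
tube-law wave speed. In this model the root BCW area is governed by the
*proximal-to-distal calibre contrast*: enlarging the root/ascending aorta,
enlarging the transverse arch, or tilting the taper towards a relatively
smaller descending aorta each increases the backward compression wave
(margins of 40–95% at ±2 SD), consistent with impedance mismatch seen from
a lower proximal characteristic impedance. A *localised* distal narrowing
without proximal enlargement behaves differently: it partially shields the
root from terminal reflections and can reduce the measured root BCW. The
`proto_modes()` set used for the in-silico corroboration therefore spans
three spatial flavours of the proximal-vs-distal contrast — the geometry
shared by the adverse calibre patterns — rather than a localised stenosis.
The experiment's acceptance property is directional and strict: for each
component, the variant with the larger proximal/distal calibre ratio must
produce the strictly larger BCW area.

## Association statistics

Pearson correlations (two-sided t test), multivariable OLS with intercept
(F test overall, Wald t per coefficient, rank-deficiency is an error naming
the collinear columns) and logistic regression (IRLS via `glm`, separation
detected and flagged) are computed through the standard R fitting machinery;
the test suite checks them against hand-rolled normal-equation and
covariance formulas to 1e-8/1e-12 and calibrates type-I error on null
simulations. Variables failing a Shapiro–Wilk screen at alpha = 0.05 are
natural-log transformed when strictly positive (the test and the base of
the transform are configuration; defaults as stated), and transformed
columns are flagged in the output. Significance is marked at p < 0.05 with
*no* multiple-testing adjustment — a deliberate, recorded property of the
association table (`multiplicity_adjustment = "none"`), chosen to avoid
rejecting true associations at the cost of false-discovery risk, with the
1D model serving as the independent corroboration.

## Problem sizes and determinism

The shipped study configuration uses 60 subjects (the scale of a
single-centre surveillance cohort), 100-point centrelines, five retained
components per shape model, and a proto-aorta experiment over three radius
components at ±2 SD with six cardiac cycles per simulation; synthetic
recovery experiments use 200–500 subjects where sampling error would
otherwise dominate. All randomness flows through a single seed, and the
full pipeline is bit-reproducible: the same configuration and seed yield
byte-identical cohort tables, association tables and simulation outputs.

```{r example, eval = FALSE}
report <- run_study(study_config(n_subjects = 60, seed = 1))
print(report)
report$assoc          # univariable association table
report$proto_experiment
```

## Known limitations

* Correspondence across subjects is by equal arc-length index; strongly
  displaced anatomical landmarks would argue for landmark-based
  correspondence, which is not implemented.
* The exponential pressure–area model has a single stiffness parameter;
  pressure-dependent stiffening within the beat is not represented.
* Wave-area magnitudes are convention-dependent (see units note); compare
  ratios, not absolute values, across studies.
* The 1D model's junction closure ignores kinetic-energy differences, the
  valve cannot regurgitate, and coronary/venous circulations are absent.
* Curvature enters the haemodynamic model only through the centreline's
  effect on segment lengths; 3D secondary-flow effects of curvature are
  beyond any 1D formulation.
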