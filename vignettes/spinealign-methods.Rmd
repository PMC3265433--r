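---
title: "Quantifying frontal-plane spinal alignment on zoned sleep surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying frontal-plane spinal alignment on zoned sleep surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinealign)
```

## The problem

A person lying on their side has no active control over spinal posture.
When the mattress supports the body poorly, the frontal projection of the
spine bends away from the straight line it forms in upright stance: on a
soft surface the heavy pelvis sinks deep while the broad rib cage stays
high, and on a very firm surface only the wide shoulder and pelvis are
supported so the lumbar spine droops over the unsupported waist. A mattress
built from zones of different stiffness — a custom-made arrangement — can
be tuned per person to keep the spine close to straight.

`spinealign` implements the full measurement and modelling chain for this
problem in the frontal plane:

1. **Geometry** — from the coordinates of surface markers on twelve
   spinous processes (C7, T1, T2, T3, T4, T6, T8, T10, T12, L1, L2, L5) to
   the kink angle `P8` and its deviation statistic `180 - P8`.
2. **Imaging** — locating bright circular markers in grayscale frames and
   ordering them into a labelled curve.
3. **Mattress metrics** — the LGA load–deflection summary (E, C, E/C) and
   a softness classification.
4. **Body–bed model** — a quasi-static, transparent surrogate for the
   multibody simulation used to design zoned arrangements, plus a
   deterministic zonal-stiffness optimizer.
5. **Group statistics** — Welch's heteroscedastic one-way ANOVA, Levene's
   test and Tamhane's T2 post hoc pairs for comparing surfaces.
6. **Synthetic cohorts** — a generator with known ground truth so every
   stage can be validated end to end.

## The P8 angle

The frontal spinal slope typically shows a discontinuity near T11, at the
transition from the flexible lumbar spine to the stiffer, rib-bound
thoracic spine. T11 itself carries no marker, so the marker chain is split
strictly between T10 and T12: the *thoracic* set (C7 … T10, eight markers)
and the *lumbar* set (T12 … L5, four markers). A line is fitted to each
set and `P8` is defined so that collinear, equally-directed lines give
`P8 = 180` degrees; the deviation from straightness is `dev_deg = 180 - P8`,
the quantity that is compared across surfaces and minimized by the
customization.

Three design choices deserve justification:

* **Orthogonal (total least squares) regression.** Marker deviations are
  perpendicular to the spine axis, and the axis orientation in the image
  frame is arbitrary; ordinary regression of y on x would make the angle
  depend on the camera orientation. The TLS direction is the leading
  eigenvector of the segment's point covariance, so `dev_deg` is invariant
  under translation, rotation, reflection and uniform scaling — verified
  to 1e-9 degrees in the test suite.
* **Angle numerics.** The angle between the two unit directions is
  computed as `atan2(|cross|, dot)` rather than `acos(dot)`: the arccosine
  loses all resolution below about 1e-6 degrees, while the arctangent form
  recovers exactly straight spines to machine precision.
* **Normalization.** To overlay curves from different subjects, a
  similarity transform maps L5 to (0, 0) and C7 to (1000, 0). Any fixed
  chord would do — `P8` is similarity-invariant by construction — so the
  choice only fixes the plotting scale ("normalized mm" on a 1000 mm
  chord).

Missing markers are an error, never interpolated: the measurement protocol
always yields all twelve, and silently imputing a vertebra would bias the
segment fits. Beyond `P8`, the per-vertebra orthogonal deviations from the
L5–C7 chord are reported (`chord_dev_mm`) as a descriptive supplement; no
other scalar shape parameters are defined here.

## Marker detection

Frames are grayscale intensity grids in [0, 1] with a known mm-per-pixel
scale. Detection binarizes at a threshold (default 0.5), labels
8-connected components, drops components below a minimum area (default 4
px), and returns the *intensity-weighted* centroid of each component —
weighting by the original intensities rather than the binary mask honours
the sub-pixel locus of the marker centre. On rendered fixtures with
Gaussian spot profiles and pixel noise of sd 0.05 the centres are
recovered to better than 0.5 px.

Ordering detections into a curve uses a caudal-to-cephalad axis hint (the
operator knows the camera orientation). The capture protocol adds four
*reference* markers outside the vertebral chain (two near L5, two 10 cm
beyond C7). The chain is identified as a run of 12 detections, consecutive
in longitudinal projection, such that every excluded detection lies more
than a configurable margin (default 30 mm) beyond the run's extremes.
Because the reference distance (5 cm) is comparable to the intervertebral
marker spacing, more than one run can satisfy the margin rule; ties are
broken by lateral smoothness — the true chain is a smooth curve, whereas a
run that includes reference markers shows large second differences in
lateral offset. No admissible run, or too few detections, is an error
reporting the count.

Image distortion and depth correction from a second overhead camera are
not modelled; no usable correction model is available, and the synthetic
frames are generated in the corrected frame to begin with.

## LGA stiffness metrics

For the loading branch of a compression test (deflection mm, force N):

* `E` (N·mm) is the work to compress the element to 450 N: the
  trapezoidal integral of force over deflection, with the 450 N endpoint
  hit exactly by linear interpolation. For a linear spring of 1 N/mm this
  is `450^2 / 2 = 101250` N·mm exactly.
* `C` (N/mm) is the average differential stiffness: the mean tangent
  slope at the three deflections where the force equals 210, 275 and
  340 N. The slope is a central finite difference on the sampled curve (a
  secant across the bracketing samples; across the two neighbours when a
  level falls exactly on a sample). A parametric fit was rejected because
  the constitutive model of a foam/spring stack is unknown; the secant is
  model-free and converges quadratically with the sampling step. The
  points are read as *force levels*, not deflections — the three values
  sit symmetrically around the 275 N midpoint of the 100–450 N working
  range, which only makes sense on the force axis.
* `E/C` (mm²) increases with softness and drives the surface class.

The official class boundaries of the LGA standard are not public; the
bands are therefore configuration with defaults chosen so that the one
published anchor — a polyurethane + memory-foam stack with E/C =
2476 mm² classified as *soft* — is reproduced: soft ≥ 2000 mm², medium
[1000, 2000) mm², firm < 1000 mm². Bands are closed on the lower edge, so
a ratio exactly on a boundary falls in the softer class. Zonal stiffness
tables are reported normalized to percent of the stiffest zone (one
decimal), with raw values retained.

## The body–bed model

The multibody simulation used for arrangement design (articulated
skeleton, contact, commercial solver) publishes no equations, so
`spinealign` replaces it with a *declared surrogate*: a transparent
quasi-static model with the same qualitative physics. It is presented as
what it is — a design-stage energy model — not as a reimplementation of
the original simulation.

The body is six longitudinal segments — head, shoulder/thorax, waist,
pelvis, thigh, leg — each with a mass, an extent along the body axis and a
lateral contour half-width (the distance from the spine midline to the
mattress contact surface in lateral lying). Defaults, overridable through
the contour configuration:

| segment  | mass fraction | extent fraction | half-width (mm) |
|----------|---------------|-----------------|------------------|
| head     | 0.08          | 0.13            | 90               |
| shoulder | 0.32          | 0.30            | ratio × pelvis   |
| waist    | 0.12          | 0.11            | 140              |
| pelvis   | 0.26          | 0.10            | 150              |
| thigh    | 0.14          | 0.20            | 120              |
| leg      | 0.08          | 0.16            | 70               |

The mass split follows standard segment-inertia tables (trunk mass
concentrated in thorax and pelvis); the half-widths encode the key
anatomy: the pelvis is wide *and* heavy, the thorax is wide (rib cage)
but light for its width, and the waist is the narrowest part of the
trunk. The shoulder half-width is derived from the preset's
shoulder-to-pelvis width proportion (triangular > 1.45 > square), so the
four anthropometric presets (HTM 181 cm/103 kg/1.59, HSM 183/93/1.33,
LTM 182/74/1.52, LSM 184/76/1.28) are realized exactly. The twelve
vertebrae are spread linearly from the cranial end of the thorax to the
cranial 30 % of the pelvis; with these extents all eight thoracic markers
lie over the thorax segment (anatomically, C7–T10 is within the rib
cage) and the lumbar markers over waist and pelvis. The lateral-lying
posture constants (trunk angle 135°, knee flexion 90°) are recorded as
body metadata.

The mattress is a row of free-standing elastic blocks (100 mm long,
200 mm high, full mattress width) on a rigid base, grouped into six zones
of equal per-block stiffness: zones 1–2 split the head + shoulder region,
3–4 the waist, 5 the pelvis, 6 thigh + leg. A segment is supported by the
blocks under it, prorated by overlap length.

Equilibrium minimizes the potential

    U(h) = Σ ½ K_i · max(w_i − h_i, 0)² + Σ m_i g h_i
           + λ Σ (h_{j−1} − 2 h_j + h_{j+1})²

over the segment midline heights `h`: elastic energy of the compressed
blocks, gravitational potential, and a trunk-bending penalty on the
second differences of the height profile with weight `λ` (`coupling`,
N/mm). The `max(·, 0)` makes contact unilateral — a narrow segment can
*bridge* clear of the mattress when its neighbours hold it up, which is
exactly what the waist does on a very firm bed. Compression saturates at
80 % of the block height (foam densification stand-in; configurable).
The problem is smooth and convex and is solved by L-BFGS-B with an
analytic gradient; with `coupling = 0` the segments decouple and the
closed form `sag = m g / K` is used, which also makes the global force
balance `Σ K_i sag_i = W g` exact. Vertebra markers take the height of
the segment beneath them. For bridged segments the reported sag is 0 and
the midline height exceeds the contour half-width; for contacting
segments `height = half-width − sag` holds identically.

**Calibrating the bending weight.** `coupling` is the one genuinely free
model constant. It was fixed at design time by scanning
{0, 0.1, 0.25, 0.5, 1} N/mm against the three qualitative signatures the
model must reproduce for *every* preset: (i) on a soft uniform bed
(2 N/mm per block) the pelvis sinks deepest and C7 ends higher than the
pelvis; (ii) on a firm uniform bed (100 N/mm) the lumbar spine lies below
the thoracic line; (iii) the deviation ordering soft > firm > customized.
At `λ = 0.1` N/mm the firm-bed waist bridges realistically while gravity
still dominates on soft beds, and the ordering holds with the widest
margins (noiseless deviations: soft 5.4–9.0°, firm 1.3–2.1° across the
presets). At `λ ≥ 0.5` the bending term overpowers gravity, the soft-bed
spine straightens artificially and the firm bed develops the larger
kink, contradicting signature (iii); `λ = 0` reproduces the ordering but
decouples the zones so that shoulder-zone stiffness could not influence
the spine, which would make customization degenerate. The default is
therefore 0.1 N/mm everywhere.

## Zonal-stiffness customization

`optimize_zones()` minimizes the model's `dev_deg` over the six per-block
zone stiffnesses inside configurable bounds (default 0.5–20 N/mm):
deterministic cyclic coordinate descent in fixed zone order 1…6, each
zone optimized on its interval by `stats::optimize()` (golden
section/parabolic), accepting a move only when it strictly improves the
deviation, repeated until a full pass improves by less than `tol`. There
is no randomness and no seed. An already-straight start is a fixed point
and is returned unchanged; when no zone move improves on the start, the
start is returned with a warning flag.

Two properties of this optimizer are worth stating honestly:

* The minimizer is *not unique*: straightness constrains height
  differences, not absolute height, so a one-parameter family of
  arrangements achieves `dev_deg ≈ 0`. The fixed zone order makes the
  result deterministic; because cranial zones are visited first, the
  descent straightens the spine mainly by softening the shoulder region,
  which is also the pattern the zoned-arrangement literature reports
  (soft shoulder zone, firmer waist support).
* Consequences verified in the tests: for every preset the customized
  deviation falls below both uniform baselines; triangular presets end
  with shoulder zones (1–2) softer than waist zones (3–4) in the
  normalized table; heavy presets show at least as large a normalized
  zone spread as their light counterparts (heavy people gain more from
  customization).

## Group statistics

The deviation angle is compared across surfaces with the heteroscedastic
toolchain appropriate when a customized surface compresses the variance
of its group: Welch's one-way ANOVA (primary omnibus test), the classical
F for reference, Levene's test (mean-centred by default, the convention
of the classical statistical packages; median centring available) to
justify the heteroscedastic route, and pairwise post hoc comparisons in
the Tamhane T2 style: Welch t per pair with Welch–Satterthwaite degrees
of freedom and Šidák familywise control (`α' = 1 − (1 − α)^{1/m}` over
`m = k(k−1)/2` pairs; adjusted p reported as `min(1, 1 − (1 − p)^m)`).
Welch and classical ANOVA are routed through `stats::oneway.test` and
Levene through `car::leveneTest`; Tamhane T2 is implemented here because
no installed package provides it. The test suite checks all four against
independent step-by-step formula implementations to 1e-9, the two-group
identities F = t², the exact two-group equal-variance Welch/classic
identity (for three or more groups Welch's small-sample correction makes
the statistics differ at O(1/n), so agreement is only asymptotic), a
10,000-replicate null simulation (empirical size 5 % ± 1 % under unequal
n and variances) and a 2,000-replicate power simulation (> 95 % at
α = 0.001 for group means 12.66/8.9/4.10, sd 3, n = 25 — the effect-size
regime the pipeline is meant to resolve). Repeated trials of a subject
on the same surface are averaged before testing; the alternative
(treating trials as independent) would overstate the effective n.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the pipeline targets: 25
subjects drawn from the four presets (default mix ¼ each), each lying on
a soft uniform bed (2 N/mm, two trials), a firm uniform bed (100 N/mm,
two trials) and a per-subject customized arrangement (one trial — it is
the end point of the tuning process). Subject variability is
multiplicative log-normal jitter (sd 0.05 on the log scale) applied
independently to segment masses and half-widths; log-normal keeps the
quantities positive and 5 % matches the within-preset anthropometric
spread the presets are meant to bracket. Marker noise is additive
Gaussian, sd 2 mm on both coordinates, the scale of palpation and
skin-motion error after manual correction. Everything is reproducible
from one integer seed, and the noiseless deviation angle is emitted as
ground truth next to every curve.

What the generator does *not* emulate: skin-marker motion artifacts
(corrected manually in the protocol it mimics), sagittal-plane posture,
soft-tissue deformation, mattress creep, and any real anthropometric
covariance structure (masses and widths jitter independently). Passing
end-to-end tests therefore shows that the pipeline recovers what the
*model* generates under realistic noise — it validates the software and
the qualitative physics, not the quantitative accuracy of the surrogate
on real bodies. In particular the cohort means (about 7°/2.5°/0.6° for
soft/firm/custom at the defaults) are smaller than the published human
values (12.66°/8.9°/4.10°), as expected from a desk-scale surrogate; the
ordering, the significance structure (Welch p < 0.001, all three Tamhane
pairs significant) and the variance heterogeneity are reproduced.

## Numerical choices and problem sizes

* TLS directions via eigen-decomposition of the 2×2 covariance; segment
  direction signs oriented caudal→cephalad, with a lexicographic
  tie-break for the degenerate perpendicular case.
* Equilibrium: L-BFGS-B, `factr 1e4`, analytic gradient, initialized at
  the uncoupled solution; non-convergence is a hard error reporting the
  gradient residual.
* Coordinate descent: inner `optimize()` tolerance 1e-4 N/mm; outer
  tolerance 1e-4° per pass; at most 25 passes (never reached in
  practice — the defaults converge in 1–2 passes).
* Marker CSV and JSON reports are written at 17 significant digits so
  round trips are bit-exact.
* Test/acceptance problem sizes, chosen to keep the full suite under a
  few minutes on one core: 25-subject cohorts for the end-to-end checks,
  a 121×121 exhaustive grid (0.05 N/mm) for the two-zone optimizer
  oracle, 100 random curves against the brute-force angle-scan oracle,
  10,000/2,000 replicates for the size/power simulations.

## Known limitations

* Segment heights are piecewise constant: all markers over one segment
  share its height, so the thoracic fit sees a single support level.
  This is the price of a six-segment body; it makes the surrogate's
  thoracic line exactly straight on uniform beds.
* The head's pillow is not modelled; the head rests on the mattress like
  every other segment. With the default contours this only adds a mild
  bending pull on the shoulder.
* The LGA class bands beyond the one published anchor are conventions,
  not standard values.
* Tamhane's T2 is implemented in its Šidák-over-Welch-pairs form; the
  original reference also describes variants with slightly different
  critical values.
* The optimizer returns one member of the optimal family (see above);
  reported zone tables should be read as *a* straightening arrangement
  with the documented cranial-first structure, not the unique one.
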