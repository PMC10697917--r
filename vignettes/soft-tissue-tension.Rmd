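---
title: "Measuring and modelling passive soft-tissue tension at the hip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling passive soft-tissue tension at the hip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiptension)
```

## The problem

Soft-tissue tension around a replaced hip is believed to govern joint
stability, yet it is hard to quantify during surgery. One way to measure it
is a force-instrumented trial femoral head: a modular head containing four
pressure sensors that is mounted on the stem during trialing, while the
anaesthetised patient's hip is taken passively from full extension to 90
degrees of flexion several times. The sensors record the three-dimensional
contact force at 100 Hz; the flexion angle is tracked alongside. Because the
patient is anaesthetised, every measured Newton comes from passive tissue
stretch and gravity, not from active contraction — the quantity surgeons
informally call "tissue tension".

`hiptension` implements the complete analysis around such recordings:

1. **instrumented head** — forward and inverse models of the four-sensor
   head, benchtop calibration, and an accuracy benchmark;
2. **frames** — the rotation chain that carries a head-frame force into the
   pelvic frame and the clinical (posterior, inferior, medial) reporting
   convention;
3. **trial pipeline** — cycle segmentation and the per-cycle/cohort summary
   statistics;
4. **passive musculoskeletal model** — an independent prediction of the same
   force profile from scaled rigid segments, Hill-type passive muscle
   forces, and gravity;
5. **synthetic cohort** — a seedable generator producing raw sensor logs
   with known ground truth, so every stage is testable without clinical
   data.

## Coordinate frames and the transformation chain

The pelvic frame O is right-handed with **x anterior, y lateral on the
operated side, z inferior**. This labelling is forced by the anatomy of the
chain: hip flexion is a rotation about the mediolateral axis, so the flexion
rotation must be the y-rotation; anteversion is an axial-plane angle
(z-rotation); neck inclination and stem varus are frontal-plane angles
(x-rotations). With these axes every angle of the chain rotates about its
anatomically correct axis and positive `rot_y(gamma)` is flexion.

The head frame O′ is fixed to the implant. A measured head-frame force
$F'$ maps to the pelvic frame as

$$F \;=\; T_y(\gamma)\, T_z(\chi)\, T_x(\varepsilon)\, T_x(\delta)^{-1} F',$$

applied innermost first: the neck-inclination rotation ($\delta$, fixed at
130° by the stem design) is written in the head's own (primed) frame and
therefore enters as its inverse, while flexion $\gamma$, anteversion $\chi$
and varus $\varepsilon$ are stated relative to the pelvis and apply
directly. Two facts support this reading: it puts the head's y′ axis in the
lateral-superior direction at neutral pose, matching how the head is
mounted; and it keeps the compressive joint load on the sensed half-spaces
of the sensor layout throughout the sweep (see below) — with the opposite
sign the instrument could not have produced usable recordings.

Reported forces are the components of the force the femoral head exerts on
the pelvis, positive when directed posteriorly, inferiorly and medially;
`to_reported()` fixes `posterior = -fx`, `inferior = +fz`,
`medial = -fy` (right hip; the operated side only flips the mediolateral
sign). Angles are degrees at every interface and radians internally.
Orthonormality of every rotation is tested to 1e-12 and the chain is checked
against an independently coded matrix-product oracle to 1e-9 N.

## The four-sensor head

Four pressure sensors sit on the faces of the 14 mm cube inside the 26 mm
hemisphere: sensor 1 on the +z′ pole, a single sensor on +y′, and an opposed
pair on ±x′. Pressure sensors register compression only, so channel $i$
reads $\max(0,\ n_i \cdot F')$. For a force whose y′ and z′ components stay
compressive — which the chain guarantees for joint loads across the 0–90°
sweep — the one sign-varying component (x′) is resolved by the pair, and the
rectification-honouring least-squares inverse reduces to the signed sum of
channel loads along each axis.

Each channel is affine in its normal load (`signal = load/gain + offset`);
`calibrate()` recovers gains and offsets by per-channel ordinary least
squares from benchtop loads with known magnitude and direction. Channels the
load protocol never excites are flagged `NA`, never invented.

`run_calibration_benchmark()` replays the benchtop accuracy protocol: polar
angles 30–90° from the pole, azimuths 0–45°, both in 15° increments, three
repetitions, magnitudes 50–800 N in 150 N steps (bracketing the measured
intraoperative range of roughly 85–800 N). The default noise model —
multiplicative Gaussian with a 1 % of-reading SD plus additive Gaussian with
a 0.5 N SD per channel, seedable — yields a mean absolute magnitude error
around 0.7–0.8 % and a mean absolute angular error around 0.4°, inside the
published accuracy class of this instrument family (2.87 %, 1.44°).

```{r benchmark}
run_calibration_benchmark(calibration_model(), noise_spec(), seed = 1)
```

## Trial summary statistics

`segment_cycles()` smooths the flexion trace with a centred 0.25 s moving
average (enough to suppress sensor noise without distorting passive motion
at ~6°/s) and keeps every maximal monotone-increasing sweep rising from
below 5° to above 85° — the rising limb of each of the three protocol
cycles. `summarize_cycle()` extracts, per cycle:

* **maximum force** — the resultant at the most extended posture (the
  minimum-flexion sample), where passive tension is greatest; for U-shaped
  profiles this coincides with the global maximum;
* **minimum force** and the **flexion angle at which it occurs** — global
  minimum of the resultant, earliest sample on ties;
* **force at 90° flexion** — linear interpolation in the flexion angle, or
  the last sample if the sweep tops out between 85° and 90°.

`cov_pct()` is `100 * sd/mean` with the sample (n−1) standard deviation —
the convention verified against the reported intersubject COVs, which match
n−1 and not n. Within-patient COVs need at least two valid cycles and are
flagged missing otherwise; corrupted cycles are flagged and excluded from
aggregates, never silently dropped. `cohort_stats()` aggregates patients the
way the study reports them: cohort mean = mean of patient means,
intersubject COV over patient means, mean intrasubject COV over per-patient
COVs (missing COVs excluded).

```{r cohort}
cohort_stats(reference_cohort())
```

Note two quantities printed in the source table are not reproducible from
its own per-patient means (the maximum-force intersubject COV and the
90°-force cohort mean); the package reproduces the internally consistent
entries and simply reports what recomputation gives for the others.

## The passive musculoskeletal model

`muscle_model()` builds a reduced rigid-segment chain: the pelvis fixed to
ground, the femur on a 3-DOF gimbal hip, and a lumped shank+foot segment on
a 1-DOF knee. The passive trial holds adduction and rotation at zero and
takes hip and knee through the range together, so knee flexion is coupled to
hip flexion by default. Twenty hip-spanning muscles act along polyline paths
(the broad glutei as three compartments each, hence 23 path actuators); the
short external rotators are omitted because the posterolateral approach
divides them. Muscle excitation is zero: each muscle contributes only its
Hill-type passive force under the rigid-tendon assumption,

$$F = F_{iso}\,\frac{e^{k_{pe}(\tilde l - 1)/\epsilon_0}-1}{e^{k_{pe}}-1},
\qquad \tilde l = \frac{L - l_{ts}}{l_{opt}} > 1,$$

with the standard shape constants $k_{pe}=4$, $\epsilon_0=0.6$ (zero force
below optimal fibre length, maximum isometric force at passive strain
$\epsilon_0$). The line of action at the hip is the path segment that
crosses the joint — the segment adjacent to the last pelvis-fixed path
point, so a pelvic via point (the iliopsoas pulley over the brim) deviates
the pull correctly. Gravity acts posteriorly on the supine patient; segment
masses use standard anthropometric fractions of body mass (thigh 0.100,
shank 0.0465, foot 0.0145). Inertia is excluded because trial motion is
slow. The joint reaction is the negated sum of the muscle pulls on the
pelvis and the transmitted limb weight; the balance residual is exactly zero
by construction and asserted to 1e-9 N.

`scale_model()` scales attachment coordinates, segment lengths, optimal
fibre lengths and tendon slack lengths isotropically by the patient/generic
height ratio and masses by the mass ratio. The default target is the
modelled reference patient (151 cm, 58 kg).

### The generic muscle fixture

No generic muscle table could be redistributed with the package, so the
shipped fixture (`hip_muscles_generic_synthetic.csv`, the `synthetic` in the
name is deliberate) was constructed for it: attachment coordinates are
plausible adult lower-limb anatomy on a 170 cm skeleton, and the two
free Hill parameters per muscle were solved from two interpretable design
quantities — the flexion angle at which the muscle becomes taut (flexors
engage toward extension, extensors toward deep flexion, abductors stay
within slack over a pure sagittal sweep) and the normalised passive force it
reaches at its taut end of the sweep. Where the implied fibre length
exceeded 80 % of the path length it was capped and the strength rescaled to
preserve the end-force target, so `f_iso_max` values are effective rather
than physiological. The construction was frozen before the test suite
existed; its stated design envelope is the measured qualitative behaviour
(U-shaped resultant, interior minimum between 10° and 50°, extensors
lengthening monotonically with flexion and flexors with extension).

With the patient-scaled default model the sweep gives a resultant of about
229 N at extension, a minimum of about 95 N at 32° and about 171 N at 90° —
the same U-shape and direction swing as the measurements (posterior
component growing, superior component fading with flexion), with the
minimum inside the measured 11–50° range. Per-muscle soft-tissue stiffness
is not identifiable from trial data, so a single global `passive_scale`
multiplier is exposed instead.

```{r sweep, eval = FALSE}
model <- scale_model(muscle_model(), height_cm = 151, mass_kg = 58)
sw <- sweep_flexion(model)
autoplot(sw)
```

## The synthetic cohort generator

`virtual_patient_spec()` fixes the study conditions: a U-shaped resultant
through the anchors (f at extension, minimum f at its angle, f at 90°) with
the modelled patient's means as defaults; a constant mediolateral component
(0.25 of the minimum force — the measured mediolateral component is small
and nearly constant); and an in-plane direction that rotates linearly from
superior at extension toward posterior at deep flexion, parameterised by two
crossover angles. The defaults put the anterior-to-posterior crossover at 0°
(posterior component non-negative throughout) and the superior-to-inferior
crossover at 90° (the superior component decays to zero at deep flexion) —
the choice that maximises the compressive margin on the sensors while
matching the reported component directions. The resultant interpolates its
anchors with shape-preserving monotone cubics (zero slope at the minimum and
the outer ends), so it never undershoots the specified minimum.

`generate_recording()` builds the triangular flexion profile (15 s per
half-sweep at 100 Hz — slow passive motion, consistent with neglecting
inertia), maps the ground-truth pelvic force into the head frame by the
inverse chain, projects it onto the four channels with the noise model, and
returns the raw log with its ground truth; everything is deterministic given
the seed. `generate_cohort()` draws per-patient magnitudes log-normally
(joint forces are positive and the measured between-patient spread is large
and right-skewed), parameterised by cohort means and CVs with the measured
four-patient cohort as defaults; the log-normal is moment-matched so the
requested CV is the analytic CV of the distribution.

What the generator deliberately does **not** emulate: flexion-angle
measurement error (the angle trace is exact), sensor drift, temperature
sensitivity and hysteresis, abduction/adduction excursions, and any
dislocation or rim-loading events. Passing round-trip tests therefore
demonstrates the correctness of the pipeline's algebra and statistics under
the stated noise model — not robustness to every artefact of a real
intraoperative recording.

## Numerical choices

* Orthonormality tolerance 1e-12; chain-vs-oracle and force-balance
  tolerances 1e-9 N (double-precision headroom at the 10–1000 N scale).
* Ties at the force minimum resolve to the earliest sample; force at 90° is
  linear interpolation in the flexion angle.
* Smoothing (0.25 s centred moving average) is applied only for cycle
  segmentation; summary metrics are computed on the raw resultant, keeping
  the noiseless pipeline bias-free.
* The flexion angle of the minimum force sits in a nearly flat basin on the
  flexion side of the U (the curvature there is ~30x smaller than on the
  extension side for the default anchors), so under sensor noise its
  location is judged on the sweep's full scale (within 4.5°, i.e. 5 % of
  90°) rather than relative to its own small value; the force metrics
  recover to 1 % noiseless and 5 % under default noise.
* Recordings reconstruct per sample with vectorised closed-form rotations;
  a full three-cycle 100 Hz trial (~9000 samples) processes in well under a
  second, and the test suite's simulations use the same full-scale
  recordings throughout.

## Limitations

The model is a sagittal-plane passive chain: no pelvic tilt or obliquity, no
wrapping-surface muscle geometry, no tendon compliance, no subject-specific
stiffness. The fixture is synthetic-generic: patterns and magnitudes are in
the measured range, but per-muscle forces are not anatomical ground truth.
The generator's component split is validated only qualitatively, since no
numeric component magnitudes are available to anchor it.
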