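---
title: "Methods: sensing, gait segmentation, and benchmarking in spfgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensing, gait segmentation, and benchmarking in spfgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spfgait)
```

## The sensing model

The instrumented foot carries 16 optoelectronic pressure transducers
(tactels) between the carbon lamina and the foot cover — 5 under the heel
and 11 under the forefoot — plus an IMU on the tibial part. A pressed
tactel outputs a negative voltage related to the applied normal force by a
quartic characterization curve

$$F(V) = p_1 V^4 + p_2 V^3 + p_3 V^2 + p_4 V + p_5 \quad [\mathrm{N}]$$

with coefficients $p_1 = 186.1$, $p_2 = 224.5$, $p_3 = 64.76$,
$p_4 = -18.59$, $p_5 = 0$. Because $p_5 = 0$, an unpressed tactel reads
0 N, and on the negative branch the curve is strictly monotone
(force grows as voltage becomes more negative), which is what makes the
inverse map well defined for the simulator. The curve was obtained under
quasi-static normal loading; shear sensitivity, viscoelasticity, and
hysteresis are not modeled (see Limitations).

The vertical ground reaction force is the gated sum
$\mathrm{vGRF} = \sum_i F(V_i)\,[V_i \le V_T]$, and the longitudinal
center of pressure is the force-weighted mean coordinate
$\mathrm{CoPy} = \sum_i F_i w_{y_i} y_i / \sum_i F_i w_{y_i}$, defined
only when $\mathrm{vGRF} \ge \mathrm{vGRF_T}$.

Three modeling choices deserve comment because the reference design
leaves them open:

* **Orientation of the CoPy validity condition.** As printed, the
  source formula marks CoPy valid when $\mathrm{vGRF} \le
  \mathrm{vGRF_T}$ and undefined otherwise — the opposite of the
  physics (the center of pressure exists only when the foot is loaded)
  and of the pressure-threshold detector, for which stance *is*
  $\mathrm{vGRF} \ge \mathrm{vGRF_T}$. We treat this as a typographical
  inversion and define CoPy on the loaded side.
* **$V_T$ value.** Only the existence and purpose of the gate (noise
  rejection on unpressed tactels) are specified. The default is
  $V_T = -0.05$ V, ten standard deviations of the default simulator
  voltage noise, so an idle tactel essentially never leaks into the force
  sum. It is configurable in the JSON config.
* **Per-tactel coordinates and CoP weights.** Only the 0–22.8 cm span and
  the 5/11 heel/forefoot split are constrained. The bundled layout places
  the heel tactels uniformly on [0, 6] cm and the forefoot tactels
  uniformly on [12, 22.8] cm, with a sensor-free midfoot gap as in the
  physical sole. The weights $w_{y_i}$ default to 1 for every tactel: the
  lever arm is already carried by $y_i$, and the estimator is invariant to
  a common positive scaling of the weights, so a distinct physical weight
  would only matter if tactels were to be de-emphasized individually.

Negative calibrated forces (possible for very small deflections) are
clamped to 0 N per tactel, and gating monotonicity holds in the physical
direction: making the gate stricter (more negative $V_T$) never adds
active contributions.

## The two event detectors

**Pressure-threshold rule.** Stance is $\mathrm{vGRF} \ge
\mathrm{vGRF_T}$ with $\mathrm{vGRF_T}$ tuned within [10, 20] N
(default 15 N); HS and TO are the swing→stance and stance→swing
transitions. Comparisons are inclusive and the event timestamp is the
first sample of the new phase — no sub-sample interpolation, since errors
are reported at 10 ms resolution. A trial that starts mid-phase emits no
event for the partial leading phase.

**IMU finite-state machine.** The causal single-pass detector cycles
through `WAIT_MSW → SEARCH_HS → IDLE → SEARCH_TO`, with thresholds
$\omega_{xT}^{MSw} = 75$ deg/s, $\omega_{xT}^{TO} = -65$ deg/s,
$a_T = 7$ m/s², a 0.75 s HS search window after mid-swing (timeout edge
back to `WAIT_MSW`), a 0.4 s idle after HS, and a 30 ms pre-peak window
for the acceleration burst test. A "local maximum" is undefined for
streaming data, so the package confirms an extremum once
`confirm_lag` samples (default 3, i.e. 30 ms at 100 Hz) have passed
without a more extreme value; the emitted timestamp is the extremum time,
the knowledge of it is delayed by the lag. Ties on plateaus resolve to
the earliest plateau sample. The idle timer is anchored at the HS event
timestamp (not its confirmation time), which reproduces the
offline-equivalent behavior of the published state diagram. At 100 Hz the
pre-peak window covers 3 samples; rates that cannot fit 2 samples in it
are rejected as a configuration error.

Both detectors are deterministic, and the FSM structurally guarantees
alternating HS/TO output (at most one HS per mid-swing).

## The synthetic gait generator

`simulate_trial()` emulates the signal morphology the detectors assume,
with known ground truth:

* **Stance vGRF**: two raised-cosine lobes (weight acceptance centered at
  28% of stance, push-off at 72%, half-widths 28% of stance, second lobe
  at 95% amplitude), zero at contact and lift-off, peaking at
  `peak_scale` × body mass (default 10.4 N/kg, the scale of force-plate
  measurements of mass-normalized peak vGRF). A generative form is a
  package choice; the source reports only measured profiles.
* **CoPy**: a monotone smoothstep from 2 cm (heel region) at contact to
  21 cm (forefoot region) at lift-off.
* **Tactel forces**: the instantaneous total is spread over the tactels
  nearest the instantaneous CoPy with an Epanechnikov kernel (half-width
  3 cm), then side masses are rebalanced linearly so the weighted
  centroid equals the target *exactly* (the balance equation is linear in
  the force fractions, so the correction is exact to rounding). The
  simulator additionally imposes a per-tactel force floor equal to the
  gate-equivalent force $F(V_T)$, so that every emitted nonzero force
  maps to an *active* voltage; when the floor and exactness conflict
  (support collapsed to two tactels very close to the target), exactness
  wins and a sub-floor force — at most a gate-equivalent worth, gated out
  by the sensing chain — is allowed. This corner only arises at
  barely-loaded frames near contact/lift-off.
* **Voltages**: forces pass through the inverse calibration on the
  negative branch ([-2, 0] V, validated as monotone at startup), plus
  i.i.d. Gaussian voltage noise (SD 0.005 V).
* **IMU**: per stride, one positive angular-velocity hump (150 deg/s)
  peaking at mid-swing, one negative trough (−120 deg/s) centered at true
  TO, and a sharp `az` impact transient (12 m/s², half-width 30 ms)
  20 ms after true contact on top of gravity (9.81 m/s²); channel noise
  SDs 0.1 m/s² and 1 deg/s. Accelerations are raw accelerometer output
  (gravity included), matching the assumption of the FSM. Positive
  $\omega_x$ is the swing-phase rotation, used identically by detector
  and simulator.
* **Force plate**: the noise-free profile sampled at 200 Hz plus 0.5 N
  noise; on-board sensors run at 100 Hz.

Default study conditions: stride period 1.6 s, duty factor 0.62, body
mass 70 kg, 20 strides per trial, with the first heel strike one full
swing after trial start so the FSM's arming peak exists for stride 1.
Everything is driven by one integer seed; identical seeds give bitwise
identical trials.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: partial plantar coverage (the main cause of
the large real-world underestimation of PS vGRF), tactel viscoelasticity
and shear response, inter-subject and inter-stride variability of timing
and morphology, soft-tissue and shoe effects, broken tactels (beyond
manually zeroing channels), and force-plate geometry (stride exclusion
for partial plate contact is a no-op here).

## Benchmarking procedure

Reference events come from the force-plate channel with the conventional
20 N threshold. Detected events are paired to reference events one-to-one
per type by an order-preserving assignment that maximizes the number of
within-gap pairs and then minimizes total absolute error (the gap
defaults to half the reference stride period); a greedy nearest-neighbor
rule can differ from the optimal assignment in conflict cases, so the
optimal one is used. Timing errors are `detected − reference`; each trial
is summarized by the median absolute error and the IQR of absolute errors
(linear-interpolation quantiles, the `type = 7` convention), and trials
are grouped by the median of the per-trial summaries — individuals first,
then the group, mirroring per-subject-first reporting. Both pooled and
per-trial numbers are retained.

Waveform agreement uses the offline path only: tactel voltages are
low-pass filtered (2nd-order Butterworth, 25 Hz cutoff, applied
forward–backward for zero phase; odd-reflection padding suppresses edge
transients so the DC gain is exact), vGRF and CoPy are recomputed,
resampled over 1000 samples between reference HS and TO, and compared by
Pearson correlation and RMSE, pooled and per stride. The vGRF reference
waveform is the force-plate channel; the CoPy reference is the
generator's analytic trajectory, standing in for the motion-capture-based
force-plate CoP that simulation cannot provide. Mass-normalized per-stride
vGRF peaks are summarized as median (IQR) for both sources.

**Direction of the stance-duration bias.** Against *ground truth* both
detectors underestimate stance robustly: the force must rise to the
threshold after contact and falls below it before lift-off, and the IMU
impact peak lags contact. Against the *20 N reference* the sign depends
on the pressure threshold: at $\mathrm{vGRF_T} = 15$ N the PS events
bracket the 20 N reference window, because the simulated PS vGRF is not
coverage-underestimated the way the physical sensor's is. The package
therefore states the bias property against truth.

## Numerical choices

* Calibration evaluation is nested (Horner); the inverse is a bracketing
  root-finder (`stats::uniroot`, tolerance 1e-12 V) on a branch whose
  monotonicity is checked on a dense grid. The simulator uses a
  vectorized grid-seeded Newton polish for speed; it agrees with the
  bracketing inverse to well below the 1e-6 N contract.
* Stance resampling is linear interpolation (exact on linear signals);
  quantiles are linear-interpolation order statistics; Pearson/RMSE are
  computed over finite samples only.
* Degenerate inputs are explicit errors: empty series, non-uniform
  timestamps, loaded frames whose CoP weights all vanish, cut-off at or
  above Nyquist, stance windows with `to <= hs`, non-alternating event
  sequences.

## Problem sizes

The validation suite runs cohorts of 10 trials × 20 strides at default
noise for the end-to-end timing budget, 1000-frame random batches for
the CoPy oracle, and a few hundred random draws for the distribution,
matching, and statistics oracles — sizes at which every property is
exercised across the full operating range of the sensors while the whole
suite completes in well under a minute.

## Limitations

The package validates the *algorithms*, not the hardware: agreement on
synthetic trials bounds implementation error, not sensing error. Real
deployments add unmodeled effects listed above; in particular, absolute
PS vGRF amplitude should be treated as qualitative (its real-world
counterpart is strongly coverage-dependent), while event timing and CoPy
progression are the quantities the design targets.
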