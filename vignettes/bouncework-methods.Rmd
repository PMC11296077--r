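---
title: "Methods: work partition, spring-mass-actuator fit, and the synthetic test bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: work partition, spring-mass-actuator fit, and the synthetic test bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bouncework)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the defaults and why they were chosen, the
numerical decisions, and what the synthetic test bench does and does not
demonstrate about real data.

## Coordinate and frame conventions

All mechanics are sagittal-plane: `y` is the fore–aft axis, positive in
the runner's direction of progression; `z` is vertical, positive up. The
frame is fixed to the treadmill machine (the lab), so the belt surface
moves at `−V_avg` along `y` and a steady runner is stationary on average.
The lateral force component is dropped; in steady running its
contribution to external work is negligible.

The force record is the master clock; markers are spline-resampled onto
it. Half-open, 0-based-in-spirit index intervals `[touchdown, toeoff)` on
the 1 kHz grid define contacts; strides run from one right touchdown to
the next.

## External (CoM) work

Newton's law per axis gives the CoM accelerations directly from the
forces, `a_f = F_y/m` and `a_v = F_z/m − g`. Velocities and the vertical
displacement follow by trapezoidal cumulative integration *per stride*,
with the integration constants chosen so the stride **time average**
(trapezoidal, not the raw sample mean — consecutive strides share their
boundary sample, and an arithmetic mean double-counts it, which leaks a
linear drift into `S_v` of order 1/n) of `v_f` and `v_v` is zero in the
lab frame. Per-stride constants stop integration drift from accumulating
over the trial; the analysis is per-stride anyway.

The fore–aft energy is evaluated in the frame of the belt surface:

`E_kf = ½ m (v_f − v_belt)² = ½ m (v_f + V_avg)²`.

This is the only frame in which the mechanical energy of a treadmill
runner behaves as it does overground: braking lowers `E_kf` while the
body descends, so `E_kf` and `E_v = ½ m v_v² + m g S_v` fluctuate in
phase — the signature of a bouncing gait. Writing the offset with the
opposite sign (subtracting a positive belt speed in progression-positive
axes) would put the two curves in anti-phase during stance, misrepresent
the gait, and break the exact power balance that links external-plus-
internal work to joint work on rigid-body data. With the belt-frame form
and a dynamically consistent rigid trial, the identity

`d(E_com + ΣE_int)/dt = Σ_joints M_j ω_j`

holds exactly (stationary-in-belt-frame contact, non-rotating trunk),
which is what makes the soft-tissue null test meaningful.

`W_com±` are the sums of positive/negative sample-to-sample increments of
`E_com` over the stride — no smoothing, no dead band (the 30 Hz filter
already suppresses noise). The two sums telescope:
`W⁺ + W⁻ = E(end) − E(start)` exactly.

## Internal work and the transfer assumptions

Each limb is thigh (GT–knee), shank (knee–ankle) and foot
(ankle–midpoint(heel, VM)); the trunk is one rigid segment from
midpoint(waist, backwaist) to the neck marker. The foot's distal point is
the heel/fifth-metatarsal midpoint because it is stable against toe-marker
occlusion. Segment energies `½(m_i V_i′² + I_i ω_i²)` (velocities relative
to the force-derived CoM) are summed over the segments of one limb
*before* increments are taken: energy may flow between ipsilateral
segments but not between limbs, not with the trunk, and not with the CoM
energy. The same rule is applied at the joint level: joint powers of one
limb are summed per frame before integration. Allowing all-segment
transfer would reduce total work substantially and change the meaning of
the residual.

Anthropometry ships as a named, swappable table; the default `"winter"`
carries the standard Winter/Dempster fractions (foot 0.0145/0.50/0.475,
shank 0.0465/0.433/0.302, thigh 0.100/0.433/0.323, trunk-head-arms
0.678/0.626-from-hip/0.496 for mass, CoM position and gyration radius).
The modelled masses sum to exactly 1, which the synthetic bench relies
on. Velocities and accelerations come from central differences on the
filtered 1 kHz grid, with second-order one-sided stencils at record ends.

## Inverse dynamics

Bottom-up sagittal Newton–Euler with hinge joints: the foot receives the
GRF at the COP (frames assigned wholly to the contacting foot, zero to
the airborne foot — running has no double support and the pipeline
refuses overlapping contacts), then ankle, knee and hip are solved in
turn. Joint centres are the GT, knee and ankle markers without offsets.
COP samples under the 300 N validity threshold inside a loaded frame are
clamped to the nearest valid sample; the error is bounded because force,
hence moment, is small there. Reported moments are extension-positive at
the ankle and hip and flexion-positive at the knee; the joint angular
velocity carries the matching sign so `P_j = M_j ω_j` holds exactly at
every frame.

## Total and soft-tissue work

`W_tot± = W_com± + W_int,R± + W_int,L± + W_int,trunk±` and
`W_ST± = W_tot± − W_j,R± − W_j,L±`, both exact by construction. The
rigid-body joint route misses non-rigid motion; the residual is
attributed to soft-tissue deformation. On perfectly rigid synthetic
trials the residual is not exactly zero — the four-bucket (CoM, two
limbs, trunk) and two-bucket (per-limb joint) decompositions cancel
cross-bucket transfers differently — so the test bench asserts a 10%
bound on `|W_ST−|/W_tot+` as an engineering null, not zero.

## Spring-mass-actuator fit and hysteresis

Per contact, the leg is the COP→GT line; `L_leg` its length, `V_leg` its
central-difference derivative, and `F_projected` the mass-specific GRF
component along it. Frames with `F_z < 300 N` are masked (the treadmill
COP is unreliable at low load) and the COP is never extrapolated past the
mask. Ordinary least squares of `F_projected` on `[1, L_leg, V_leg]`
gives `cst`, `k` and `c`, per step; per-stride values average right and
left steps first, then strides — matching the statistics pipeline.
Because the regressor is leg *length* (not compression), a spring-like
leg has a negative slope; `|k|` is the stiffness magnitude and `c < 0`
means the actuator absorbs energy like a damper.

Compression runs from touchdown to the global minimum of `L_leg`
(earliest index on ties); monotone contacts are excluded from the
hysteresis with a warning. The printed split-integral form of the
compression/decompression area difference, taken literally with signed
`dL`, does not vanish for a conservative spring traversing a closed loop;
the package therefore computes `Δ_area` as the hysteresis loop area
`−∮F dL` (absorbed minus returned work), which is zero for any pure
spring and positive for a damper — consistent with its use as deviation
from elastic behaviour. The literal variant stays available behind
`analysis_config(delta_area_mode = "literal")` for auditing. For the
sinusoidal loop `L = L₀ − A(1 − cos ωt)` under `F = cst + kL + cV` the
loop area has the closed form `−c·π·A²·ω`, which anchors the oracle
tests.

## Statistics

Pearson's r with the Fisher-z interval (`atanh`, half-width
`qnorm(0.975)/√(n−3)`, back-transformed) and a two-sided p from the t
distribution with n−2 degrees of freedom. `pearson_ci(r =, n =)`
reproduces interval arithmetic for published coefficients without raw
data. The correlation table relates `Δ_area` to total soft-tissue work
(`|W_ST⁺| + |W_ST⁻|`), to `c` and to `k`. Mixed-effects condition
modelling is out of scope; condition means ± SD are reported instead.

## Defaults and tunables

| parameter | default | why |
|---|---|---|
| force/marker cutoff | 30 Hz | top of the instrumented treadmill's documented 10–30 Hz band, also used for kinematics; configurable |
| filter | 8th-order Bessel, forward–backward | zero lag; analog prototype pre-warped so the two-pass −3 dB lands at the cutoff |
| contact threshold | 10% of body weight | standard vertical-force event rule |
| debounce | 20 ms | removes threshold chatter without deleting real contacts |
| COP validity | 300 N vertical | treadmill COP unreliable below |
| anthropometry | Winter table | the conventional source; swappable |
| Δ_area mode | loop | see above |

## The synthetic test bench

`simulate_trial()` builds trials force-first: one half-sine vertical
burst per step whose stride impulse balances body weight exactly (flight
force exactly zero, never negative), plus a 0.5-body-weight, 60 ms
early-stance impact transient (the rearfoot impact peak of real traces;
its impulse is compensated in the active peak), and a braking-then-
propulsion fore–aft sinusoid with zero net impulse. The CoM comes from
trapezoid integration of that force — the same scheme the pipeline uses.
Feet ride the belt during stance (translation at −V, no rotation) and
swing through three C²-joined quintic phases (decelerate, carry forward,
paw back to belt speed); knees follow by two-link inverse kinematics with
the anterior branch; and the trunk position is solved per frame so the
anthropometric mass-weighted CoM of all seven segments equals the
force-derived CoM to machine precision. Newton consistency is therefore
an identity, not an approximation — that is what gives the rigid-mode
soft-tissue null its meaning. A joint-angles-first construction cannot
deliver this: arbitrary smooth joint trajectories do not produce
ballistic flight.

Geometry is a deliberately crouched model (CoM at 0.49·height, deeper
when long flight phases demand extension reserve) so the legs keep
flexion margin at touchdown across the whole 8–17 km/h × 2.0–3.6 steps/s
grid; infeasible parameter sets are rejected with a reach error. Default
contact time is a rough published-contact-time fit,
`min(0.13 + 0.25/V, 0.8·T_step, 0.70/V)` s. Step frequency is snapped to
the force grid so a stride is a whole number of samples. Instrument noise
defaults to zero and is opt-in (`force_noise_sd`, `marker_noise_sd`, with
a mandatory seed).

**Wobble mode** splits the trunk into a rigid remainder and a wobbling
point mass (defaults: 15% of body mass, 10 Hz, damping ratio 0.4 —
typical wobbling-mass model values) joined by a vertical spring-damper.
During stance the wobble's inertial force flows into the GRF, so the
whole-body CoM deviates; during flight it flows into a recoil of the
rigid skeleton, so the force stays exactly zero; a smooth quintic stance
weight blends the two routes, and the oscillator is integrated in the
time domain (RK4 at 1 kHz) including the recoil feedback. The
construction stays dynamically consistent at every instant, which makes
the damper's energy `∫c ṙ² dt` per stride an exact invariant: the net
joint work per stride equals it identically on the clean signals (the
test suite asserts this within numerical error). The differencing test —
wobble minus rigid, same kinematics — therefore recovers the ledger
dissipation through the **net** soft-tissue change
`−Δ(W_ST⁺ + W_ST⁻)`; the per-sign split is deliberately not the target,
because a damped oscillator genuinely stores and returns energy within
the stride (soft tissues do both signs of work), inflating `ΔW_ST⁻` and
`ΔW_ST⁺` together.

**What the bench does not emulate.** The trunk-mounted wobble barely
couples into the COP→GT force–length loop (both endpoints sit outside the
wobbling mass's path), so trial-level `Δ_area` is nearly flat across the
wobble damping sweep. In real runners the hysteresis–dissipation coupling
is carried by leg-level soft tissue (heel pad, shank and foot structures)
below the GT marker, which this generator deliberately does not model —
modelling it while preserving the exact energy ledger would require a
compliant contact. The hysteresis–dissipation relationship is therefore
validated at the level where it is exact: the spring-loop harness
(`simulate_spring_loop()`), where a damping sweep gives a strictly
increasing measured `Δ_area` and a correlation with the per-loop
dissipated energy near 1. Passing the bench consequently shows that the
pipeline measures each construct correctly and that dissipation injected
above the hip is recovered by the work partition; it does not certify the
empirical trunk-wobble-to-leg-loop pathway seen in human data.

Other non-emulated features: no marker soft-tissue artifact, no
double-support gaits, no arm swing, no frontal/transverse mechanics, no
physiological joint-moment profiles (the construction's moments are
whatever the prescribed kinematics imply — they are compared at matched
30 Hz bandwidth because the phase transitions carry supra-physiological
frequency content that the study's own filter removes).

## Numerical choices

- Bessel biquad cascade (4 second-order sections) rather than a direct
  8th-order recursion: direct forms are ill-conditioned at cutoff/rate
  ratios of 0.03. Odd-reflection padding suppresses edge transients.
- Cubic splines (`stats::spline`, fmm) for marker oversampling: exact at
  the original sample times and on cubic trajectories.
- Trapezoidal integration everywhere, matching the stated scheme;
  integration constants via trapezoidal time averages (see above).
- Ties in the compression split break to the earliest index; degenerate
  (monotone) contacts are excluded from `Δ_area` with a warning; open
  loops (end gap > 10% of compression depth) are flagged.
- OLS through a QR factorization; the rank check rejects collinear
  designs. Tests cross-check coefficients against plain normal equations
  and R²/RMSE against their textbook forms.
- Problem sizes used by the test bench: 6–10-stride trials at 1 kHz,
  50-step Monte-Carlo spring fits, 2000-replicate coverage runs — all
  chosen as the smallest sizes at which the asserted tolerances are
  comfortably diagnostic.

## Known limitations

- The soft-tissue residual inherits every inverse-dynamics assumption
  (segment inertia tables, marker-defined joint centres, hinge joints);
  it is an estimate of non-rigid energy flow, not a tissue-level
  measurement.
- `E_kf` requires the belt speed; belt-speed fluctuation under load is
  not modelled (V_avg is treated as constant).
- The C3D path implements the Intel-float subset only.
- Foot labelling uses ankle-to-COP proximity at mid-contact; it assumes
  a single-belt treadmill and alternating gait.
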