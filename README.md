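# bouncework

Mechanical work partition and spring-mass-actuator analysis of treadmill
running, for biomechanists who record ground reaction forces (GRF) and
sagittal-plane marker kinematics on an instrumented treadmill.

During running the muscle-tendon system does work to move the body, but a
measurable fraction of the mechanical energy is absorbed and partly
returned by non-rigid tissues — heel pad, viscera, muscle and fat wobble.
`bouncework` quantifies that soft-tissue contribution and relates it to
the elastic quality of the bounce:

1. **External work** `W_com±`: the CoM accelerations come from the force
   record (`a_f = F_y/m`, `a_v = F_z/m − g`), trapezoid-integrated per
   stride with zero-time-average constants, giving the energy of the CoM
   relative to the surroundings
   `E_com = ½m(v_f − v_belt)² + ½m v_v² + m g S_v`; positive and negative
   work are the signed increment sums of that curve.
2. **Internal work** `W_int±`: segmental energy
   `E_int,i = ½(m_i V_i′² + I_i ω_i²)` with `V_i′` relative to the CoM,
   summed over the segments of each limb *before* taking increments
   (energy may transfer within a limb, not between limbs), plus a trunk
   term.
3. **Joint work** `W_j±`: sagittal bottom-up Newton–Euler inverse dynamics
   (foot → ankle → knee → hip, hinge joints), joint powers
   `P_j = M_j ω_j` summed per limb, time-integrated, increments signed.
4. **Soft-tissue work**: the rigid-body route misses non-rigid motion, so
   `W_tot± = W_com± + W_int,R± + W_int,L± + W_int,trunk±` and
   `W_ST± = W_tot± − W_j,R± − W_j,L±`.
5. **Bouncing mechanism**: over each contact the leg is the COP→greater
   trochanter line; the mass-specific GRF projected on it is regressed as
   `F_projected = cst + k·L_leg + c·V_leg` (leg stiffness `k`, actuator /
   damping coefficient `c`, negative `c` = energy-absorbing damper), and
   the force–length hysteresis `Δ_area = −∮F dL` measures the deviation
   from an ideal elastic rebound. Note that regressing on leg *length*
   makes a spring-like leg's slope negative; `|k|` is the stiffness
   magnitude.
6. **Statistics**: right/left-then-stride averaging and Pearson
   correlations with Fisher-z 95% confidence intervals.

Every stage is validated end-to-end on synthetic treadmill trials with
exact ground truth (`simulate_trial()`): prescribed feasible GRF, inverse
kinematics limbs, a trunk solved so the model CoM matches the force CoM
identically, and an optional wobbling-mass element whose dissipated energy
per stride is known exactly.

## Worked example

```r
library(bouncework)

# a 10-stride synthetic trial: 73.7 kg runner, 14 km/h, 2.8 steps/s
sim <- simulate_trial(sim_params(belt_speed = 14/3.6,
                                 step_frequency = 2.8, n_strides = 10))
an  <- analyze_trial(sim$trial)
print(sim$trial)
#> <bw_trial> subject sim, mass 73.7 kg, belt 3.89 m/s
#>   forces : 7337 samples @ 1000 Hz (7.34 s)
#>   markers: 1468 samples @ 200 Hz, 13 markers
print(an)
#> <bw_analysis> 10 strides, 20 step fits
#>   W_tot+ 6.36  W_tot- -6.36  W_ST+ 0.16  W_ST- -0.16  (J/kg, stride mean)
#>   spring fit: k -219.5 N/kg/m, c -3.0 N s/kg/m, R2 0.985, delta_area 1.267 J/kg
```

Reading: the body performs 6.36 J/kg of positive total work per stride and
absorbs the same amount (steady state); on this *rigid* synthetic trial
the soft-tissue residual is a 0.16 J/kg bookkeeping floor (2.5% of
`W_tot+`), the leg behaves almost linearly (R² = 0.985) with a stiffness
magnitude of 220 N·kg⁻¹·m⁻¹, and the contact loop hysteresis is
1.27 J/kg. Published-scale correlation arithmetic is one call:

```r
pearson_ci(r = 0.70, n = 193)
#> r(191) = 0.70 (95% CI [0.62, 0.77]); p = 9.69e-30
```

A wobble-mode trial (`sim_params(..., wobble = list(zeta = 0.4))`) injects
a damped oscillating mass with an exactly known dissipation per stride;
differencing its analysis against the rigid trial recovers that
dissipation through the `W_ST` partition.

A thin command-line layer is included
(`inst/cli/bouncework analyze|simulate|correlate`), and trials round-trip
through a tab-separated text format (`write_trial()`/`read_trial()`) or a
minimal C3D path (`write_c3d()`/`read_c3d()` with a marker alias table).

## Scope

Sagittal plane only (the lateral GRF component is negligible in steady
running); no arm segments (their power contribution is minor and the
internal/joint routes treat them consistently); running gaits only — no
double-support walking. See the methods vignette
(`vignettes/bouncework-methods.Rmd`) for the model assumptions, parameter
defaults, generator design and known limitations.
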