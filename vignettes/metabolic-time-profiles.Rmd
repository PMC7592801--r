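---
title: "Estimating the within-stride time profile of metabolic rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the within-stride time profile of metabolic rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridemet)
```

Indirect calorimetry measures the metabolic rate of walking once per
breath, so only stride *averages* are observable. This package estimates
the unobservable *time profile* of metabolic rate within the stride cycle
by two routes that share the same joint-level inputs, and provides the
statistical machinery to ask whether the routes agree with calorimetry
and with each other. This vignette explains the models, their
assumptions, the tunable parameters, the synthetic-data generator that
stands in for laboratory recordings, and the numerical choices that make
the pipeline well-posed.

## The musculoskeletal route

### Muscle-tendon model

Each of the eight modeled muscles is a Hill-type muscle-tendon unit:
contractile element (CE) and parallel elastic element in series with a
tendon, under a constant-thickness pennation model
(`l_fiber * sin(pennation)` constant). The normalized curves are:

- active force-length: a Gaussian in normalized fiber length whose value
  drops to `fl_floor` (default 0.05) one width coefficient away from
  optimal length; the width comes from the per-muscle parameter table;
- force-velocity: a Hill hyperbola on the shortening side (curvature
  `af = 0.25`) and an exponential approach to an eccentric plateau
  (default 1.5 `F_max`) with slope continuity at zero velocity;
- passive element and tendon: exponential toes reaching `F_max` at 60%
  fiber strain and 4.9% tendon strain respectively, extended linearly
  (C1) at extreme strains so transients cannot overflow.

Muscle excitation is the MVC-normalized EMG envelope; activation follows
first-order dynamics with asymmetric time constants (15 ms activation,
60 ms deactivation), integrated by the exact exponential update. The
lateral gastrocnemius, for which no EMG is recorded, is driven by the
medial gastrocnemius channel.

The fiber length is the only mechanical state per muscle. At each step
the fiber velocity solves the damped force equilibrium

    a fl(l) fv(v) + beta v / v_max + f_pe(l) = f_tendon / cos(pennation)

by safeguarded Newton iteration; the left side is strictly increasing in
`v`, so the root is unique and depends smoothly on every parameter. The
small damper (`beta = 0.1`, in units of `F_max` at `v_max`) is standard
in equilibrium muscle models: without it the velocity solve becomes
singular at low activation or slack tendon, and the integrated dynamics
turn effectively chaotic — a 1e-8 relative parameter change then produces
order-1e-3 changes in simulated moments, which destroys any calibration.
The reported `f_ce` is the active contractile force at the true
activation; the damper and the solver's activation floor are accounted in
the reported equilibrium residual, which stays at solver tolerance
(~1e-7 `F_max`) throughout.

Integration is classical fixed-step Runge-Kutta with substeps chosen so
the effective step does not exceed a per-muscle bound that scales with
tendon slack length (0.01 s per meter of slack, clamped to 0.5-2.5 ms).
The bound reflects the stiffness of the tendon-fiber equilibrium: the
relaxation time scales with tendon compliance, and the gluteus maximus
with its 5 cm tendon is the binding case. Halving the step changes fiber
trajectories by well under 0.1%. The default initial state is the
rigid-tendon fiber length at the first sample with activation equal to
the first excitation sample; the first two strides are treated as
warm-up and excluded from every reported quantity.

### Geometry

Muscle paths are reduced to per-joint moment-arm polynomials
`r_j(theta)`, with the muscle-tendon length defined so that
`d l_mt / d theta_j = -r_j` exactly. The packaged arms are constant
normative sagittal values; they are configuration, not measured anatomy.
One geometric choice matters for calibration: the reference lengths place
the neutral-pose fiber at 1.10 optimal lengths, so that under load the
fibers operate on the plateau and upper ascending limb with the passive
element engaged at the long end of the excursion. This is the
physiologically typical operating range for the plantarflexors in
walking, and it is what makes the two calibrated length parameters
jointly observable: the tendon toe pins the slack length, while the steep
passive curve pins the optimal length. With fibers confined to the deep
ascending limb the two parameters trade off along a compensation valley
(a longer tendon against a shorter fiber) that joint moments cannot
resolve — we verified cost changes of only ~1e-5 (N m/kg)^2 at 50%
parameter error in that regime.

Sign conventions are package-wide: hip flexion, knee flexion and ankle
dorsiflexion positive for both angles and moments (a positive moment acts
to increase the angle). "Extension direction" therefore means a negative
moment.

### Muscle energetics

Per muscle and sample, metabolic rate is the sum of:

- activation-maintenance heat: a base rate linear in the effective
  fast-twitch fraction, scaled by activation to the power 0.6 and — above
  optimal fiber length — by the active force-length value;
- shortening-lengthening heat: proportional to normalized fiber velocity
  with separate shortening coefficients per fiber type (inversely
  proportional to the fiber-type maximum shortening velocities, scaled by
  activation squared) and a single lengthening coefficient (scaled
  linearly by activation), with the same above-optimum length scaling;
- fiber mechanical work: `f_ce` times shortening velocity, signed, so
  work absorption during lengthening is included.

Fiber-type composition follows an orderly recruitment model: at zero
activation the active pool is entirely slow-twitch, at full activation it
equals the muscle's anatomical ratio, with a smooth monotone transition.
All heat rates are multiplied by the aerobic factor S = 1.5. Per-muscle
rates are converted to W per kg body mass via the muscle masses and
clamped at zero from below per sample (net negative work cannot
synthesize ATP); no resting metabolism is modeled, so all outputs are
net rates. The numeric heat-rate coefficients are a packaged, versioned
configuration set (`energetics_coefficients()`); every structural
property the tests rely on — nonnegativity after clamping, exact
component decomposition, exact linearity in S, zero profile at zero
activation — holds for any positive coefficient values.

### Calibration

Tendon slack length and optimal fiber length of every muscle are
calibrated per participant against reference joint moments on the
baseline (level-grade, level-shoe) trial, minimizing full-stride mean
squared moment errors at the ankle and knee, the hip error restricted to
samples where the reference moment is extensor (the model carries no
uni-articular hip flexor), plus three penalties weighted 1e6 each: the
number of muscles whose tendon force never exceeds 1 N, an indicator
that the soleus mean force falls below the mean of the gastrocnemius
means, and the number of muscles whose fiber length leaves
`[L_opt (1 - w), L_opt (1 + w)]` at any evaluated sample.

The optimizer is a generalized pattern search in the search-poll
paradigm, bounded to 50-150% of the starting values. Because scaling
errors inherited from a common limb-scaling step are strongly correlated
across muscles, a global two-factor scan (all optimal fiber lengths, all
slack lengths) runs first; then each muscle's two parameters are
refined — strongest muscles first, since they carry most of the moment
signal — by a lattice search over the muscle's box followed by compass
polls (coordinate and diagonal directions) with an
expanding/contracting mesh at three refinement scales, at most 300 poll
iterations per muscle search. Sweeps over the muscles repeat (at most
three times) until a pass improves the cost by less than 0.1%, and a
total evaluation budget (6000 cost evaluations) bounds the wall time on
noisy fits where marginal improvements never cease. The plain
coordinate-poll search stalls on this cost surface: the per-muscle
compensation valleys are curved and carry pocket minima, which is what
the lattice search step and the diagonal poll directions are for. On
noise-free truth trials the procedure recovers all sixteen length
parameters exactly from a uniformly 20%-mis-scaled start; under
independent random perturbations the moment error is recovered (MSE
below 1e-3 (N m/kg)^2) but weakly-loaded muscles' optimal fiber lengths
can remain off at that error level — an identifiability limit of
moment-based calibration, not of the optimizer.

For the search the trial is decimated to 100 Hz; all input signals are
6 Hz band-limited, so this loses nothing, and the quantities that do not
depend on the candidate parameters (activations, muscle-tendon lengths,
moment arms) are computed once per calibration rather than per cost
evaluation.

## The joint-space route

Per joint and sample, with moment `M` (N m per kg) and angular velocity
`omega` (rad/s): an activation-maintenance term `c_AM |M|`, a
shortening-lengthening term `c_SL |M omega|`, and mechanical work costed
at separate efficiencies for positive and negative power, with negative
(eccentric) work cheaper. The limb profile is the exact sum over joints;
contralateral and upper-body channels are structurally zero after
unilateral masking. Coefficient values are again a packaged
configuration set (`jointspace_coefficients()`), with an optional moment
dead-band (default 0); additivity, per-sample nonnegativity and the
zero-input zero-profile identity are coefficient-independent. Metabolic
cost is attributed to muscle groups by the sign of the joint moment at
each sample (plantarflexors vs dorsiflexors, extensors vs flexors).

## The synthetic cohort

The generator emulates the statistical structure of the underlying
treadmill study: six participants (mass 79.9 +/- 13.8 kg), seven
conditions (treadmill grades -6/0/+6 degrees with level shoes, shoe
inclinations -7/-3/+3/+7 degrees on the level), 1 m/s belt speed, 2000 Hz
sampling. Signals are stride-locked periodic templates — truncated
Fourier series (8 harmonics) fitted to canonical normative shapes for
angles and moments, circular Gaussian bursts for EMG envelopes, an
analytic double-bump vertical GRF that is zero in swing, rises steeply at
contact, and is normalized so both legs' GRFs average exactly body
weight. Condition effects are multiplicative and chosen once: uphill
grade scales positive-power regions of the moments and
plantarflexor/hip-extensor EMG up; downhill scales negative-power
regions and knee-extensor/tibialis EMG up; shoe inclination perturbs the
ankle moment and tibialis/plantarflexor EMG. Trial noise is per-stride
multiplicative lognormal amplitude variation plus additive white noise
(5% default). Stride-average respiratory gas pairs are emulated from a
latent net rate (3.3 W/kg at baseline) whose grade and shoe factors are
quadratics through the study-scale condition effects, at RER 0.85 with
Brockway coefficients 16.58/4.51 J per ml.

What the generator does *not* emulate bounds what green tests mean for
real data: there are no soft-tissue or marker artifacts, no EMG
crosstalk, no left-right asymmetry, no stride-to-stride shape variation
beyond amplitude scaling, and the synthetic "calorimetry" is driven by a
latent factor rather than by the biomechanics, so cross-method
correlations on real data can be weaker in either direction.
Truth-known trials — where the trial's joint moments are *replaced* by
the muscle-generated moments under known parameters — give the
calibration a known global optimum and are the basis of the
parameter-recovery tests.

## Numerical and design choices

- Zero-phase (forward-backward) 4th-order Butterworth filters everywhere
  (EMG 20 Hz high-pass then 6 Hz low-pass on the rectified signal; GRF
  6 Hz low-pass), with odd-reflection end padding so edge transients
  decay in the pads; effective attenuation is doubled by the two passes.
- Contact detection threshold 20 N with 50 ms debouncing in both
  directions (dropouts inside stance and spikes inside swing).
- Stride grid: 1001 points (0-100% inclusive, 0.1% steps) by default;
  cohort-level runs use 501 to halve memory with no visible change.
- Outlier rule: median +/- 3 IQR with linear-interpolation quantiles; a
  degenerate zero IQR retains all values.
- The repeated-measures correlation is computed by within-subject
  centering, which is algebraically the ANCOVA with subject intercepts
  and a common slope; the tests verify equality against `lm`/`anova` on
  small tables. Slopes are reported with calorimetry on the y-axis, so a
  slope above one means the estimator understates the measured change.
- Phase comparisons use the four phase averages per participant and
  condition as the repeated observations, Bonferroni-adjusted over
  conditions at alpha = 0.05.
- Study-scale problem sizes (chosen once): five strides per trial, muscle
  simulation at 200 Hz for estimation and 100 Hz for calibration, two
  warm-up strides excluded everywhere.

## Known limitations

Absolute rate levels are not comparable to whole-body calorimetry (eight
muscles, one limb, no upper body, no resting rate): analyses are in
percent of baseline by design. Optimal fiber lengths of weakly-loaded
muscles are only weakly identifiable from moments, as discussed above.
The heat-rate and joint-space coefficient sets are package defaults, not
fitted values; conclusions that depend on their exact magnitudes (rather
than on the structural identities) should treat them as configurable.
Frontal-plane mechanics, muscle wrapping geometry, and EMG-to-excitation
delays beyond first-order dynamics are out of scope.
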