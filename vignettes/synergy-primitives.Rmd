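---
title: "Movement primitives with shared, time-shiftable synergies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement primitives with shared, time-shiftable synergies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmpsynergy)
```

## The model

A dynamic movement primitive drives each actuator with a globally stable
damped-spring system,

$$\tau \dot z = \alpha_z\big(\beta_z (g - y^*) - z\big) + f, \qquad
  \tau \dot y^* = z,$$

whose attractor is the goal $g$ and whose shape is sculpted by a learnable
forcing function $f$ of a *phase* variable — an abstraction of time.
Discrete movements use a decaying phase $\tau\dot s = -\alpha_s s$ (the
forcing switches itself off as $s \to 0$, so the trajectory always ends at
the goal); rhythmic movements use a linearly advancing, $2\pi$-periodic
angle $\tau\dot\phi = 1$.

Classically, $f$ is a normalized mixture of *fixed* basis functions with
learnable weights, and each motor task needs its own weight vector.  This
package implements the generalization in which $f$ for task $k$ is a
superposition of $M$ **shared synergies**:

$$f(s, k) = \sum_{m=1}^{M} \beta_{m,k}\,
  \Lambda(s, \theta_m, \Delta s_{m,k})\; s,$$

where each synergy $\Lambda$ is itself a sum of $N$ *parametrized*
Gaussians (amplitude $a_{m,n}$, mean $\mu_{m,n}$, bandwidth $h_{m,n}$ —
all learnable), and rhythmic movements replace the Gaussians by von Mises
kernels $a\,e^{h(\cos(\phi - \mu + \Delta s) - 1)}$ and drop the trailing
phase factor.  Only the mixing weight $\beta_{m,k}$ and the time shift
$\Delta s_{m,k}$ are task-specific; the synergy shapes $\theta_m$ encode
knowledge shared across all $K$ tasks.  With one synergy, fixed grid means
and bandwidths, $\beta = 1$ and zero shift, the classical primitive is
recovered *exactly* — `dmp_as_special_case()` constructs that mapping and
the test suite verifies the identity to $10^{-12}$.

Three coefficient-sharing schemes are supported (`task_coefficients()`):
`per_dimension` gives each actuator its own weight and shift
(Hadamard-product mixing), `time_varying` shares a single scalar weight
and shift across all actuators — the classical *time-varying muscle
synergy*, where the whole spatiotemporal pattern is scaled and slid in
time as a unit — and `dmp_special_case` pins $\beta = 1$, $\Delta s = 0$.

### A note on the shifted phase factor

For time-varying synergies the shift can be read as acting on the whole
forcing (including the trailing $s$ factor) or only inside the kernels.
The two differ by a second-order term; this package applies the shift
inside the kernel argument only, in all schemes, which makes the
`time_varying` scheme exactly the tied special case of `per_dimension`
(a property the tests exercise on random draws).

## From desired trajectories to plants

`rollout_primitive()` integrates the attractor into a desired trajectory
$\langle y^*_t, \dot y^*_t\rangle$.  Robots track it with the linear
feedback law (`feedback_control()`)

$$u_t = \mathrm{diag}(k_{pos})(y^*_t - y_t)
      + \mathrm{diag}(k_{vel})(\dot y^*_t - \dot y_t),$$

while the muscle-driven arm skips the attractor and applies the forcing
directly as muscle excitations through first-order **activation
dynamics** (`step_activation()`):

$$\dot a = (e^2 - e\,a)/\tau_{rise} + (e - a)/\tau_{fall},$$

with $\tau_{rise} = 10$ ms and $\tau_{fall} = 40$ ms.  For constant
excitation the fixed point is $a = e$; for $e = 1$ the response is
$1 - e^{-125 t}$.  Activations are clamped to $[0, 1]$, and excitations
are clipped to $[0, 1]$ *before* the ODE — synergy output can be negative
and no clipping rule is prescribed elsewhere, so this package clips in the
environment and documents it.

## The three benchmark environments

**Point-mass via-point task** (`pointmass_task()`): a 1 kg mass must pass
through one of five via-points ($\pm 0.2, \pm 0.1, 0$) and stop at the
goal $g = 1$, under motor noise $\sigma = 0.5$ with gains
$k_{pos} = 400$, $k_{vel} = 15$, horizon $T = 50$.  The cost is
$10^5(y_{t_{vp}} - vp_k)^2 + 10^4(\dot y_T^2 + 10 (y_T - g)^2) +
5\cdot 10^{-4}\sum_t u_t$.  Two deliberate choices:

* the via time $t_{vp}$ is nowhere prescribed; the default is the
  movement midpoint $T/2$;
* the control penalty is *printed* as an unsquared sum, which would reward
  negative accelerations; the default mode squares it
  (`control_penalty = "squared"`), and `"as_printed"` is available for
  fidelity.

**Planar five-link biped** (`walker_task()`): torso plus two
thigh--shank legs, actuated only at hips and knees, pinned stance foot,
hybrid dynamics with an instantaneous inelastic impact map at heel strike
and **phase resetting** ($\phi \leftarrow 0$ at every impact, so the gait
cycle synchronizes with ground contact).  The cost per task,
$-0.6(x_T - x_1) + 0.2(5 - T\Delta t) + 50\sum_i (r_i - r^*_k)^2$,
rewards distance and duration and penalizes step-height deviations from
the task's target $r^*_k \in \{0.15, 0.2, 0.25, 0.3\}$ m.  The continuous
dynamics use the absolute-link-angle formulation of a pinned planar tree
($M_{jk} = A_{jk}\cos(\theta_j - \theta_k) + \delta_{jk}I_j$, Coriolis
$\sum_k A_{jk}\sin(\theta_j-\theta_k)\dot\theta_k^2$), integrated with
fixed-step RK4 at $\Delta t = 2$ ms; torque-free energy drift is below
$10^{-8}$ relative over 0.5 s.  The impact map solves five angular-momentum
conservation relations (whole robot about the new contact point, each
distal sub-chain about its connecting joint) and never increases kinetic
energy.  Masses, lengths, limits, gains and the initial state are
*synthetic fixtures* in the style of standard five-link walker models
(shank 3.2 kg / 0.4 m, thigh 6.8 kg / 0.4 m, torso 12 kg / 0.625 m,
mid-link centres of mass, rod inertias); no reference values for them are
available, so no quantitative walking result here is comparable to
published numbers.  Motor noise ($\sigma = 1$) is added to the commanded
torques after gain multiplication.  Ground contact is declared when the
swing foot crosses height zero moving downward at a horizontal separation
of at least 5 cm from the stance foot (the separation guard suppresses
scuff retriggering immediately after an impact).

**Muscle-actuated planar arm** (`arm_task()`): an explicit stand-in for a
physiological arm — two links (shoulder, elbow), six lumped muscles
(mono-articular antagonist pairs at each joint plus a bi-articular pair)
with constant moment arms and force $= a \cdot F_{max}$, open loop,
$T = 500$ steps at $\Delta t = 1$ ms, six targets 15 cm from the initial
marker (wrist) position at equally spaced directions.  Gravity is
compensated by default so zero excitation keeps the arm at rest.  The
cost is $\sum_k\big[3\,\frac1T\sum_t \|g_k - v_k(t)\| +
10^{-3}\int_0^1 f^\top f\, ds\big]$, the excitation integral taken by the
trapezoidal rule on the recorded phase grid.  Tendon dynamics, muscle
wrapping and physiological muscle sets are intentionally out of scope;
published costs for the physiological plant are not comparable.

## Policy search

All task-specific parameters ($\beta$, optionally $\Delta s$) and all
shared shape parameters ($a, \mu, h$ per kernel per dimension per
synergy) are flattened into one policy vector (`parameter_layout()`,
`pack_policy()`/`unpack_policy()`).  The accounting is

* task-specific: $K M (1 + \Delta)$ scalars (`time_varying`) or
  $K M D (1 + \Delta)$ (`per_dimension`), with $\Delta \in \{0,1\}$
  indicating learned shifts;
* shared: $3 N D M$.

For the benchmark configurations this yields 11 free parameters for the
via-point set ($5 + 2 \times 3$) and totals $45, 90, 135, 180, 225$ for
the reaching set with $M = 1..5$ — the values `scripts/acceptance.R`
recomputes.

`synergy_learn()` minimizes the summed episode cost
$J(\theta) = \sum_k C(\tau, k)$ with a hand-implemented standard
$(\mu/\mu_w, \lambda)$ CMA-ES (`cma_es()`): rank-based selection,
rank-one and rank-$\mu$ covariance updates, cumulative step-size
adaptation, default population $4 + \lfloor 3\ln n\rfloor$, box bounds by
projection with a quadratic penalty, restart from the incumbent on a
degenerate covariance.  No CMA implementation ships with the supported R
stack, hence the in-package implementation; it is validated against a
quadratic oracle (sphere to $10^{-8}$ in 5000 evaluations at $n = 10$).

Numerical choices worth knowing:

* **Initial policy**: all $\beta = 0$ (the unforced, stable attractor),
  unit amplitudes, kernel means spread evenly over the phase range,
  bandwidths at the 50%-overlap value.  Zero weights mean the search
  starts from the known-safe trajectory.
* **Bandwidths** are log-parametrized in the flat vector, so any real
  coordinate maps to a positive bandwidth; means are box-bounded to the
  phase range.
* **Failed rollouts** (a fallen walker simply ends its episode and is
  costed as recorded; genuine numerical failure) contribute a large
  finite penalty ($10^6$), never an exception mid-search.
* **One rollout per evaluation** by default, matching per-sample
  learning-curve accounting; `rollouts_per_eval` trades evaluations for
  variance reduction.
* **Identifiability**: $\beta_{m,k} \cdot a_{m,n}$ has a scale ambiguity.
  Learning imposes no constraint (none is prescribed); recovery *tests*
  normalize each synergy's amplitudes to unit maximum and absorb the
  scale into $\beta$.

`generalize_fixed_synergies()` freezes the learned shapes and optimizes
only the task-specific block for a new task set — e.g. 48 free parameters
for the reaching configuration with $M = 4$, against 180 when learning
from scratch.

## Integrator accuracy

Plants and the attractor are stepped explicitly at the environment step.
For the linear attractor, explicit Euler has a global error of order
$|\lambda|\,\Delta t/(2e)$ relative to the transient amplitude, which for
any system converging within 1 s exceeds $10^{-3}$ at $\Delta t = 1$ ms;
`rollout_primitive(method = "rk4")` is provided where closed-form-level
accuracy matters, and the Euler path is verified by its first-order
convergence to the matrix-exponential solution.  The same analysis
applies to the activation ODE: at $\Delta t = 10\,\mu s$ the Euler
trajectory deviates from $1 - e^{-125t}$ by at most $2.3\times 10^{-4}$
(at $t = 8$ ms), first-order in $\Delta t$.

## What the synthetic patterns do and do not establish

`generate_patterns()` evaluates the forcing of known ground-truth
synergies on a phase grid per task and muscle, adds i.i.d. Gaussian noise
and optionally clips to $[0,1]$.  This emulates the *statistical
structure* the representation assumes — low-rank spatiotemporal patterns
built from scaled, shifted shared components — but not the features of
real electromyography (rectification artefacts, multiplicative noise,
crosstalk, nonstationarity).  `recover_coefficients()` solves the inverse
problem: with shifts fixed the weights are linear, recovered by QR least
squares (exact at zero noise, rank deficiency reported rather than
regularized); with free shifts a grid search over per-task shift
combinations with inner least squares.  A green recovery test therefore
establishes the *representation and its inverse are mutually consistent*,
not that real muscle recordings decompose this way.

## Known limitations

* The walker's physical parameters are package fixtures; gait quality and
  learned costs are not comparable to any published table.
* The arm is a six-muscle caricature; only the cost *functional* and the
  pipeline (excitation, activation dynamics, moment arms, forward
  dynamics, marker cost) mirror the muscle-driven setting.
* Impact detection uses a horizontal-separation guard instead of event
  root-finding; at $\Delta t = 2$ ms the impact is applied at the end of
  the crossing step.
* The walker's generalization experiment (new step height with frozen
  synergies) is supported by the API (`generalize_fixed_synergies()`)
  but its outcome depends on the fixture parameters, so it is exercised
  as a smoke path, not as a quantitative benchmark.
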