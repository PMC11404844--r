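---
title: "Simulating ideal motor- and spring-based assistance during walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ideal motor- and spring-based assistance during walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During walking, each lower-limb joint moment measured by inverse dynamics
can be produced by many different combinations of muscle forces: there are
more muscles than equations of motion. `exoassist` resolves this muscle
redundancy by trajectory optimization and uses the same machinery to ask a
design question: if an ideal assistive device adds torque at one joint,
what torque profile minimizes the muscular effort, and what does that do to
muscle activations, net muscle moments and metabolic rates?

Two actuation modes are modeled. A *motor-based* device delivers an
arbitrary unidirectional torque trajectory at the assisted degree of
freedom. A *spring-based* device is a torsional spring that engages at time
$t_c$ and disengages at $t_d$, with torque proportional to the angular
displacement from the engagement angle; its three design variables
(stiffness $k_r$, $t_c$, $t_d$) are optimized under the constraint that the
engagement and disengagement angles match, $(q(t_c)-q(t_d))^2 < 0.01$, so
the spring operates on a closed angle path and does zero net work up to
smoothing leakage.

## The redundancy problem

For one gait cycle $[t_i, t_f]$ with prescribed joint angles $q(t)$, net
joint moments $\tau_{ID,j}(t)$, muscle-tendon lengths and moment arms, the
solver minimizes

$$ J = w_a \int \sum_n a_n^2 \, dt \; + \; w_r \int \sum_j e_{R,j}^2 \, dt
   \; + \; w_v \int \sum_n \tilde v_n^2 \, dt $$

subject to the moment balance at every joint,
$\tau_{ID,j} = \tau_{MUS,j} + e_{R,j} T_R + \tau_{EXO,j}$, and to Hill-type
muscle dynamics. The defaults $w_a = 1$, $w_r = 1000$, $w_v = 0.001$,
$T_R = 100\,$N·m follow the study conditions this package reproduces: the
reserve actuators $e_R$ exist to guarantee feasibility and are heavily
penalized; the fiber-velocity term is a small regularizer.

Muscle mechanics follow the implicit formulation of De Groote et al.
(2016): normalized fiber length is a state, its scaled time derivative
$\tilde v$ is a control, and the force balance between the pennated fiber
(active + passive + a small damping term) and the elastic tendon is imposed
as an algebraic path constraint. Activation dynamics are first-order with
activation/deactivation time constants of 15/60 ms and a smooth tanh switch
between the branches; activations and excitations live in
$[a_{min}, 1]$ with $a_{min} = 0.01$ to keep the equilibrium
well-conditioned.

### Transcription and solver

The cycle is discretized on a uniform periodic mesh of $N$ intervals
(default 100). The scheme is implicit midpoint: states (activation,
normalized fiber length) live on mesh nodes, controls (excitation, fiber
velocity, motor torque) on interval midpoints, and all path constraints,
the moment balance and the objective quadrature are evaluated at the
midpoints. Identifying node $N{+}1$ with node 1 builds state periodicity
into the transcription, which is the natural closure for a gait cycle. The
midpoint scheme is second order, so the objective is stable under mesh
refinement (halving the mesh changes $J$ by well under one percent on the
synthetic fixtures when the solver is run to tight tolerances).

The reserves are eliminated analytically through the moment balance, which
therefore holds exactly at every collocation point; what remains is a
bound-constrained problem with the Hill and activation-dynamics residuals
as equality constraints. It is solved by an augmented-Lagrangian method:
the bound-constrained inner problems go to L-BFGS-B (driven natively in
compiled code with analytic gradients; the gradient implementation is
cross-checked against an independent R reference and against finite
differences in the test suite), multipliers are updated between inner
solves, and the penalty parameter escalates when feasibility stagnates, up
to a cap beyond which conditioning would degrade. Two numerical choices
matter enough to document:

* **Variable scaling.** Gradients with respect to normalized fiber length
  are roughly two orders of magnitude stiffer than those with respect to
  activation (the tendon force-length slope amplifies length changes), and
  motor torques live on a ~100 N·m scale. The inner solver works in a
  scaled space (fiber lengths x60, torques /25) that equalizes these.
* **Reserve-weight continuation.** The problem is non-convex: descent from
  a cold start tends to land in a basin that leans on the reserve
  actuators near rapid force decays (push-off), where deactivation-rate
  limits make muscle force hard to shed. A first pass with the reserve
  term boosted tenfold pulls the iterate into the low-reserve basin; the
  final pass optimizes the true objective. The reported solution is always
  evaluated at the study weights.

The deterministic initial guess is a per-frame rigid-tendon static
optimization (a small box-constrained quadratic program per frame), with
fiber lengths from the quasi-static Hill equilibrium. This replaces a flat
constant-activation start: it is equally reproducible and starts the
solver near the feasible manifold.

### Device handling

The motor torque trajectory enters the collocation problem as a free
per-interval variable, box-constrained to the assisting direction. For the
spring, the torque for fixed $(k_r, t_c, t_d)$ depends only on the
prescribed kinematics, so the inner problem is a fixed-assistance solve and
the design variables are searched in an outer loop. The closure constraint
pins $t_d$ to crossings of $q(t) = q(t_c)$, so candidate engagement windows
are enumerated from those crossings, the stiffness is fitted per window
against a fast rigid-tendon surrogate, the best windows are compared with
full solves, and a zero-stiffness fallback against the unassisted solution
guarantees the spring never reports a worse objective than no assistance.
The tanh window sharpness $b = 1000\,s^{-1}$ makes the torque onset much
steeper than the mesh spacing, which is why the engagement times are
searched rather than differentiated through. The spring is unidirectional:
torque that would act against the assisted muscle group is clipped to zero,
modeling an element that disengages rather than pushes back; whether the
original devices could push back inside the window is left open in the
source material, and the clipped model is this package's choice.

## Metabolic model

Per-muscle metabolic rate is contractile-element work rate plus heat rate,
$\dot E = \dot W_{CE} + \dot H$, with $\dot W_{CE} = F_{CE} V_{CE}$ in the
shortening-positive convention. The heat rate follows the Bhargava-family
decomposition: activation and maintenance heats scale with muscle mass
(derived as $m = F_{max}/\sigma \cdot \rho \cdot \ell_{opt}$ with
$\sigma = 0.25$ MPa, $\rho = 1059.7$ kg/m³) and with slow/fast fiber
recruitment curves $\sin(\tfrac{\pi}{2}e)$ and $1-\cos(\tfrac{\pi}{2}e)$;
the shortening/lengthening heat coefficient is $0.16 F_{iso} + 0.18 F_{CE}$
concentrically and $0.157 F_{CE}$ eccentrically. The maintenance heat's
fiber-length dependence uses the smooth active force-length multiplier in
place of the piecewise curve of the original formulation. The basal term is
off by default because the package compares muscle-action rates between
conditions.

Eccentric contraction can drive $\dot W_{CE} + \dot H$ negative. The
published adjustment formulas, substituted literally, yield
$\dot E = -\dot H$, which stays negative whenever $\dot H > 0$ and so
cannot achieve the stated goal of non-negative rates. This package
implements the evident intent: where the raw rate is negative the heat
correction exactly cancels the deficit, clamping $\dot E$ at zero. The
literal substitution is retained behind `literal_eq12 = TRUE` for audit.

## The synthetic study conditions

No motion-capture data ship with the package. The synthetic generator
emulates the structure of the upstream pipeline's outputs: smooth periodic
joint kinematics built from three harmonics per joint with gait-like
phasing (stance dorsiflexion peak before preswing plantarflexion,
swing-phase knee flexion, sinusoid-like hip flexion-extension, stance-phase
hip adduction), constant moment arms (so muscle-tendon lengths close
exactly against the angles), a nine-muscle lower-limb set spanning ankle,
knee, sagittal hip and frontal hip with at least one agonist and one
antagonist per joint, and walking-speed scales of 0.55, 1.0 and 1.45 of
preferred speed with cycle duration $T = 1.1 \cdot s^{-0.35}$ s and mild
amplitude scaling. Per-seed jitter perturbs harmonic amplitudes (4%) and
phases so seeds differ; all randomness flows through one seeded generator.

Ground truths are constructed to be *recoverable*: net joint moments are
built from known activations rather than the other way round. The
construction runs in two stages. First, gait-like target moment profiles
(plantarflexion bump at push-off, knee-extension bump in loading response,
hip extension-then-flexion, double-bump hip abduction; amplitudes around
1 N·m/kg scaled by speed) are converted to activations by per-frame static
optimization, smoothed to a few harmonics, filtered through the activation
dynamics so they are reachable under bounded excitations, and integrated
through the fiber dynamics (trapezoidal stepping of the stiff contraction
equation, muscles decoupled) to yield exactly consistent net moments.
Second, because that rigid-tendon-derived pattern is feasible but not
optimal for the elastic-tendon dynamic problem, the provisional trial is
re-solved with the full collocation method and the solution is adopted as
the ground truth, with the stored net moments rebuilt from its own muscle
moments. The stored trial grid is twice as fine as the default mesh and
carries the solution's exact node and midpoint values, so a default-mesh
solve reads its collocation data without interpolation error and the truth
is an exactly feasible zero-reserve point of the stored problem. What
recovery experiments on these fixtures demonstrate is therefore estimator
consistency - determinism, constraint handling, and insensitivity to
re-solving from the default initial guess - not robustness to measurement
noise, soft-tissue artifact or model mismatch, none of which the generator
emulates.

One caveat the tests make explicit: under the study weights, the optimal
solution at fast walking genuinely allocates a fraction of a newton-meter
to the reserve actuators during push-off, where deactivation-rate limits
bind; a zero-reserve feasible point exists but has a slightly higher
objective. Reserve use at the optimum is therefore not identically zero,
and its share of the objective grows with walking speed.

## Parameter tuning

The two-step tuning procedure is a bounded least-squares surrogate for the
original workflow, which is described only by its goals. Step one adjusts
optimal fiber length, tendon slack length and tendon stiffness per muscle
(within +-30% of nominal) so quasi-static fiber-length trajectories -
the Hill equilibrium at a fixed reference activation of 0.05 - match
target trajectories and excursions. Whether the original used dynamic or
quasi-static fiber simulation is not stated; quasi-static is this
package's documented choice, giving a deterministic separable problem.
Step two adjusts the passive-curve scale (and optionally shift) so summed
rigid-tendon muscle passive moments match joint passive moment-angle
targets; the rigid-tendon passive model is linear in the scales, which
makes scale recovery exact and the fit well-posed. Target tables are
user-supplied delimited files; the repository ships only synthetic
fixtures.

## Worked example

```{r example}
library(exoassist)

spec <- synthetic_model_spec(speed_scale = 1.0)   # normal walking speed
trial <- synthetic_trial(spec, seed = 0)

un <- solve_unassisted(trial, spec$muscles)
motor <- solve_assisted(trial, spec$muscles,
                        device = device_for("ankle_pf", "motor"),
                        unassisted = un)
spring <- solve_assisted(trial, spec$muscles,
                         device = device_for("ankle_pf", "spring"),
                         unassisted = un)

met_un <- compute_metabolics(un, spec$muscles)
met_m <- compute_metabolics(motor$solution, spec$muscles)
percent_change(met_un$avg_e_leg_w, met_m$avg_e_leg_w)
```

The full three-speed experiment with all four assisted joints and both
actuation modes, including the comparison tables, is one call:

```{r experiment}
res <- run_experiment("results", seed = 0,
                      options = local({
                        o <- solver_options(mesh = 50)
                        o$spring_search <- "screen"
                        o
                      }))
res$normal$report
```

## Problem sizes and limitations

The default mesh is 100 intervals per cycle; the batch experiment and the
nesting regression run at 50 intervals with the screening spring search,
which keeps a full 3-speed x 4-joint x 2-mode experiment in the
ten-minute range on one core. Known limitations: kinematics are always
prescribed (no predictive adaptation of gait to the device); devices are
massless and frictionless; a single joint is assisted at a time; the
synthetic trials make no claim of subject fidelity, so headline percentage
changes computed on them characterize the pipeline, not human walking; and
the assistive optimum is defined by minimal summed squared activations,
which - as the assisted-condition reports themselves show - does not
always translate into proportional metabolic savings.
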