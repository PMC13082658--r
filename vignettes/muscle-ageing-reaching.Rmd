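---
title: "A two-muscle elbow model of ballistic reaching and muscle ageing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-muscle elbow model of ballistic reaching and muscle ageing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachopt)
```

`reachopt` simulates rapid point-to-point elbow movements driven by an
antagonistic pair of identical Hill-type muscles, finds the excitation
schedules that a perfect controller would choose, and asks how the optimal
behaviour degrades as muscle parameters shift the way they do with ageing.
This vignette is the package's account of the model, the numerical choices
behind it, and what its tests do and do not establish.

## The model

A frictionless elbow in a horizontal plane (no gravity) carries a lumped
forearm-plus-hand inertia $I = 6.88\times10^{-2}\,$kg m$^2$. A flexor and an
extensor act through a constant moment arm $r = 0.04\,$m; at the resting
angle $\theta_0 = 90^\circ$ both muscles sit at their resting length
$l_0 = 0.32\,$m, and

$$l_\mathrm{flex} = l_0 - r(\theta - \theta_0), \qquad
  l_\mathrm{ext} = l_0 + r(\theta - \theta_0),$$

so $l_\mathrm{flex} + l_\mathrm{ext} = 2 l_0$ identically. The equation of
motion is $I\ddot\theta = r(F_\mathrm{flex} - F_\mathrm{ext})$.

Each muscle produces tension

$$F = F_\mathrm{max}\,\bigl(a\, f_L(\hat l)\, f_V(\hat v) + f_P(\hat l)\bigr),$$

with activation $a \in [0,1]$, normalised length $\hat l = l/l_0$ and
normalised strain rate $\hat v$ (per $v_\mathrm{max}$, positive =
lengthening). The curve shapes are:

* **Active force–length** $f_L(\hat l) = \exp\!\bigl(-((\hat l^{\,b_2} -
  1)/b_3)^{b_1}\bigr)$ with $b = (2, -1.3, 0.53)$. The even exponent
  $b_1 = 2$ makes the curve — and its Hessian — smooth everywhere, which the
  trajectory optimiser relies on.
* **Parallel passive** $f_P(\hat l) = c_1\bigl(e^{c_2\,\mathrm{sp}(\hat l -
  c_3)} - 1\bigr)$ with $c_2 = 5$, slack length $c_3 = 1$, and
  $\mathrm{sp}(x)$ a softplus of gain $s = 500$ replacing $\max(x, 0)$: the
  element is tension-only, engages beyond slack, and scales linearly in the
  stiffness parameter $c_1$.
* **Force–velocity**: the classic concentric hyperbola $(1 + \hat v)/(1 -
  d_1 \hat v)$ (zero force at $\hat v = -1$, curvature $d_1 = 4$) blended
  through a tanh switch of gain $s$ into an eccentric branch $d_2 - (d_2 -
  1)/(1 + d_3 \hat v)$ that saturates at the plateau $d_2$ ($d_3 = 30.24$).
  Both branch arguments are softplus/softmin-guarded so neither hyperbola
  can pole, and the blend is divided by its value at $\hat v = 0$ so the
  isometric point is exactly 1.

The exact smoothing construction around former cusps is a modelling choice
of this package (only the gain $s = 500$ is fixed); all curve definitions
sit behind `muscle_params()` so alternates can be swapped in one place.

**Eccentric plateau scaling.** Eccentric strength is comparatively spared
by ageing, so when $F_\mathrm{max}$ is swept the plateau is rescaled as
$d_{2,\mathrm{eff}} = 1.4 \times 1300 / F_\mathrm{max}$, keeping the
absolute eccentric force ceiling at its baseline value. A literal
$1300/F_\mathrm{max}$ variant and a no-scaling variant are config switches
(`d2_scaling`).

**Excitation to activation.** Activation follows the neural excitation
$u \in [0,1]$ through a first-order law with separate activation and
deactivation time constants ($\alpha_a = 94.5\,$ms, $\alpha_d = 65\,$ms at
baseline),

$$\dot a = \frac{u - a}{\tau(a, u)},\qquad
  \tau = \begin{cases}\alpha_a\,(0.5 + 1.5a) & u > a\\
  \alpha_d/(0.5 + 1.5a) & u \le a,\end{cases}$$

with the regime switch blended by the same tanh gain $s$. The
activation-dependent factors follow the Thelen-style formulation this
component is modelled on. A constant-time-constant variant
(`activation_scaling = "constant"`) is retained: it leaves the corner
performance almost unchanged but roughly doubles the deactivation time
scale near rest, which moves the stiffness-neutral boundary (below) from
$\sim$45 ms to $\sim$88 ms and weakens the deactivation–stiffness
interaction. The activation-dependent default reproduces the reference
behaviour of this model family and is used throughout.

## The optimal-control problem

The task: start at rest at $135^\circ$ flexion, reach and hold $45^\circ$
within $T = 0.4\,$s. With target muscle lengths $l^\ast$, the objective is
the summed squared length error over the $N = 80$ nodes ($\Delta t =
5\,$ms)

$$J = \sum_{i=1}^{N}\bigl[(l_{\mathrm{ag},i} - l^\ast_\mathrm{ag})^2 +
     (l_{\mathrm{ant},i} - l^\ast_\mathrm{ant})^2\bigr] + J_\mathrm{end},
  \qquad J_\mathrm{end} = w\,e_N,\; w = 0.01,$$

the terminal position being penalised, not constrained. The fixed initial
node contributes only a constant and is excluded by default
(`include_node0` restores it). Controls are piecewise-constant bilateral
excitations in $[0,1]$. Terminal rest is the one hard terminal constraint,
$\omega(T) = 0$.

An optional augmented objective adds
$W_\mathrm{exc}\sum u_i^2 + W_\mathrm{work}\,\Delta t \sum
\mathrm{smab}(\dot l F \,|\, s_w)$ with
$\mathrm{smab}(x|s) = x\tanh(sx)$, $W_\mathrm{exc} = 10^{-5}$ m,
$W_\mathrm{work} = 10^{-4}$ m/J, $s_w = 100$ — a crude effort model that
smooths the otherwise bang-bang excitations.

**Initial conditions.** The arm starts at rest. In the flexed start
posture the (stretched) agonist's passive element pulls toward the target,
so stasis requires the antagonist to balance it: initial activations are
set to the minimal static-equilibrium point — agonist drive zero,
antagonist activation from a root-find on the net torque
(`make_equilibrium_case()`). With $c_1 = 0$ both start at zero. Any extra
initial coactivation along the equilibrium manifold only adds resistive
force during acceleration, so the minimal point is the one an optimal
solution uses.

**Transcription and solver.** The problem is solved by direct shooting:
the 160 excitation values are the decision variables, states follow from
classical RK4 integration of the dynamics (so the dynamics hold *exactly*
at every node and a replay through `forward_simulate()` reproduces the
solution), and the gradient of the objective is computed by a discrete
adjoint sweep over the RK4 stages. Stage Jacobians come from complex-step
differentiation of the templated C++ dynamics — accurate to machine
precision with no subtractive cancellation, at roughly the cost of a dozen
dynamics evaluations per stage. The box-constrained problem is optimised
with L-BFGS-B (`factr = 10`, `pgtol = 1e-9`, memory 20), and the terminal
rest equality is enforced by an augmented-Lagrangian outer loop
(multiplier update until $|\omega(T)| \le 10^{-6}$ rad/s, typically 2–4
rounds). Everything is deterministic: identical inputs give bit-identical
objectives on a fixed platform, warm-started re-solves are stationary to
$10^{-8}$, and flexion tasks are mapped through the model's exact mirror
symmetry onto a canonical extension frame so mirrored tasks return exactly
mirrored solutions.

The cold start follows the study protocol: muscle lengths interpolated
linearly from start to target and all other states and controls zero — for
shooting, the zero-control part of that guess is what enters. Fine-grid
sweeps over the deactivation–stiffness plane are warm-started from the
baseline solution.

## Performance metrics

* `rmse_metric()`: $J_\mathrm{RMSE} = \sqrt{J_\mathrm{SSE}/N}\,/\,(2
  l_0)$, the error of one muscle in resting lengths. The alternate
  reading $\sqrt{J_\mathrm{SSE}/(2N)}/l_0$ (halving inside the root) is a
  config switch; the default was frozen by checking the two candidates
  against the published corner-case values, which only the default
  reproduces.
* `coactivation()`: $a_c(t) = \min(a_\mathrm{ant}, a_\mathrm{ag})$ and its
  trapezoid time average.
* `time_to_target()` / `time_to_stable()`: first entry into, and last
  entry without subsequent exit from, a tolerance band around the target,
  linearly interpolated between nodes. The band is 1% of the excursion
  (0.9° for the 90° task) — the supplement that defines these metrics does
  not print a tolerance; 1% makes the slowest corner case "reach the
  target" just inside the horizon, consistent with the published
  worst-case time. Exposed as `tol_frac`.
* `ballistic_fraction()`: the share of the squared-error sum accrued at
  nodes up to $T_T$ — a ratio of error sums rather than of RMS values,
  chosen for additivity between the two phases.

## Parameter sweeps and the importance analysis

`build_full_factorial()` crosses the multiplier grids
($F_\mathrm{max}\times v_\mathrm{max} \times \alpha_a \times \alpha_d
\times c_1 = 4\times4\times7\times7\times5 = 3920$ combinations);
`run_sweep()` solves each (cold starts, deterministic order, failures
flagged and retried once from the baseline warm start, never dropped).
`build_finer_grid()` spans the $\alpha_d \times c_1$ plane at 0.6 ms /
0.005-unit increments by default; its composition is explicit
configuration because the published trial count for this grid cannot be
reconciled with the printed increments, so nothing is hard-coded.

`fit_importance()` min-range-normalises the five parameters and the
response, forms the ten pairwise interaction products of the normalised
main effects (on a full factorial containing the range endpoints these
products already span $[0,1]$; re-normalising them is a sensitivity
switch), and fits OLS. Coefficient magnitudes are the "importance" of each
term; the reduced variants keep the first-order-important terms with and
without the $\alpha_d{:}c_1$ interaction. `coactivation_regression()`
regresses max-normalised $J_\mathrm{RMSE}$ on mean coactivation.
`find_neutral_deactivation()` bisects the sign of the stiffness effect
$J_\mathrm{RMSE}(c_1{=}0.05) - J_\mathrm{RMSE}(c_1{=}0.04)$ to 0.5 ms.

## What the generator emulates, and what the tests show

`scenario_generator`-style fixtures (`make_corner_params()`,
`make_excitation()`, `make_equilibrium_case()`,
`make_regression_table()`) make every stage testable without external
data: excitation archetypes drive the forward-simulation oracle,
equilibrium cases pin the initial-condition policy, and planted-structure
tables give the regression a known ground truth. All are deterministic
given a seed. They emulate the *structure* of study inputs, not empirical
signals: no EMG, no noise, no feedback delays, no tendon dynamics. Tests
passing on these fixtures therefore validate the computational pipeline
and the model's internal mechanics — they do not validate the model
against human data.

## Problem sizes used by the test suite

The long-running full-factorial statistics are exercised in the test suite
on a proportionally thinned sub-factorial — three levels spanning each
range for $F_\mathrm{max}$, $v_\mathrm{max}$, $\alpha_a$ and $\alpha_d$,
the stiffness endpoints for $c_1$ ($3\times3\times3\times3\times2 = 162$
solves) — and the deactivation–stiffness plane on a $5\times5$ grid. The
regression coefficient pattern and the model $R^2$ values are robust to
this thinning (interior levels must be present: an endpoints-only design
hides the lack of fit and inflates $R^2$). The statistics that summarise
the response *distribution* — the coactivation–performance correlation,
the maximum mean coactivation, the ballistic-fraction tail — are both
design-dependent and sensitive to the absolute coactivation magnitudes
produced by the adopted curve closed forms, so they are weaker checks of
this implementation than the normalised importance pattern. The full
3920-trial design runs with `run_sweep()` on `build_full_factorial()` in
a few CPU-hours.

## Numerical choices and degenerate inputs

Smoothing leaves tiny, documented residues: the passive curve leaks
$\sim 7\times10^{-3} c_1$ at exactly slack length, and isometric
`muscle_force(1, 1, 0)` is $F_\mathrm{max}$ to $3.5\times10^{-4}$
relative. Curves reject non-positive lengths; activations outside $[0,1]$
are domain errors; a constant vector cannot be min-range-normalised; a
rank-deficient importance design and a zero-variance coactivation
regression are errors, not silent fits. The equilibrium root-find reports
infeasibility when the required antagonist activation would exceed 1.
Bisection refuses brackets without a sign change.

## Known limitations

One degree of freedom, identical muscles, constant moment arm, no tendon,
no electromechanical delay, no history-dependent force, no noise or
feedback: mechanistic conclusions transfer to biology only qualitatively.
The published corner values are reproduced to a few percent but depend on
curve closed forms that are this package's own (documented) choices; the
`muscle_params()` seam is the supported place to swap alternatives.
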