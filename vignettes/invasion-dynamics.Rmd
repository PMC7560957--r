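---
title: "Resident–invader dynamics in fluctuating environments with fluctinvade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resident–invader dynamics in fluctuating environments with fluctinvade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctinvade)
```

## The model class

`fluctinvade` works with continuous-time models of populations indexed by a
heritable strategy $x \in \mathbb{R}^d$, living in an explicitly modelled
environment with stochastic forcing:

$$\dot n_i = f(x_i, e_t, \theta_t)\, n_i, \qquad i = 1, \dots, k,$$
$$\dot e_{1,t} = G_1(e_t, \theta_t) + \sum_j H_1(x_j, e_t, \theta_t)\, n_{j,t},
\qquad e_{2,t} = G_2(e_t, \theta_t) + \sum_j H_2(x_j, e_t, \theta_t)\, n_{j,t},$$
$$\dot\theta_t = A(\theta_t) + B(\theta_t)\, \dot W_t.$$

The per-capita growth rate $f$ is linear in the population sizes; all
nonlinearity enters through the feedback environment $e = (e_1, e_2)$, whose
first component is driven by an ODE and whose second component is defined
implicitly by the current state (resource levels, foraging totals, population
aggregates and the like). The driver $\theta$ is a Markov process — here a
diffusion, typically Ornstein–Uhlenbeck — that forces the environment but is
not affected by the populations; this is what separates environmental
*stochasticity* from environmental *feedback*. Structured populations replace
the scalar rate $f$ by an $\ell \times \ell$ matrix of transition rates and
are handled in the total-size/class-distribution decomposition, in which the
class distribution lives on the probability simplex.

Models are plain R closures collected by `unstructured_model()` /
`structured_model()`; `validate_model()` probes shapes and second-order
smoothness (which the local expansion below requires) on a declared state
box. Function-valued environments (as in competition models, where every
possible mutant experiences its own interaction sum) are represented
finite-dimensionally by carrying the pairwise interaction inside $f$; the
Lotka–Volterra fixture shows the pattern.

## Simulation

`simulate_polymorphic()`, `simulate_structured()` and `simulate_dimorphic()`
use a fixed-step Euler–Maruyama scheme in the Itô interpretation. The choices
that matter:

* **Fixed step, pre-generated noise.** All Wiener increments derive from the
  seed up front, so identical configurations are bitwise reproducible and
  different formulations of the same dynamics (two explicit populations
  vs. the $(N, P)$ total-size/relative-frequency coordinates) consume the
  *same* path and can be compared pathwise. The test suite exploits this for
  the change-of-variables equivalence checks.
* **Absorbing zero.** Populations are clipped at zero and clip events
  counted; the extinction set is invariant in the exact dynamics, so this is
  the faithful discrete analogue.
* **Implicit environment.** When $G_2, H_2$ do not depend on $e_2$ (all
  bundled fixtures) the implicit equation is evaluated in one pass; otherwise
  a damped fixed-point iteration with a Newton fallback is used, warm-started
  from the previous step.
* **Deterministic skeletons** (zero-diffusion driver) are integrated with
  `deSolve::lsoda` for attractor work, where adaptive error control matters
  more than path reproducibility.

The default step `dt = 1e-3` (fixture time units) is conservative; the tests
use `1e-2`–`2e-3` depending on the stiffness of the fixture, sizes chosen so
the whole suite runs in a few minutes while keeping the Euler bias well under
the Monte-Carlo standard errors being asserted against.

## Residents and invasion fitness

A *resident* is a population that is non-growing on the long run (its
per-capita growth rate has zero time average) and stochastically persistent
(it spends an arbitrarily small fraction of time near extinction).
`resident_diagnostics()` makes both conditions operational: the growth rate
is a Birkhoff time average with a batch-means standard error (we never
represent the invariant measure itself; burn-in defaults to 20%), and
persistence is checked as occupancy of an $\eta$-neighborhood of the
extinction set, with defaults $\eta^* = 10^{-3}\times$ the median population
and $\varepsilon^* = 0.01$. Only the measure reachable from the supplied
initial condition is diagnosed.

The invasion fitness $S_x(y)$ of a rare mutant $y$ is the long-run average of
$f(y, e_t, \theta_t)$ over the environment generated by the resident.
`invasion_fitness()` always averages the mutant's growth rate along the
resident attractor rather than simulating the mutant's exponentially
growing or shrinking size — the two are equivalent, but only the former is
numerically safe. Four methods share this interface: `ergodic` (time average
along a stochastic trajectory, with SE), `periodic` (average over one
detected period of a deterministic limit cycle), `equilibrium`, and
`closed_form` (fixture overrides). Selective neutrality, $S_x(x) = 0$, holds
by construction and is asserted across all fixtures and methods in the
tests — it is the single best end-to-end diagnostic of the machinery.

For limit cycles, `periodic_attractor()` finds the cycle with an
event-located Poincaré section (upward crossings of the first population
coordinate through its post-transient mean) and `invasion_fitness()`
integrates the mutant growth over exactly one period. Near a Hopf point,
damped oscillations can masquerade as cycles for a long time; the attractor
search therefore monitors the amplitude across its observation window and
falls back to classifying the equilibrium's Jacobian when the amplitude is
still shrinking. `find_hopf()` locates the bifurcation itself by bisection
on the leading eigenvalue of the interior equilibrium, tracked by
warm-started Newton solves from the stable end of the bracket.

## The local expansion and outcome classification

For two similar strategies $x_i = x + \epsilon \xi_i$ the dynamics of the
invader's relative frequency $P$ is slow compared to everything else, and its
averaged dynamics is determined by local properties of the two-argument
fitness surface $s(x', y') = S_{x'}(y')$ at $(x, x)$:

* the selection gradient $g = \partial_y S_x(y)|_{y=x}$, and
* the curvature matrices $C_{11} = \tfrac12\partial_{xx}s$,
  $C_{22} = \tfrac12\partial_{yy}s$, $C_{21} = \tfrac12\partial_{yx}s$,
  $C_{12} = C_{21}^\top$, which satisfy the conservation law
  $C_{11} + C_{22} + C_{12} + C_{21} = 0$ (a consequence of neutrality).

`second_order_coefficients()` estimates these by mixed central differences
with step $h = 10^{-3}(1 + \lVert x\rVert)$ by default. Second derivatives of
noisy functions are fragile, so with the ergodic method every stencil
evaluation reuses a frozen resident trajectory per distinct resident
(common random numbers); the tests show this cuts the gradient-estimate
variance by far more than the required order of magnitude. $C_{12}$ is set to
$C_{21}^\top$ rather than re-estimated, and the conservation defect is
reported as a built-in accuracy check.

`expand_fitness_second_order()` assembles the pairwise fitness predictions.
One genuinely open design point: with vector strategies the mixed term of the
second-order expansion can be written with either mixed-derivative matrix,
and the two differ when that matrix is non-symmetric (the chemostat's is).
We use the exact Taylor form
$S_{x_1}(x_2) = \epsilon\,g^\top(\xi_2{-}\xi_1) + \epsilon^2(\xi_1^\top
C_{11}\xi_1 + 2\xi_1^\top C_{12}\xi_2 + \xi_2^\top C_{22}\xi_2) +
O(\epsilon^3)$, which coincides with the usual scalar-trait formula and is
the version that passes the $O(\epsilon^3)$ Richardson check in the tests.

`classify_outcome()` then reads the generic outcome off the signs of
$(S_{x_1}(x_2), S_{x_2}(x_1))$ in the regime set by which statistic is
resolved: a resolved first-order drive gives invasion-implies-substitution;
a vanishing drive with resolved quadratic statistic gives the four
"Lotka–Volterra" outcomes — substitution either way, protected coexistence at
$p^* = S_{12}/(S_{12}+S_{21})$, or bistable mutual exclusion; a vanishing
quadratic with resolved mixed statistic gives substitution only; and when
all three vanish the case is degenerate (higher-order terms, out of scope,
would decide) and is reported as undetermined rather than guessed. The
theorems behind the classification assume strict inequalities, so a dead
band is mandatory: $3\times$ the propagated fitness SE for ergodic
estimates, $10^{-8}$ for closed forms. Sign patterns inconsistent with the
active regime are flagged and returned undetermined instead of being forced
into a category.

`compare_to_averaged()` closes the loop empirically: it simulates the
dimorphic system at each $\epsilon$ out to a horizon of 20 units of the
relevant slow clock ($t_1 = \epsilon t$ or $t_2 = \epsilon^2 t$; the
constants in the underlying limit theorems are existential, so the window is
scaled by the measured drive), and reports $\sup |P_t - p^*|$ over the second
half of the window. The first half is treated as the unknown settling time.

## The example registry

Four fully parameterized models double as the synthetic test-bed; their
defaults are the published parameter sets and are frozen field-by-field in
the tests.

* **Chemostat** — bacteria $x = (\beta, \gamma, \delta)$ on a nutrient whose
  input switches randomly between $\rho_1 \pm \rho_2$ through the bounded map
  $2\theta/(1+\theta^2)$ of an OU driver. Neutrality pins
  $E[R] = (\delta + D)/(\gamma\beta)$, giving the closed-form fitness
  $\gamma'\beta' E[R] - \delta' - D$ and the clean result that invasion is
  equivalent to a threshold inequality — so substitution is the only
  possible outcome, which the classifier reproduces.
* **Lotka–Volterra competition** — log-normally modulated growth rate and
  carrying capacity with a non-symmetric competition kernel. The closed-form
  fitness is $r(y)\,\kappa\,(1 - \alpha(x, y) K(x)/K(y))$. Two printed
  conventions needed resolving: the kernel's argument order in the fitness
  and the constant $\kappa = E[e^{\rho_1\theta}]$. We evaluate the kernel
  with (resident, mutant) arguments and use the exact OU moment
  $\kappa = e^{\rho_1^2 b^2/(4a)}$ (`prefactor_mode = "ou_exact"`); this
  combination reproduces all six published pairwise fitness values exactly
  and puts the second kernel's singular strategies at $\pm 0.5$ on the
  $C_{11} + C_{22} = 0$ substitution line, as described for that kernel. The
  alternative constant $e^{\rho_1^2 b^2/(2a)}$ remains available and can
  never change a sign.
* **Structured SIRS** — viral strains with infected/recovered classes,
  environment $e = (S, M)$, and log-normally fluctuating transmission. The
  small-noise fitness approximation computes the deterministic endemic
  equilibrium (a scalar root in $M$), linearizes the four-dimensional
  resident system, solves the stationary covariance from the continuous
  Lyapunov equation (Kronecker identity; no dedicated solver is needed at
  dimension four), and contracts the Hessian of $e^{\rho_1\theta}S/M$
  against it. The covariance correction is itself $O(\rho_1^2)$ — the same
  order as the approximation's stated error — so a percent-level discrepancy
  against independently simulated averages is inherent to the formula, not a
  bug; the tests document this.
* **Prey–predator** — deterministic timidity evolution with non-equilibrium
  resident dynamics: the interior equilibrium loses stability through a
  supercritical Hopf bifurcation as timidity decreases (located at
  $x \approx 0.6298$ for the default parameters by `find_hopf()`), and
  invasion fitness on the periodic side is a period average per the
  time-average definition.

An `analytic_model()` fixture exposes an arbitrary two-argument fitness
surface directly and is the unit-test workhorse for the expansion and
classification code.

## What the synthetic fixtures do and do not show

The fixtures exercise every structural feature the theory needs — feedback
through both environment components, implicit environments, bounded and
unbounded noise, population structure, and non-equilibrium attractors — with
known closed-form or semi-analytic answers to test against. They are still
low-dimensional, smooth, and ergodic by construction. Passing tests therefore
demonstrate correctness of the numerics and of the classification logic, not
that real systems satisfy the standing assumptions (ergodic driver,
second-order smoothness, square-integrable growth rates, a unique relevant
invariant measure reachable from the chosen initial condition). Multiple
coexisting invariant measures are diagnosed only per initial condition, and
basin probabilities of bistable pairs are reported as bistability, not
estimated.

## Numerical choices and limitations

* Finite-difference steps: $10^{-5}$ (relative) for validation probes and
  Jacobians, $10^{-3}(1+\lVert x\rVert)$ for fitness derivatives; both
  configurable.
* Period detection refines a sampled-grid estimate with integrator event
  location; the reported uncertainty is the difference between the two.
* The implicit-environment solver assumes the fixed-point map is a
  contraction near the trajectory (true for all bundled fixtures); the
  Newton fallback widens the basin but no global guarantee is attempted.
* Euler–Maruyama is weak order 1; the equivalence and convergence tests
  measure exactly that rate. No higher-order SDE schemes are provided.
* Degenerate expansions (all three regime statistics under tolerance) are
  reported as undetermined; unprotected coexistence driven by higher-order
  terms is out of scope.

## A worked example

```{r, eval = FALSE}
m <- chemostat_model()
x <- c(2, 0.8, 0.095); y <- c(1.99, 0.85, 0.09)
invasion_fitness(m, x, y, method = "closed_form")$value   # 0.01615156
classify_pair(m, x, y)                                    # substitution, p* = 1

pp <- prey_predator_model()
att <- periodic_attractor(pp, list(0.27))                 # tau = 11.193
invasion_fitness(pp, att, 0.3, method = "periodic")$value # 0.0021660
find_hopf(function(z) pp, c(0.3, 1), eq_guess = c(0.5, 0.5))$x_hopf # 0.62983
```
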