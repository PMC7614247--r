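---
title: "Reducing dynamical networks with nonlinear memory functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing dynamical networks with nonlinear memory functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memnet)
```

## The problem

A deterministic reaction or gene-regulation network evolves as
$\dot{x} = R(x)$ with smooth, closed-form rate laws. As networks grow, full
models become hard to simulate and harder to interpret. `memnet` reduces such
a network to an arbitrary **subnetwork** $x^s$ of tracked species, eliminating
the remaining **bulk** species $x^b$ while retaining their dynamical effect.

The baseline reduction is the quasi-steady-state (QSS) approximation: for any
subnetwork state, the bulk is assumed to sit at its steady state
$x^{b*}(x^s)$, defined by $R^b(x^s, x^{b*}) = 0$, giving the reduced drift
$v(x^s) = R^s(x^s, x^{b*}(x^s))$. The method's one structural assumption is
that this bulk steady state is *unique* for every subnetwork state — the
subnetwork must be able to produce all fixed points itself. The QSS reduction
preserves fixed points but distorts transients: the bulk does not actually
equilibrate instantly.

The package's core corrects this with a closed-form, state-dependent
**memory function**. Projection-operator (Zwanzig–Mori) theory says the exact
reduced dynamics take the form

$$\frac{d x^s}{dt} = v(x^s(t)) + \int_0^t M\!\big(x^s(t'),\, t - t'\big)\,dt'
  + r(t),$$

where the memory $M$ carries the influence of the subnetwork's past, fed back
through the bulk, and the random force $r$ vanishes when the bulk starts at
QSS. A systematic linearization in the bulk's deviation from QSS yields an
explicit memory:

$$M(x^s, \tau) = B\big(\varphi_v(x^s, \tau)\big)\, G(\tau)\, c(x^s),$$

built from objects the package evaluates exactly at $(x^s, x^{b*}(x^s))$:

* $c = J^{-1} A\, v$ — how fast the bulk is being pushed off QSS
  ($A = \partial R^b/\partial x^s$, $J = \partial R^b/\partial x^b$). Since
  $c \propto v$, the memory vanishes identically at every reduced fixed
  point: the reduction never moves steady states.
* $G(\tau)$ — the time-ordered exponential of the bulk-deviation relaxation
  generator $\Lambda = J + J^{-1} A B$ along the QSS flow $\varphi_v$,
  computed as the solution of the matrix ODE
  $dG/d\tau = \Lambda(\varphi_v(x^s, \tau))\, G$, $G(0) = I$.
* $B = \partial R^s / \partial x^b$ — how bulk deviations feed back into the
  subnetwork drift, evaluated at the transported point.

Two reduced integrators use this memory:

* **ZMn** (`integrate_zmn()`) solves the projected integro-differential
  equation literally, discretizing the history integral on a fixed grid with
  trapezoidal weights; the memory function itself is propagated along the
  QSS flow.
* **ZMs** (`integrate_zms()`) is the self-consistent variant: propagation
  uses the actual memory-corrected trajectory instead of the QSS flow. The
  memory integral then collapses to one auxiliary ODE per bulk species,
  $\dot m = c(x^s) + \Lambda(x^s)\, m$, $m(0) = 0$, with memory term $B\,m$.
  ZMs is cheaper, extends the linearization partially to higher order, and is
  *exact* whenever the rates depend at most linearly on the bulk species (the
  auxiliary $m$ then equals the true bulk deviation). It is the default
  variant throughout the analysis tooling; ZMn is retained for validation and
  for introspecting the memory function itself.

Near a fixed point both variants linearize to the same convolution kernel
$K(\tau) = B^* e^{\tau \Lambda^*} (J^{*-1} A^*) V^*$ (with
$V = \partial v/\partial x^s$), and the projected linear system reproduces
the subnetwork block of the full linearized dynamics exactly — so relaxation
rates near stable states are inherited from the full model. This exactness is
a falsifiable property here: the test suite integrates both routes and
compares impulse responses.

## Orientation of the generator, certified by oracles

Index conventions in memory formulas of this kind are notoriously easy to
transpose. The package fixes all contraction orders by *requiring* two
independent properties to hold numerically:

1. on a fixture whose bulk matrix is asymmetric and whose rates are linear in
   the bulk, the ZMs trajectory must equal the full subnetwork trajectory to
   integrator precision;
2. the linearized-kernel impulse response must match the full linearized
   system.

Both fail if $\Lambda$, its transpose, or the propagator ordering is swapped
anywhere. The scalar-bulk case (where ordering is immaterial) is additionally
pinned to a quadrature oracle and to a method-of-lines residual check of the
transport PDE that the memory solves.

## Memory channels

Because $c$ contains the outgoing derivatives $\partial R_{b''}/\partial
x_{s'}$ and $B$ the incoming derivatives $\partial R_s/\partial x_b$, the
memory splits exactly into additive **channels** — quadruples (source
species, outgoing bulk mediator, incoming bulk mediator, target species) —
with the propagator shared between them (`decompose_channels()`). Channels
whose derivative is identically zero (absent edges) are dropped. The
quadruple level is canonical; sender–receiver aggregation is provided as a
view when exporting graphs.

`rank_channels()` scores channels along a ZMs trajectory by carrying one
auxiliary accumulator per outgoing channel and integrating the absolute
contribution of each channel to $\dot x^s$; scores are normalized to sum to
one. This importance metric is a reconstruction — the package documents it as
such and also offers maximum-absolute and signed-integral metrics.
`ablate_channels()` simulates with a chosen subset of channels kept and the
rest set to QSS; keeping all channels reproduces ZMs exactly (the
per-channel accumulators sum to the per-bulk accumulator), keeping none
reproduces QSS.

## What the fixtures emulate

* `bistable2` — the two-species mutual-repression switch
  $\dot x_j = a/(1 + x_i^n) - x_j$. Its published phase portrait prints
  steady states $(6, 0.028)/(0.028, 6)$ and a saddle at $(1.46, 1.46)$;
  those values satisfy the rate law for $a = 6, n = 3$, which are therefore
  the fixture defaults (the figure's stated $a = 4, n = 2$ is inconsistent
  with its own printed fixed points; we document rather than resolve the
  discrepancy).
* `multistable_or` — the $N$-species "or"-logic cross-repression network; at
  $N = 3$, $a = 4$, $n = 2$ it is tetrastable (three high–low–low states plus
  a symmetric one), the standard testbed for basin-of-attraction fidelity.
* `repressilator` — three-species cyclic repression with a supercritical Hopf
  bifurcation in the $(a, n)$ plane. With bulk $\{x_3\}$, the memoryless QSS
  reduction can only damp; the ZMs reduction recovers sustained oscillations
  with a qualitatively matching Hopf boundary. Quantitative period/amplitude
  matching in the sustained regime is *not* claimed.
* `neural_tube4` — an illustrative four-transcription-factor circuit
  (Nkx2.2, Olig2, Irx3, Pax6) with the cross-repressive topology of the
  vertebrate neural tube network and a signal parameter $p \in [0,1]$. The
  shipped parameters are plausible but not a published fit (that
  parametrization is unavailable), so every neural-tube analysis in the
  package is structural or qualitative, and the fate-map workflow ships as an
  example script rather than a tested claim.
* `linear_bulk_demo` — one subnetwork species, two bulk species, rates linear
  in the bulk with an asymmetric Hurwitz bulk matrix; the ZMs-exactness and
  orientation-certification fixture.

Hill repression terms in the fixtures are written as $(x^2)^{n/2}$, the
smooth even extension of $|x|^n$: identical on the positive orthant where the
models live, but well defined when a *reduced* trajectory makes a small
negative excursion (reduced dynamics do not preserve positivity) and for
non-integer Hill exponents in parameter scans.

What the fixtures do not emulate: stochasticity, spatial coupling, explicit
delays, conservation laws, or rate laws outside smooth
arithmetic/Hill/exponential forms. Passing tests therefore certify the
projection machinery on smooth multistable and oscillatory ODE networks, not
performance on noisy or non-smooth biological data.

## Numerical choices

* **Bulk QSS solves** use damped Newton iteration with the analytic bulk
  Jacobian, residual tolerance $10^{-12}$ (max-norm). Cold solves multi-start
  deterministically (origin, cached solution, 8 Halton points in a
  production/degradation box) and raise an error if distinct roots are found
  — the unique-QSS precondition is *detected*, not assumed silently, though a
  multi-start sweep is a heuristic detector, not a proof. Warm solves during
  integration reuse the previous bulk solution (continuation).
* **Fixed points** are located by multi-start damped Newton over a
  user-supplied box (Halton starts, duplicates merged at $10^{-6}$), polished
  to near machine precision so that downstream properties (memory vanishing
  at fixed points) are limited by arithmetic, not root residuals.
  Eigenvalues with $|\mathrm{Re}\,\lambda| < 10^{-8}$ flag a point as
  `marginal` rather than forcing a stable/saddle call — Hopf scans sit
  exactly at marginality.
* **ODE integration** uses `deSolve::lsoda` (adaptive, stiff-capable),
  default `rtol` $10^{-8}$ for production runs and $10^{-9}/10^{-12}$ for
  QSS flows; trajectories store exact right-hand-side derivatives at the
  output nodes and interpolate with cubic Hermite polynomials (exact at
  nodes, $O(h^4)$ between; evaluation times are clamped to the stored range).
* **ZMn discretization**: history step $h = t_{\rm end}/800$ by default with
  trapezoidal weights and a Heun outer stepper (both second order; halving
  $h$ shrinks the error fourfold, which is regression-tested). Per outer
  step, all history auxiliaries (flow point and propagator per node) advance
  by one batched Runge–Kutta step, so cost per step is linear in history
  length; nodes whose propagator norm decays below $10^{-12}$ stop
  contributing. No discretization for this integral is prescribed by the
  theory; these choices are certified by self-convergence and by agreement
  with ZMs near fixed points.
* **Oscillation classification** discards the first 30% of a trajectory,
  splits the rest into six blocks, and measures the peak-to-trough envelope
  per block; verdicts are `sustained-oscillatory` when per-period envelope
  ratios stay within 1% of unity across five successive blocks (each
  containing at least one maximum), `damped-oscillatory`, `converged`, or
  `inconclusive`. Envelope ratios are normalized per period, making the rule
  robust to limit cycles with secondary extrema. In Hopf scans the
  simulation verdict for the full system is cross-checked against the
  eigenvalue criterion at the symmetric fixed point, with a marginality band
  (default $|\mathrm{Re}\,\lambda| < 0.02$) where simulation-based
  classification is intrinsically unreliable.
* **Basin maps** integrate each lattice node until within $10^{-3}$
  (absolute) of a catalogued attractor or $t_{\max} = 500$; unresolved nodes
  are reported as `NA`, never silently labeled. Full-variant runs initialize
  the bulk at QSS. Separatrix points can be refined by bisection (20 steps
  by default) between oppositely-labeled nodes.

## Problem sizes used in the shipped checks

The test suite exercises: the two-node switch everywhere; the three-species
tetrastable network on a $21 \times 21$ basin lattice (three variants); a
$10 \times 8$ grid Hopf scan of the repressilator over
$a \in [1.5, 12]$, $n \in [2.4, 4.2]$ at trajectory horizon $t = 100$ (the
scan range brackets the full system's Hopf curve, which in closed form runs
through $x_c = (2/(n-2))^{1/n}$, $a_c = x_c\, n/(n-2)$ and exists only for
$n > 2$);
channel checks at 100 random states per fixture; and a
$171 \times 601$ method-of-lines grid for the transport-PDE residual. These
sizes were chosen as the smallest at which each qualitative claim is stable
under refinement.

## Known limitations

* The memory is first order in bulk deviations from QSS; strongly nonlinear
  bulk excursions are only partially captured (ZMs resums some higher-order
  effects, with exactness only for bulk-linear rates).
* Sustained-oscillation *existence* and the Hopf boundary are replicated
  qualitatively; period and amplitude in the sustained regime are not
  quantitative targets.
* The unique-QSS assumption restricts admissible partitions; the solver
  detects violations at evaluation points along trajectories, which is
  necessarily a heuristic.
* Reduced trajectories may leave the positive orthant transiently; fixtures
  are smooth there by construction, but user models with poles at negative
  concentrations may fail mid-integration (the error reports the last time
  reached).
* The channel-importance metric is a documented reconstruction; rankings
  should be read as orderings, not calibrated effect sizes.

## A worked example

```{r example, eval = FALSE}
model <- fixture_model("bistable2")        # two-node switch, a = 6, n = 3
partition <- default_partition(model)      # x1 tracked, x2 eliminated

find_fixed_points(model, c(0, 10), system = "full")
#> stable (0.028, 6.000) and (6.000, 0.028), saddle (1.460, 1.460)

times <- seq(0, 30, length.out = 301)
full <- integrate_full(model, 1.4, times, partition = partition)
qss <- integrate_qss(model, partition, 1.4, times)
zms <- integrate_zms(model, partition, 1.4, times)
# QSS collapses to the low state far too fast; ZMs tracks the full transient

memory_function(model, partition, xs = 1.5, tau = c(0, 0.5, 1, 2))
# negative memory opposing the positive drift: the reduction slows itself
# down to mimic the sluggish bulk
```
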