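---
title: "Fixation of green-technology innovation strategies in finite populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation of green-technology innovation strategies in finite populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greengame)
```

## The model

`greengame` analyses a two-stage evolutionary game played by a finite
population of `N` firms deciding whether to invest in green technology.

**Stage 1 (innovate V vs. do-not-innovate D).** Innovators pay an R&D cost
`C` that succeeds with probability `P(C)`, earn a discounted share of the
societal reward `R` (share `a` against a non-innovator, `b` jointly against
another innovator) over a horizon discounted at rate `r`, and collect a
policy incentive `T` on success. Non-innovators earn nothing against an
innovator and bear the per-capita ecological loss `-R*` against another
non-innovator. That last cell is what makes the game interesting: universal
free-riding is itself costly, so innovation can be favoured even without a
subsidy.

**Stage 2 (lead L vs. follow F).** Once innovation is universal, the
second-order free-riding problem appears: followers wait out the monopoly
period `(0, t1)` and then share the duopoly reward over `(t1, t2)` without
paying the R&D cost. The policy lever here is the *differential
coefficient* `mu` in `[1, 2]`: leaders receive `mu * T`, followers
`(2 - mu) * T`, so the mean incentive is `T` regardless of `mu`.

Strategy frequencies evolve by a frequency-dependent Moran process: at each
step one firm reproduces (i.e., its strategy is imitated) with probability
proportional to fitness and replaces a uniformly chosen firm, so the
population size stays `N`. With `i` innovators, expected payoffs use
opponent sampling that excludes the focal player:

```
U_A(i) = ((i-1) pi_AA + (N-i) pi_AB) / (N-1)
U_B(i) = (i pi_BA + (N-i-1) pi_BB) / (N-1)
```

The chain on `i = 0..N` is tridiagonal; without mutation the boundaries are
absorbing and the probability that a single invader takes over the
population (its *fixation probability*) has the classical birth–death
closed form implemented in `fixation_vector()`. The ratio of the two
single-invader fixation probabilities equals the product of the state-wise
fitness ratios, and its first-order expansion in the selection strength `u`
is the weak-selection approximation of `weak_selection_ratio()`.

## Fitness maps, negative payoffs, and the clamp

The baseline fitness map is linear, `f = 1 - u + u U`. Under the bundled
scenario the mutual free-riding payoff is `-R* = -100`, so the linear map
produces negative fitness already at `u` around 0.01 — a negative
reproduction rate is meaningless, and the published account of the model
does not say how (or whether) it handled this. We make the choice explicit:

* linear fitness is clamped below at a configurable `fitness_floor`
  (default `1e-9`); every clamp is counted and the count travels with each
  result (`$clamped`), with an optional message under
  `options(greengame.verbose = TRUE)`;
* the exponential map `f = exp(u U)`, which is always positive and is the
  standard choice under stronger selection, is available everywhere via
  `fitness_map = "exponential"`.

Two consequences of the clamp are worth knowing. First, monotonicity of
fixation in `u` is *not* guaranteed under the clamped linear map: as `u`
grows, more states hit the floor on both sides, and the fixation
probability of the favoured strategy can fall. The package therefore runs
selection-strength scans on the exponential map, for which the fixation
probability is provably monotone whenever every payoff difference favours
the focal strategy. Monotonicity in `T` and in `mu` is a different matter:
the incentive enters only the focal strategy's payoffs, `max(f, floor)`
preserves monotonicity, and so those scans are run on the linear default.

Second, the clamp is what produces the incentive *threshold*. At truly weak
selection (`u` below roughly 0.08 in the bundled scenario) rare innovators
are favoured at any `T >= 0` — the `-R*` cell already punishes free riders
— and `N Q_V` never drops below 1. At moderate and strong selection the
linear map floors the innovators' fitness in the upper state range while
free riders' fitness is still positive there, suppressing fixation until
the incentive lifts innovator payoffs out of the inadmissible region. The
package's threshold scans default to `u = 0.5` (the strength used in the
published simulations); the acceptance checks use `u = 0.1`, the smallest
strength at which the effect exists.

## What the engine computes

```{r fixation}
sc <- suppressWarnings(load_scenario(scenario_preset()))
p <- sc$econ
stage1_payoffs(p)
fr <- fixation_result(moran_model(stage1_payoffs(p), N = p$N, u = 0.005))
fr
```

`absorbing_solve()` recomputes the same fixation vector by a dense linear
solve of the absorbing-chain equations; it shares no code with the product
formula and the two agree to `1e-10` on randomized games — that equivalence
is the package's core correctness check.

```{r sweep}
sw <- sweep_incentive(p, T_grid = seq(1, 150, by = 5), u = 0.1)
sw
```

The threshold is located on the `N * Q_V` metric against its neutral
baseline 1, bisection-refined to `1e-3` on the incentive axis (both the
metric and the baseline are selectable; in the weak-selection regime all
choices cross at the same point). `sweep_mu_T()` scans the stage-2 plane
and reports, per `(mu, T)` point, the fixation metrics, the interior
equilibrium of the payoff-difference profile, and the *incentive-response
coefficient* — the derivative of the first-order invasion exponent with
respect to `T`,

```
d/dT sum_i (U_L - U_F) = P(C) ((N-1) mu - (N/2)(2 - mu)),
```

which grows with `mu` and quantifies the "a more unequal split makes the
incentive bite faster" trade-off. `two_stage_run()` composes the stages:
stage 2 is analysed conditional on stage-1 fixation and skipped (marked
unreached) when innovation is strictly dominated.

## Simulation

`run_ensemble()` realizes the process: reproducer by fitness, uniform
replacement, and — following the published setting — a 1% chance per
replacement event that the offspring's strategy flips. Mutation semantics
are stated rather than inherited: the convention here is mutation on every
replacement event, the most common Moran-with-mutation choice; per-copy or
per-generation conventions exist and would change the stationary
distribution. With mutation the chain is irreducible and reversible, so
`stationary_distribution()` gives the exact long-run occupancy by detailed
balance, and `empirical_stationary()` cross-checks a long simulated chain
against it (total-variation distance about 0.02 at `10^6` steps, `N = 20`).

All randomness flows through R's seedable generator; an ensemble with the
same spec and seed reproduces bitwise, and every CLI output is accompanied
by a parameter echo sufficient to re-run it exactly.

## Numerical choices

* Products of `N - 1` fitness ratios overflow easily (especially with
  clamped ratios near `1e9`); fixation quantities are accumulated in log
  space with a max-shift, and the fixation ratio is reported both raw and
  as a log.
* The fixation-ratio identity `Q_A/Q_B = prod f_A/f_B` is exact for the
  clamped fitnesses actually used, so it holds at machine precision in
  clamp-free regimes and remains internally consistent when clamps fire.
* Interior equilibria are sign changes of the payoff-difference profile,
  located by linear interpolation between adjacent integer states (the
  profile is affine in `i` for 2x2 games, so interpolation is exact);
  positive-to-negative crossings are classified stable.
* The weak-selection routine warns when its first-order value strays more
  than 10% from the exact ratio, and its truncation error is `O(u^2)`:
  halving `u` near `u = 0.01` reduces the error by a factor of about 4.
* The dense oracle is limited to `N <= 2000` by default; the product
  formula itself is O(N) and has no practical limit here.

## The synthetic scenario and its limits

The bundled preset (`scenario_preset()`) encodes the published simulation
scenario: `N = 100`, `C1 = 2`, `a = 0.4`, `b = 0.7`, `R = 1000`, `C = 100`,
`P(C) = 0.4`, `r = 0.015`, `t1 = 100`, `t2 = 300`, `R* = 100`, mutation
0.01, selection strength 0.5. Two printed inconsistencies are handled
deliberately rather than silently: the scenario violates the model text's
`R = N R*` identity (loading it warns once but runs unmodified), and the
model restricts `T` to `(0, 1)` while simulating `T` up to 150 (any
positive `T` is accepted). `P(C)` is a direct input; no functional form is
fitted. The printed constraint `0 < ab < 2a` is enforced as printed, though
it reduces to `0 < b < 2` (a crowding-out bound `b < 2a` may have been
intended; we do not impose it).

Randomized test games draw all four payoffs uniformly from `[-2, 2]` —
small enough that the linear map stays admissible at the selection
strengths tested, which is precisely the regime where the analytic theory
is exact. What passing tests show is that the engine computes the model
correctly, not that the model describes real innovation markets: real
firms are heterogeneous, interact on networks, and learn asymmetrically,
none of which is represented here.

Two published headline numbers are knowingly not reproduced, because they
are not well-defined: the "invasion dynamics"/"replacement probabilities"
tables report probabilities exceeding 1 with no defining formula, and the
reported interior equilibrium (0.6774 at `T = 85, mu = 1.297`, and the
claim that `T = 150, mu = 1.085` shares it) does not solve
`U_L(i) = U_F(i)` under the printed parameters — the package computes those
roots as 0.9231 and 0.8686. The package instead reports clearly defined
metrics (`Q`, `N Q`, log fixation ratio, invasion exponent, equilibrium
roots) and, for contour comparisons, extracts genuine iso-equilibrium
pairs with `iso_equilibrium_T()`.

## Problem sizes used in the checks

Test and acceptance computations use the scenario's `N = 100` for analytic
quantities, randomized games at `N` up to 50 for the oracle equivalence,
10,000-replicate ensembles at `N = 20` for Monte Carlo agreement, and
`5x10^5`–`10^6`-step chains at `N = 20` for stationary cross-checks —
sizes chosen so the full suite exercises every code path in well under a
minute while keeping Monte Carlo confidence intervals tight.
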