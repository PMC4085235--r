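---
title: "Stochastic Bulirsch-Stoer simulation of chemical kinetics: methods and design"
author: "StochBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic Bulirsch-Stoer simulation of chemical kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StochBS)
```

## The problem

A well-stirred chemical system with `N` species and `M` mass-action
reactions is a continuous-time Markov jump process on the lattice of
copy-number vectors `X(t)`.  Each reaction `j` has a stoichiometric change
vector $\nu_j$ and a propensity $a_j(x)$, with
$a_j(x)\,dt$ the probability that reaction `j` fires in $[t, t+dt)$.
Propensities use Gillespie's distinct-combination convention,
$a_j(x) = c_j \prod_i \binom{x_i}{m_{ij}}$, so a homodimerisation
contributes $x(x-1)/2$ and a trimerisation $x(x-1)(x-2)/6$.  Buffered
("fixed") species enter propensities but are never updated.

Gillespie's stochastic simulation algorithm (SSA) samples every reaction
event and is statistically exact, but becomes slow when populations or
rates are large.  Leaping methods fire many reactions per step:
the Euler $\tau$-leap draws $K_j \sim \mathrm{Poisson}(a_j(x)\tau)$.  Its
accuracy is limited by freezing the propensities at the step start, which
is precisely the first-order error that the methods in this package
remove.

## The Stochastic Bulirsch-Stoer method

The exact update of the jump process over one step is
$$X_{n+1} = X_n + \sum_j \nu_j\,
  \mathcal{P}\!\Big(\textstyle\int_{t_n}^{t_n+\tau} a_j(X(s))\,ds\Big),$$
so the quantity worth computing accurately is the *propensity integral*
$\Delta a_j$.  The SBS computes the expected integral along the
deterministic reaction-rate trajectory started at $X_n$, to very high
order, and then draws one Poisson variate per reaction channel:

1. **Modified midpoint (Gragg) stages.**  For substep counts
   $n_q = 2q$, the reaction-rate equations
   $\dot x = \sum_j \nu_j a_j(x)$ are advanced with the two-step midpoint
   scheme; its global error expands in even powers of $\hat\tau = \tau/n_q$.
2. **Composite trapezoid.**  Propensities evaluated at the raw stages
   give $\Delta a^{\hat\tau_q}_j$, a second-order approximation of
   $\int a_j$, again with an even error expansion.
3. **Neville/Romberg extrapolation in $\hat\tau^2$.**  Successive rows are
   combined by
   $Y_{q-r,q} = Y_{q-r+1,q} + (Y_{q-r+1,q} - Y_{q-r,q-1}) /
   ((n_q/n_{q-r})^2 - 1)$; each new column removes the next even error
   term.
4. **Error gate.**  Column `q` is scaled by a mixed tolerance,
   $err_q = \lVert Y^{\hat\tau_1,\hat\tau_q} - Y^{\hat\tau_2,\hat\tau_q}
   \rVert_2 / (atol + rtol\,\lVert Y^{\hat\tau_1,\hat\tau_q}\rVert_2)$,
   and accepted when $err_q \le 1$.  A step with no acceptable column in
   the working window is redone with $\tau/2$, as is a step whose Poisson
   update would drive a population negative.
5. **Order/stepsize control.**  Candidate stepsizes
   $\tau_k = \tau\,S_1 (S_2/err_k)^{1/(2(k-1)+1)}$ are formed per column,
   and the next (column, stepsize) pair minimises the work per unit step
   $W_q = A_q/\tau_q$, where $A_1 = 3$ and $A_{q+1} = A_q + n_{q+1}$
   counts drift evaluations (all rows share the start-state evaluation,
   hence $A_q = 1 + \sum_{q' \le q} n_{q'}$).  The first step tests
   columns upward to `kMax` (default 8); later steps test only
   $\{k-1, k, k+1\}$.

### The degree-of-advancement variant (SBS-DA)

Instead of propensity integrals, the SBS-DA integrates the per-step mean
$\mu_j$ and variance $V_j$ of the reaction counts under a first-order
closure with coefficients frozen at the step start:
$$\dot\mu_j = \sum_{j'} f_{jj'}(X_n)\mu_{j'} + a_j(X_n), \qquad
  \dot V_j = 2 f_{jj} V_j + \dot\mu_j, \qquad
  f_{jj'} = \sum_i \frac{\partial a_j}{\partial x_i}\nu_{ij'},$$
with $\mu_j(0) = V_j(0) = 0$.  Two Neville tables are built jointly (the
stacked $(\mu, V)$ vector is extrapolated in one pass); convergence is
gated on the $\mu$ block, and the variance inherits the accepted column.
The update draws $K_j \sim \mathrm{Poisson}(\mu_j)$ when $\mu_j < 10$ and
a rounded Gaussian $\lfloor N(\mu_j, V_j)\rceil$ clamped at zero
otherwise.  The closure is exact for linear propensities; for non-linear
ones it caps the weak order of the mean at two, which is the structural
contrast the order studies exhibit.

### Comparators

* **SSA** (compiled): exact paths, the distributional reference.
* **Euler tau-leap (TL)**: adaptive stepsize from the
  Cao-Gillespie-Petzold bound — $\tau$ bounds the mean and standard
  deviation of the relative propensity change by `epsilon`, with the
  highest-order correction factors $g_i$ (e.g. $2 + 1/(x-1)$ for a
  species consumed twice in a second-order reaction).  The paper-level
  description only fixes the principle, so this standard bound-based
  scheme without critical-reaction partitioning is used; negative
  populations reject the draw and halve $\tau$.
* **Unbiased tau-leap (UBTL)**: the same stepsize bound, but the
  reaction-count moments from the closure ODEs (8 and 16 substeps with
  one extrapolation) and the hybrid Poisson/Gaussian update.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `s1`, `s2` | stepsize safety factors, dimensionless, in (0,1) | 0.25 | smaller values shrink steps; equilibrium column error is $S_2 S_1^{2(k-1)+1}$ |
| `atol`, `rtol` | absolute/relative error tolerances | 1e-6 | scale the Romberg column error |
| `kMax` | deepest column tried on the first step | 8 | conventional Bulirsch-Stoer depth |
| `tau0` | initial stepsize (time units) | `NA` | `NA` uses `tau0Multiple / a0(x0)`, a conservative multiple of the expected SSA step |
| `tau0Multiple` | multiple for the conservative policy | 10 | |
| `epsilon` | leap-condition bound for TL/UBTL | 0.05 | TL needs $\epsilon \ll 1$; UBTL tolerates much larger values |
| `maxGrowth` | stepsize growth cap per step | 4 | the printed stepsize rule caps the vanishing-error guard at `tau*s1*maxGrowth`; the general branch is capped at `tau*maxGrowth`, since a cap containing $S_1$ would forbid growth whenever $S_1 \le 1/\mathrm{maxGrowth}$ |

Two practical regimes exist, governed mostly by `tau0` and the safety
factors: a low-$\tau$ regime (column 2, many cheap steps) and a
high-$\tau$ regime (columns 3+, few steps).  Both are valid; the
high-$\tau$ regime is far cheaper per realisation.  The step diagnostics
(`stepInfo`) record $\tau$, the accepted column, rejections and work so
the regime can be inspected.

## Exact measurement machinery

Monte-Carlo averaging is too noisy to reveal weak orders of accurate
methods, so the order studies are fully deterministic:

* **Linear mean recursion** (`linearMeanRecursion`): for a one-species
  linear system the per-step Poisson parameter is linear in the state, so
  the chain mean is an exact scalar recursion; errors against the
  closed-form Yule mean $x_0 e^{cT}$ carry no sampling noise.
* **Truncated-CME oracle** (`cmeOracle`): for systems whose effective
  stoichiometry has rank one, the master equation on the reachable
  truncated support is solved by uniformization to round-off-level series
  tolerance, with leakage monitored.
* **Exact chain propagation** (`chainDistribution`): the full state
  distribution of a fixed-step method is propagated by convolving its
  deterministically parameterised Poisson (or hybrid) kernels; kernel
  mass that would leave the admissible window is lumped at the boundary
  state (negligible, by construction, in the regimes studied).

## What the generator and benchmarks emulate

The bundled systems carry their standard parameterisations: chain decay
($c = 1, 1$; $X(0) = (10000, 1, 0)$; $T = 5$; bins 2/5/5),
Michaelis-Menten ($c = 10^{-4}, 0.5, 0.5$; $X(0) = (1000, 200, 2000, 0)$;
$T = 10$; bins 5), Schlögl ($c = 3{\times}10^{-7}, 10^{-4}, 10^{-3}, 3.5$;
$A = 10^5$, $B = 2{\times}10^5$ buffered; $X(0) = 250$; $T = 10$; bin 10),
mutually inhibiting enzymes (8 species, 12 reactions; $T = 2$; bins
100/100/50), the Yule order-study system ($c = 0.2$, $X(0) = 1000$,
$T = 12$) and pairwise annihilation.  These are idealised mass-action
networks: well-stirred, constant volume and temperature, no cell growth,
no extrinsic noise, integer copy numbers.  Passing tests show the solvers
reproduce the mathematics of this model class; they say nothing about
rate-law misspecification or spatial effects in real data.

## Problem sizes and numerical choices

The validation suite and the reproduction script use sizes chosen to keep
every measurement deterministic or tightly converged:

* weak orders on the linear system: stepsizes 1.5 down to 0.25, exact
  recursion (no replicates involved);
* non-linear orders: $X+Y\to\emptyset$ with $X_0 = Y_0 = 200$
  ($c = 5{\times}10^{-4}$) for the order-2 measurements and
  $X_0 = Y_0 = 2000$ ($c = 5{\times}10^{-5}$, stepsizes 6 down to 2) for
  the SBS $k=2$ order-4 measurement.  At small populations the
  noise-dependent term of the weak-error expansion dominates and hides
  the fourth-order deterministic term, so the higher-order regime is
  visible only at the larger population and larger steps — the same
  large-population, large-step condition under which the method is argued
  to attain its deterministic order;
* the method comparison on chain decay: $10^4$ realisations per method at
  each method's fastest benchmark setting ($rtol = 10^{-5}$ for the SBS
  methods with their published safety factors and `tau0 = 1`;
  $\epsilon = 0.125$ for TL, $\epsilon = 4$ for UBTL), scored as the
  total L1 histogram distance over all three species against the exact
  analytic marginals (binomial convolutions), bins 2/5/5, origin 0.

Other numerical choices: trapezoid nodes are the raw midpoint stages (the
Gragg-smoothed endpoint is returned for diagnostics only); extrapolation
is polynomial in $\hat\tau^2$, not rational; one scalar error per column
(L2 norm over reaction channels) rather than per-component errors;
variance and mean extrapolants are clamped at zero (a warning is issued
for substantially negative means); rounding in the Gaussian branch is
half-up; the stepsize shrink floor is $10^{-12}\,T$.  Ensembles seed
realisation `i` with `seed + i`, so any subset is reproducible and
independent of batch splitting.

Two engines exist for TL/SBS/SBS-DA/UBTL: the reference implementation in
R (the documented module surface) and a compiled mirror used for
ensembles.  The mirror follows the R code statement by statement and uses
the same RNG stream, so the two are bit-identical for identical seeds —
this is asserted in the test suite across three benchmark systems.

## Known limitations

* Explicit method: no stiff-stability safeguards; very stiff systems need
  small steps or a different solver family.
* The SBS-DA variance closure is diagonal (no covariances between
  reaction channels) and first-order; its mean is order-two-limited on
  non-linear systems.
* The Poisson update is exact in mean but not in distribution for finite
  steps (e.g. binomial thinning is approximated by a Poisson decrement),
  so large-step runs trade distributional accuracy for speed exactly as
  the stepsize-control tolerances dictate.
* The CME oracle and exact chain propagation require an effectively
  one-dimensional (rank-one) system and a bounded reachable support.
* Mass-action propensities only; no Hill or Michaelis-Menten closed-form
  rate laws, no time-varying rate constants, no SBML import.
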