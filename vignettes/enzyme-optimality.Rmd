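---
title: "Optimal enzyme utilization: model, formulation and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal enzyme utilization: model, formulation and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzopt)
```

## The question the package answers

Selection for efficient use of cellular resources pushes enzymes toward a
large net flux per unit of total enzyme, `v_net / E_tot`.  Given an
elementary reaction mechanism, fixed reactant concentrations and the
reaction's thermodynamics, `enzopt` finds the elementary rate constants, the
distribution of the enzyme over its mechanistic states, and the allocation of
the thermodynamic driving force over the elementary steps that maximize this
ratio, subject to the biophysical limits on how fast elementary events can
be.  The result is a condition-specific upper bound on catalytic efficiency
together with the operating mode (saturation, binding preference,
free-energy allocation) that achieves it.

## Model

An elementary mechanism is a graph of enzyme states (`E`, `EA`, `EAB`,
`EP`, ...) connected by reversible steps, each a mass-action association,
dissociation or isomerization.  Three mechanisms are built in: the
three-step reversible Michaelis-Menten scheme (`mech_uni_uni()`), the
compulsory-order Bi-Uni scheme (`mech_ordered_bi_uni()`), and the
random-ordered Bi-Uni scheme (`mech_random_bi_uni()`) in which either
substrate may bind first.  Arbitrary mechanisms are declared through the
same `mechanism()` constructor used by the built-ins, as a table of steps
with binding annotations; route structure (the step set common to all
catalytic routes, the branch combinations whose net fluxes add up to the
overall flux, and the branch cycles expressing microscopic reversibility)
is derived from the graph, never supplied by hand.

Bimolecular rate constants are bounded by diffusion (`1e8`-`1e10` per molar
per second in the literature), monomolecular ones by vibrational frequencies
(`1e4`-`1e6` per second).  `rate_limits()` defaults to the geometric
mid-range of both intervals, `1e9` and `1e5`; dissociation and
isomerization steps share one limit.  Normalizing every rate constant by
its limit confines it to `[0, 1]`, and the ratio of the two limits defines
the characteristic concentration `[C]_ch = k_max_mono / k_max_bi` (0.1 mM
at the defaults), which is the unit of all concentrations.  The equilibrium
constant is made dimensionless with one factor of `[C]_ch` per excess
substrate, which is forced by dimensional consistency of the displacement
definition for any stoichiometry.

Each step `i` carries a thermodynamic displacement `gamma_i`, the ratio of
its backward to forward unidirectional flux; `gamma_i = 1` is elementary
equilibrium.  The overall displacement `Gamma = (1/Keq) * prod(P) / prod(S)`
equals the product of the `gamma_i` along every catalytic route, and the
product around every branch cycle cancels to 1.  For a reaction running
toward products, `Gamma <= gamma_i <= 1`.  Points beyond equilibrium
(`Gamma > 1`) are mapped onto the forward convention by reversing the
mechanism and inverting `Gamma` and `Keq`; the reported net flux carries
the original sign (`v_net_signed`).  Exact equilibrium is answered
analytically with zero flux rather than solved, avoiding a degenerate model
with an empty displacement range.

With unidirectional fluxes decomposed through the displacements, the
maximization over rate constants, enzyme states and displacements is a
nonlinear program: the rate equations contain products of rate constants
and state abundances and of fluxes and displacements.  Three reformulation
steps make it a mixed-integer linear program:

1. *Change of variables.* Each product `k * e` becomes one variable `z`
   bounded above by its enzyme state (`z_f[i] <= e_from`,
   `z_b[i] <= e_to`), which is exact because the normalized constants live
   in `[0, 1]`.
2. *Displacement discretization.* One displacement per route is eliminated
   through `Gamma`; the remaining independent displacements (or
   mechanistically meaningful composites) are approximated
   piecewise-constantly on `N` bins, `g = Gamma + p (1 - Gamma) / N` with
   `p` written in binary.  Both endpoints are reachable (`p` ranges `0..N`
   inclusive), so a displacement can sit exactly at `Gamma` or at 1.  For
   the three-step mechanism the independent set is `(g_1, g_12)` with
   `gamma_2 = g_12/g_1`, `gamma_3 = Gamma/g_12` and the ordering
   `g_12 <= g_1`; for the random-ordered mechanism it is
   `(g_cycle, g_1, g_5, g_3)` where the shared branch product `g_cycle`
   satisfies the cycle constraint by construction, with
   `gamma_4 = Gamma/(g_cycle g_3)` and the floor
   `g_cycle * g_3 >= Gamma` keeping `gamma_4 <= 1`.  For arbitrary
   unbranched mechanisms the package generalizes the nested cumulative
   chain; for arbitrary two-route mechanisms, a chain per branch plus the
   branch composite plus individual trunk variables.  Mechanisms with more
   than two trunk steps after one branching region would need products of
   three or more binary expansions and are rejected with an explicit error
   rather than silently mis-modelled.
3. *Linearization.* Rate equations are multiplied out by the denominators
   of the displacement expressions, so no division appears.  Products of a
   continuous variable with a binary are replaced by one variable and three
   inequalities (the standard big-M scheme, with the big-M set to the upper
   bound of the continuous factor); products of two binaries by one binary
   and three inequalities.  Aggregate cuts on each expansion
   (`cont * (g - Gamma) <= (1 - Gamma) * cont`) and displacement-implied
   flux cuts (`v_i <= c_f z_f (1 - Gamma)`) tighten the LP relaxation
   without excluding any integer solution.

The default bin width is `1e-4` for unbranched mechanisms and `1e-3` for
the random-ordered mechanism, tightened to `1e-4` whenever `Gamma >= 0.9`
where the displacement range is narrow.  The objective `max v_net` is
solved as a MILP.

## Certified presolve

Branch-and-bound on this model is exact but slow when driven only by the
LP relaxation, because the relaxation detaches the bilinear products.  The
package therefore computes, before every solve, a certified reduction of
the binary domain (`displacement_windows()`).  It exploits a monotonicity
property of the inner problem: at fixed displacements the maximal flux has
a closed form (unbranched) or reduces to minimizing a piecewise-linear
convex function of the branch split (two routes), and every enzyme
requirement coefficient increases with its displacement.  Evaluating the
inner optimum at the per-step displacement lower bounds of a box of
independent-displacement values therefore bounds the achievable flux
anywhere in the box from above.  A breadth-first interval subdivision keeps
a feasible lattice point as incumbent, discards boxes that provably cannot
reach it, and, once the surviving boxes cover few enough lattice points,
enumerates them exactly.  The enumeration yields the exact lattice optimum
and the hull of all bin assignments within `1e-8` (relative) of it; the
MILP is then solved with its binary expansions bounded to that hull and
with the objective bounds pinned.  No optimal or alternative-optimal
assignment is ever excluded (every tie within `1e-8` survives, an order of
magnitude wider than the `1e-9` slack used when the objective is pinned
for variability analysis), so variability results are identical to those
of the unrestricted model; the solver's work collapses to selecting a
vertex.  When a model is built for suboptimal exploration
(`suboptimal_cut = c_l`), the pruning threshold scales by `c_l` and the
objective lower bound is omitted, so the whole suboptimal region survives.

The solver backend is HiGHS through a thin adapter (model serialized as
sparse triplets, solved out of process, solution read back); it runs
single-threaded with a relative MIP gap of `1e-9` and is deterministic for
a fixed model.  Returned solutions are *polished*: the binary bin choices
are decoded into displacement values and the continuous block is recomputed
from the inner fixed-displacement problem in closed form, so enzyme
conservation and the rate identities hold to machine precision rather than
solver feasibility tolerance.  At a flat optimum of the branch split the
polished solution sits at the midpoint of the flat interval -- a
deterministic tie-break; genuine multiplicity is quantified by variability
analysis, never by the solver's vertex choice.

## Post-optimal analyses

*Back-calculation.* The optimization carries `z = k e`, not the rate
constants; `back_calculate_k()` divides by the state occupancies and flags
a constant as undefined when its state falls below `1e-9` -- below
feasibility tolerance the ratio is numerically meaningless.  Feeding the
recovered constants to the independent mass-action steady-state solver
(`steady_state()`, a linear solve of the state balance with one row
replaced by conservation) reproduces the optimum; this round trip is a
standing test invariant.

*Derived quantities.* Saturation `sigma = 1 - e_free`; the splitting ratio
`alpha` of branched mechanisms is the fraction of net flux through the
branch in which substrate A binds first; free-energy shares
`log(gamma_i)/log(Gamma)` sum to 1 along every route.

*Variability and sampling.* Alternative optima are detected by
re-optimizing each variable's minimum and maximum with the net flux pinned
(the splitting-ratio interval pins the denominator and ranges the
upper-branch flux, avoiding a ratio objective).  At flexible optima the
displacements are sampled uniformly within their variability ranges and
fixed; the remaining model is linear.  Its optimal face is the flat
segment of the branch split, along which the enzyme states move linearly
-- that segment is sampled uniformly and exactly, because a random-walk
sampler cannot mix on a measure-zero face.  The suboptimal region
(`v_net >= c_l v*`), which is full-dimensional, is explored with an
artificially centered hit-and-run walk (burn-in 100, thinning 10, both
exposed); draws whose displacements cannot reach the cut are discarded and
counted.  Uniqueness is declared when every variability interval is
narrower than ten times the feasibility tolerance.

*Macroscopic parameters.* `initial_rate_macroscopics()` titrates one
substrate at vanishing product (exact zero: the steady-state solver needs
no displacement), co-substrates saturating at `1e3` dimensionless units,
and fits `v = kcat S / (Km + S)` by least squares -- a Hanes-linearized
start refined by `nls`, in two passes with 12 log-spaced points spanning
`0.01`-`100` times the first-pass `Km`.  For the three-step mechanism the
textbook closed forms (`uni_uni_closed_form()`) serve as an independent
cross-check, and the fitted parameters satisfy the Haldane relation
`(kcat_f/Km_S)/(kcat_b/Km_P) = Keq` to fit tolerance.

## A worked point

```{r example, eval = FALSE}
mech <- mech_random_bi_uni()
pt <- operating_point(mech, c(A = 1, B = 1, P = 1), keq = 2)
sol <- solve_optimal(mech, pt, keep_model = TRUE)
saturation(sol)
splitting_ratio(sol)
alpha_variability(sol$model, sol)
```

At equal substrate availability the optimum is flexible: the
splitting-ratio interval has positive width centered on 0.5, and all
alternative optima share the same saturation and displacement allocation,
trading only the branch fluxes and the `EA`/`EB` occupancies against each
other.  At distinct substrate concentrations the optimum is unique.

## Problem sizes, tolerances and defaults

* Bin width (`resolution`): `1e-4` unbranched, `1e-3` random-ordered,
  `1e-4` near equilibrium.  Objective error from discretization is second
  order in the bin width near an interior optimum.
* MIP relative gap `1e-9`, so discretization, not the solver, dominates
  the error budget; solver feasibility artifacts are removed by polishing.
* Oracle grids: the brute-force check (`brute_force_optimum()`) evaluates
  the same independent-displacement lattice at 200 intervals per axis for
  the three-step mechanism and 25 per axis for the random-ordered one;
  agreement within two grid widths (relative) is the acceptance bar, and
  refinement from 100 to 400 intervals moves the oracle by well under 1%.
* The concentration-space scans exercised by the tests use a 9 x 9
  log-spaced substrate grid over `[0.1, 10]^2` at `P = 1`, `Keq = 2` --
  about a decade around the characteristic concentration, the range usually
  called physiological.
* Sampling defaults: 50 draws, burn-in 100, thinning 10, seed exposed
  everywhere; scans embed a provenance block (package version, solver,
  seed, resolution).

## Limitations

* Default discretization plans cover arbitrary unbranched mechanisms and
  branched mechanisms with two routes and at most two trunk steps (which
  includes all random-ordered Bi-Uni-type schemes); richer branching
  requires a user-supplied plan and products of more than two binary
  expansions, which the model builder deliberately refuses.
* The certified presolve relies on the closed-form/two-route inner
  evaluators; mechanisms with three or more routes fall back to the
  unreduced model with the generic LP inner solver, which is exact but
  slow.
* Activity coefficients, ionic strength and pH corrections to the standard
  Gibbs energy are out of scope; the temperature enters only through the
  `Keq` conversion (defaults 298.15 K, R = 8.314 J/mol/K).
* Optimality is with respect to maximal net flux per total enzyme at fixed
  concentrations; no claim is made about other objectives (transient
  times, intermediate pools) or about enzyme expression costs.
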