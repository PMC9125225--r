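---
title: "Unit structures, entropy-production decomposition, and the strengthened second law"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unit structures, entropy-production decomposition, and the strengthened second law}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unitssl)
```

## The model

`unitssl` works with finite, multi-dimensional continuous-time Markov
chains (CTMCs).  The state is a tuple $x = (x_1, \dots, x_N)$ over named
*coordinates* — physically separated subsystems, lattice positions,
chemical copy numbers — and the distribution obeys the master equation
$\dot p = K(t)\,p$ with the column convention $K[x, x']$ = rate from
$x'$ to $x$ (columns sum to zero, off-diagonals are non-negative).

The generator is not arbitrary: it is a sum of *reservoir* terms.  Each
reservoir $v$ can move only the coordinates in its **puppet set**
$P(v)$, and its rates may read the source state only through its
**leader set** $L(v) \supseteq P(v)$:
$$ K_{x x'}(t) \;=\; \sum_v L^{(v)}_{x_{P(v)},\,x'_{L(v)}}(t)\;
   \delta_{x_{-P(v)},\,x'_{-P(v)}}. $$
These *dependency constraints* are the extra physical knowledge the
package exploits: which subsystems can directly influence which others.
Multipartite processes (every transition moves a single coordinate) are
the special case of singleton puppet sets, but reservoirs with larger
puppet sets — simultaneous multi-coordinate transitions — are fully
supported (the lattice-walker example relies on them).

A **unit** is a coordinate set $\omega$ whose marginal evolves as a
self-contained CTMC, independent of the outside coordinates;
`is_unit()` tests this directly by checking that the grouped column
sums of $K$ do not depend on the outside source coordinates (tolerance
`1e-10`, sampled at the protocol's segment endpoints plus ten interior
points per segment; exact for constant rates).  A **unit structure**
$\mathcal N^*$ is a set of units that covers the coordinates and is
closed under non-empty intersection.  `validate_structure()` also
checks the well-formedness conditions used by the bound below: *flush*
(every simultaneous-transition coordinate set lies inside some unit),
no *vacuous* units (a unit all of whose coordinates are covered by
proper subunits), no *equivalent* nested pairs (for each nested pair
there are transitions moving a coordinate of the difference; the
structural check assumes full support), and *tightness* (every
reservoir affecting a unit has its whole leader set inside it).

The structure is conveniently drawn as a **dependency graph**: an edge
runs from a unit to each maximal proper subunit.  Roots, leaves, and
the height (longest chain, a leaf counting 1) come from
`build_dependency_graph()`.

## Entropy flow, entropy production, and their decomposition

With $k_B = 1$ and natural logarithms throughout, the entropy-flow (EF)
rate into the reservoirs and the entropy-production (EP) rate are the
standard Schnakenberg sums
$$ \langle\dot Q\rangle = \sum_{v,x\ne x'} L^{(v)}_{xx'} p_{x'}
   \ln\frac{L^{(v)}_{xx'}}{L^{(v)}_{x'x}}, \qquad
   \langle\dot\sigma\rangle = \sum_{v,x\ne x'} L^{(v)}_{xx'} p_{x'}
   \ln\frac{L^{(v)}_{xx'} p_{x'}}{L^{(v)}_{x'x} p_{x}} \;\ge\; 0 . $$
No local detailed balance is assumed; EF is temperature-normalized heat
only when it holds.  Rates with a positive forward entry but vanishing
reverse entry are rejected during validation ("weak reversibility") —
the log-ratios presuppose it.

A unit's EF sums only the reservoirs affecting it ($\nu(\omega)$,
`reservoirs_affecting()`); because no reservoir straddles a unit
boundary, EF is additive over disjoint units and extends to a signed
measure (unit differences are supported in `ef_rate()`).  A unit's EP
adds the derivative of the unit's own marginal entropy.  At the rate
level this needs the unit's own generator, which `ep_rate()` obtains by
restricting the system to the unit — only possible when the unit is
tight, and refused otherwise.  The *integrated* quantities need less:
`integrate_thermo()` computes
$$ \sigma_\omega = \Delta S_\omega + Q_\omega , $$
taking the endpoint marginal entropies from the solved snapshots and
quadrating only the EF rate, which contains no $\ln p$ and is smooth
even when the distribution has zeros (point-mass starts would make the
EP-rate integrand logarithmically singular at $t_i$; the entropy-change
form sidesteps this exactly rather than approximately).

For a unit structure, define the inclusion–exclusion sum of any
unit-indexed quantity over all $2^n - 1$ index subsets,
$f$ evaluated on each subset's intersection (empty intersections
contribute zero; duplicate intersections are counted once per index
subset, i.e. standard inclusion–exclusion).  The **in-ex information**
is
$$ I_{\mathcal N^*}(p) = \widehat{\sum_\omega} S_\omega \; - \; S_N , $$
which reduces to the mutual information for two disjoint units and to
the multi-information (total correlation) for any disjoint family, and
can be negative for overlapping units.  Two exact identities follow
from the structure (both are recomputed and checked on every report):
the global EF rate equals the in-ex sum of unit EF rates (each
reservoir is counted exactly once — the package verifies the counting
coefficients reservoir by reservoir), and therefore
$$ \sigma_N \;=\; \widehat{\sum_\omega}\,\sigma_\omega \;-\;
   \Delta I_{\mathcal N^*} . $$

## The strengthened second law

Dropping the in-ex sum of local EPs gives the bound
$$ \sigma_N \;\ge\; B_{\mathcal N^*} \;=\; -\Delta I_{\mathcal N^*}
   \;=\; I_{\mathcal N^*}(p_{t_i}) - I_{\mathcal N^*}(p_{t_f}) , $$
which depends only on the endpoint distributions and the dependency
constraints — not on the protocol.  It is guaranteed for dependency
graphs of height at most 2; `ssl_bound()` returns the value for taller
structures too but flags it as not guaranteed.  $B$ can be negative, in
which case the conventional second law is the better statement; the
report records its sign and the realized slack.

### A note on the inclusion–exclusion convention

For structures in which a leaf unit sits below several roots, the
convention matters.  Take the walker structure
$\{\{1\},\{2\},\{1,2,3\},\{A,1\},\{B,2\}\}$: the leaf $\{1\}$ is the
pairwise intersection of three different index pairs *and* the triple
intersection of $\{1\},\{1,2,3\},\{A,1\}$.  Standard per-index-subset
inclusion–exclusion gives $S(1)$ the net coefficient
$1 - 3 + 1 = -1$, so the in-ex information reduces to
$$ I = S(A\mid 1) + S(B\mid 2) - S(A,B\mid 1,2,3) \;\ge\; 0 , $$
and the bound $-\Delta I$ vanishes whenever the stores decouple given
the position at both endpoints.  Truncating the expansion at second
order (as is sometimes done informally) would give the coefficient
$-2$ and an apparent bound of $2\ln L$ for the uniformizing walker —
but those truncated coefficients count the walk reservoirs zero times
instead of once in the EF decomposition, breaking the identities above.
The package therefore uses the full expansion everywhere; the walker
acceptance check records the honest (near-zero) value.

## Feedback control

A measurement channel $p(c\mid x)$ (no back-action) prepares
$p(c, x) = p(c\mid x)\,p^\dagger(x)$ on an extended space whose first
coordinate is a frozen controller: no reservoir moves it, every
reservoir may read it (`extend_with_controller()`).  Lifting each unit
by the controller gives a structure whose bound $B_{\mathcal M^*}$
satisfies, exactly,
$$ B_{\mathcal M^*} - B_{\mathcal N^*} =
   \Delta\Big[\widehat{\sum_\omega} I(X_\omega; C)\Big]
   - \Delta I(X_N; C) , $$
verified to `1e-10` in the tests.  When two original units are
disjoint the bare controller must be added to the lifted structure for
closure; it sits at the bottom of every intersection chain, so its
in-ex contributions cancel and the bound is unchanged (also tested).
With a uniform Hamiltonian at both endpoints and all reservoirs at one
temperature ($k_B T = 1$), `extractable_work_bound()` reports both the
structure-aware bound $\Delta[\widehat\sum_\omega S(X_\omega\mid C)]$
and the conventional $\Delta S(X_N\mid C)$; the work interpretation
additionally assumes rates tied to a Hamiltonian by local detailed
balance, which the information-theoretic quantities themselves do not
need.

## Numerical choices

* **Enumeration.** Joint states are enumerated lexicographically with
  the last declared coordinate varying fastest; all matrices and
  vectors use this fixed order.
* **Integration.** Constant and piecewise-constant protocols are
  propagated by matrix exponentials per protocol segment (the default
  and recommended mode); arbitrary time-dependent rates fall back to
  `deSolve::ode` (`lsoda`, relative tolerance `1e-8`).  Probability
  conservation is asserted to `1e-8` at every grid point.  This is a
  desk-scale tool: dense matrices, with a warning above 20&nbsp;000
  joint states.
* **Quadrature.** Integrated EF uses the composite trapezoid rule with
  one Richardson refinement pass, segment by segment (the integrand
  jumps at protocol breakpoints); the error estimate compares the
  half- and quarter-grid extrapolations and `integrate_thermo()`
  refuses to report if it exceeds the tolerance (default `1e-6`),
  suggesting a finer grid instead of silently degrading.
* **Tolerances.** Structural identities (generator columns,
  marginal-rate independence, compatibility) use `1e-10`; map and
  normalization checks `1e-9`; consistency of conditional maps `1e-8`.
  Renormalization of distributions is never silent.
* **Degenerate inputs.** $0\ln 0 = 0$ in all entropy sums; zero rate
  matrices are valid (frozen coordinates); one-way transitions are
  rejected at validation time rather than producing infinities.
* **Search.** `enumerate_height2_structures()` does plain exhaustive
  subset search (at most 12 coordinates, bounded family budget with a
  partial-result flag) — no Möbius-function shortcuts are attempted at
  desk scale.

## The packaged examples and the random-system generator

* `build_fig1()`: four binary subsystems in a multipartite sensing
  chain — an autonomous external medium read by two receptor
  subsystems, one of which is read by a memory.  Its structure
  $\{\{1,2,3\},\{3,4\},\{3\}\}$ has two roots, one leaf, height 2, and
  is tight.  Rates are seeded draws from $U(0.2, 1.2)$ — full support,
  hence weakly reversible.
* `build_example2()`: three binary subsystems with
  $A^* = \{\{1,2\},\{2\},\{2,3\}\}$, started with $x_1 = x_3$ uniform
  and $x_2$ independent uniform, so $S = 2\ln 2$ and $I = \ln 2$.  The
  endpoint conditional must factorize as
  $p(x_1\mid x_2)\,p(x_3\mid x_2)\,p(x_2)$; since only the endpoints
  are constrained, the builder realizes it with a two-stage
  piecewise-constant protocol (uniformize $x_2$ while $x_1, x_3$
  jiggle conditionally; then freeze $x_2$ and relax $x_1, x_3$ onto
  seeded target conditionals) and *verifies* the factorization
  residual (`1e-4`) rather than assuming it.  Each stage lasts 20 time
  units at $O(1)$ rates, so mixing residuals are far below tolerance.
  The final in-ex information vanishes and the entropy production is
  bounded below by $\ln 2$.
* `build_walker()`: a walker on an $LN_{cg} \times LN_{cg}$ periodic
  lattice with within-square coordinates, a coarse-grained square
  index updated deterministically at boundary crossings (simultaneous
  two-coordinate transitions — not multipartite), and two nutrient
  stores reading one position coordinate each.  Default acceptance
  size $L = 2$, $N_{cg} = 4$, binary stores: 256 joint states,
  integrated to $t = 30$ (the slowest relaxation rate is
  $\approx 0.6$, so endpoint residuals are $\ll 10^{-3}$).
* `random_unit_system()` realizes *any* unit structure as a
  multipartite system: one reservoir per coordinate whose leader set is
  the smallest containing unit, with strictly positive seeded rates.
  This is the workhorse of the Monte-Carlo suites: 100 systems for the
  decomposition identities and 200 for the inequality suite
  (3–4 coordinates of cardinality 2–3, constant protocols integrated
  to $t = 2$ on 200–300-step grids), sizes chosen so the whole suite
  runs in well under a minute while the realized slacks
  ($\sigma_N - B \gtrsim 0.1$) dwarf the quadrature error.

What the generator emulates — and what it does not: seeded random
structure-conforming rate matrices probe the *identities and
inequalities*, which hold for any CTMC with the declared dependency
structure.  They do not emulate features of real biophysical networks
such as sparse transition graphs, detailed-balance restrictions,
metastability, or rate heterogeneity over many decades; passing suites
therefore certify the bookkeeping and the bounds, not the realism of
any particular biological parameterization.

## Known limitations

* Verifying that an arbitrary conditional map is *implementable* by a
  structure-conforming rate matrix is a generator-embedding existence
  problem; `conditional_consistency_check()` tests only the stated
  necessary condition (each unit's marginal map reads only the unit's
  initial coordinates) and says so in its result.
* Stochastic trajectory (Gillespie) simulation and stationary-state
  solvers are out of scope; long-time integration stands in.
* Dense desk-scale linear algebra only; no sparse or GPU paths.
* The height-2 representation of an arbitrary CTMC is found by
  exhaustive search, not by a constructive recipe: collapsing all
  non-root coordinates into one overarching unit is not in general
  guaranteed to produce a unit, so the package does not attempt it.
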