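---
title: "Germ-soma specialization as constrained fitness optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Germ-soma specialization as constrained fitness optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyopt)
```

## The model

A colony of $N$ cells divides its effort between two fitness components:
fecundity (reproduction) and viability (survival, proxied in Volvocalean
green algae by flagellar motility). Cell $i$ contributes fecundity
$b_i \in [0, b_i^{\max}]$ and viability $v_i$, linked by a strictly
decreasing trade-off curve $\varphi_i$ with $\varphi_i(0) = v_i^{\max}$ and
$\varphi_i(b_i^{\max}) = 0$: investing in reproduction costs survival. Group
levels are additive, $B = \sum_i b_i$ and $V = \sum_i v_i$, and colony
fitness is the Cobb-Douglas form

$$W = B^{\alpha} V^{\beta}, \qquad \alpha, \beta > 0,$$

so both components are essential ($W = 0$ iff $B = 0$ or $V = 0$) and the
exponents weigh their relative 'importance' — $\beta$ plays the role of a
generation time $T$ in the special case $W = B V^T$. The environment
supplies a budget through a linear resource constraint

$$k_1 B + k_2 V \le C,$$

with per-unit production costs $k_1, k_2$ and available resource $C$. The
optimization problem is to maximize $W$ over all per-cell allocations
subject to the box bounds, the trade-offs, and the budget. Two trade-off
modes are supported: *equality* ($v_i = \varphi_i(b_i)$, every cell exactly
on its curve) and *inequality* ($0 \le v_i \le \varphi_i(b_i)$, viability
free downward). A cell is *germ-specialized* when $b_i = b_i^{\max}$,
*soma-specialized* when $v_i = v_i^{\max}$, and a generalist otherwise.

Curvature is the central life-history parameter: concave curves describe
small colonies with low initial reproduction costs, convex curves large
colonies with high initial costs, linear curves the boundary case. The
parametric families in `tradeoff()` are fully determined by
$(v^{\max}, b^{\max})$; custom curves are accepted as functions and
validated by sampling.

## Solution regimes

The solver classifies every instance into one of the regimes that structure
the solution set (`classify_regime()`):

* **Case 1 / 1'** (resource slack): the resource-free optimum — concave
  first-order condition, slope-sorted linear greedy, or convex bang-bang
  enumeration, by curvature — costs no more than $C$, so the budget is
  irrelevant. The boundary resource level is reported as
  `C_unconstrained`.
* **Case 2 / 2'** (level set): the budget binds and the pair
  $B^* = C\alpha/(k_1(\alpha+\beta))$, $V^* = C\beta/(k_2(\alpha+\beta))$
  is attainable under the trade-offs. The optimum
  $W^* = (\alpha/k_1)^\alpha (\beta/k_2)^\beta (C/(\alpha+\beta))^{\alpha+\beta}$
  is closed-form (`wstar_case2()`), and the optimal set — everything on the
  level-set pair — is explored by seeded sampling
  (`sample_solution_set()`).
* **Case 3 / 3'** (resource surface): the budget binds but the level set is
  out of reach; optima sit where the budget surface meets the attainable
  region, at the total fecundity closest to $B^*$.
* **Case 0** (equality mode only): even the cheapest on-curve allocation
  costs more than $C$ — the environment cannot sustain the colony.

Attainability is decided with *viability envelopes*: at fixed total
fecundity $T$, `vmax_at()`/`vmin_at()` give the largest and smallest group
viability the trade-offs allow. The upper envelope is a water-filling
problem (equalize marginal slopes $|\varphi_i'|$ across cells, clipped to
the boxes); because the quadratic families have piecewise-linear
multiplier-to-allocation maps, it is solved exactly from a sorted
breakpoint table, with bisection reserved for custom curves. The lower
envelope of concave/linear cells is a concave minimization, exact by vertex
enumeration (every cell at a box face except at most one); convex cells
contribute a smooth convex subproblem handled by the same
marginal-equalization machinery. Colonies mixing convex cells with others
are handled by enumerating the convex cells' specialization patterns (each
at $0$ or $b^{\max}$, at most one interior) around those subproblems.

The surface solver maximizes
$W(T) = T^{\alpha}\min\{v^{\max}(T), (C - k_1 T)/k_2\}^{\beta}$ over total
fecundity. Writing it this way matters: with convex cells the optimum can
leave part of the budget unspent (the envelope, not the budget, binds), a
situation the concave/linear closed-form narrative never meets. Candidates
are a 161-point grid, the envelope/budget crossings (kinks of $W$), a local
`optimize()` refinement, and bisected feasibility boundaries; the per-cell
allocation is reconstructed from the envelope solution, interpolating
between the lower and upper envelope allocations when the surface viability
lies strictly between them.

## Worked example and scans

The bundled three-cell example (`worked_example_model()`) has concave
trade-offs $v_1 = 6 - 3b_1^2$, $v_2 = 4 - b_2^2$, $v_3 = 5 - 2b_3^2$,
$\alpha = \beta = 1$, $k_1 = 2$, $k_2 = 3$. Scanning $C$
(`scan_resource()`) classifies a coarse grid (default 81 points — a regime
sliver narrower than the grid step could be missed; this example's regimes
are all wider than 1.8 resource units) and bisects every regime change to a
requested tolerance, also bisecting specialization-pattern changes (a
cell's optimal fecundity hitting or leaving its bound) inside single-point
regimes. In inequality mode the regimes are provably ordered — level-set at
poor, surface at intermediate, slack at rich environments
(`quality_ordering_check()` verifies the ordering and the
$\lambda$-scaling argument behind it); in equality mode the scan instead
walks empty domain, surface, level-set, surface again, slack.

## Numerical choices

* Specialization labels use a relative tolerance of $10^{-6}$ of the
  corresponding bound; feasibility checks default to an absolute
  $10^{-8}$.
* Boundary-of-regime inputs resolve to the lower-numbered case, making
  classification deterministic at thresholds.
* Enumeration ties are kept when within $10^{-9}$ relative fitness;
  duplicate strategy *vectors* are removed but permuted variants of
  identical cells are reported individually (the convex slack regime of
  three identical cells genuinely has three tied optima). Tie lists are
  ordered lexicographically for reproducibility.
* The brute-force oracle (`brute_force_oracle()`) grids fecundity over the
  box; in inequality mode the optimal viability given $b$ is computed
  exactly (trade-off viability capped by the remaining budget), so only $b$
  is discretized. Optional nested refinement passes re-grid a shrinking box
  around the incumbent, keeping the box width while fitness still improves
  so the search can crawl along a budget ridge before shrinking.
* Level-set samples blend a random slice point towards an envelope
  allocation (or a qualifying mixture of two) until the viability level is
  hit, which spreads samples along connected arcs of the optimal set;
  connected components are counted by single-linkage clustering at radius
  $0.05\,\max_i b_i^{\max}$. Sampling is seeded (default 20180808) and
  restores the caller's RNG state.
* Degenerate inputs are rejected at validation: non-positive $\alpha$,
  $\beta$, $k_1$, $k_2$, $C$, $v^{\max}$ or $b^{\max}$, and more than 20
  cells (the convex pattern enumeration is exponential in the cell count).
  The identical-linear surface closed form refuses the degenerate cost
  ratio $k_1 = k_2 \gamma$, where that regime cannot occur.

## The random-colony generator

`random_colony()` draws test colonies of a requested curvature class:
per-cell $v^{\max} \sim U[1, 10]$ and $b^{\max} \sim U[0.5, 3]$ (linear
colonies are redrawn until all slopes are distinct, i.e. strongly
differentiated), exponents log-uniform on $[0.4, 2.5]$, costs
$U[0.5, 3]$, and a resource level drawn as a $U[0.15, 1.25]$ fraction of
the maximal conceivable usage $k_1\sum b^{\max} + k_2\sum v^{\max}$ so that
draws land in every regime. These ranges are fixed once as plausible orders
of magnitude for the dimensionless model; they emulate the *structure* of
the theory (curvature classes, heterogeneous cells, binding or slack
budgets), not any measured Volvocalean data — no empirical noise,
measurement error, or phylogenetic structure is modelled, so passing tests
demonstrate internal mathematical consistency, not fit to real colonies.

## Limitations

* Group viability is additive; non-additive forms (plausible for motility
  interactions) are outside the implementation.
* For mixed-curvature colonies the classification and surface solver are
  numeric; no analytic optimality guarantees are claimed beyond agreement
  with the grid oracle at test sizes.
* Uniqueness of the heterogeneous-linear optimum is only asserted under
  strong differentiation (distinct slopes); equal-slope groups form
  composite cells whose internal split is reported by one proportional
  representative.
* The scans are single-axis (resource level); two-parameter phase diagrams
  are out of scope.

## Problem sizes

All computations in the test-suite and the reproduction script are
desk-scale: colonies of 2-3 cells, 101-point (up to 601-point for
two-cell colonies) oracle grids with up to 25 refinement passes, 161-point
surface scans, and bisections to $10^{-3}$ resource units.
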