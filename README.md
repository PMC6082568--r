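# colonyopt

Constrained-optimization model of germ–soma division of labor in a cell
colony, for theoretical evolutionary biologists studying the emergence of
functional specialization (the Volvocalean green algae lineage being the
canonical system).

## The model

A colony of *N* cells allocates per-cell fecundity *b<sub>i</sub>* and
viability *v<sub>i</sub>* under three constraints:

* a strictly decreasing **trade-off curve** per cell,
  *v<sub>i</sub>* = φ<sub>i</sub>(*b<sub>i</sub>*) (equality mode) or
  *v<sub>i</sub>* ≤ φ<sub>i</sub>(*b<sub>i</sub>*) (inequality mode), with
  φ<sub>i</sub>(0) = *v<sub>i</sub><sup>max</sup>* and
  φ<sub>i</sub>(*b<sub>i</sub><sup>max</sup>*) = 0 — curvature (concave /
  linear / convex) tracks colony size and initial reproduction cost;
* box bounds 0 ≤ *b<sub>i</sub>* ≤ *b<sub>i</sub><sup>max</sup>*;
* a linear **resource budget** *k*₁*B* + *k*₂*V* ≤ *C* on the group levels
  *B* = Σ*b<sub>i</sub>*, *V* = Σ*v<sub>i</sub>*.

Colony fitness is maximized in the Cobb–Douglas form

> *W* = *B*<sup>α</sup> · *V*<sup>β</sup>,  α, β > 0,

where the exponents weigh the 'importance' of reproduction vs. survival
(β maps to a generation time *T* in the special case *W* = *BV*<sup>T</sup>).
A cell with *b<sub>i</sub>* = *b<sub>i</sub><sup>max</sup>* is
germ-specialized; with *v<sub>i</sub>* = *v<sub>i</sub><sup>max</sup>*,
soma-specialized.

The package provides the closed-form optima where they exist (level-set
regime fitness, identical-linear colonies, the concave first-order
condition, convex bang-bang enumeration, slope-sorted heterogeneous-linear
optima), the complete solution-regime taxonomy (resource-slack, level-set,
resource-surface, empty-domain — for both trade-off modes), attainable
viability envelopes, a brute-force grid oracle, seeded sampling of
connected optimal sets, and bisection scans that locate regime and
specialization thresholds along the resource axis.

## Worked example

The bundled three-cell colony has concave trade-offs
*v*₁ = 6 − 3*b*₁², *v*₂ = 4 − *b*₂², *v*₃ = 5 − 2*b*₃², with
α = β = 1, *k*₁ = 2, *k*₂ = 3:

```r
library(colonyopt)
m   <- worked_example_model("inequality", C = 25)
fit <- solve_colony(m)
fit
#> colony solution [CASE_3P, inequality mode]
#>   W* = 23.0299 at B* = 4.12453, V* = 5.58365
#>   optimal set: single_point (1 representative strategy), 1 component(s)
#>   specialization (first strategy): 1 germ, 0 soma, 2 unspecialized
coef(fit)
#>         B         V         W
#>  4.124530  5.583647 23.029918
```

At *C* = 25 the budget binds and the level-set pair is unattainable
(surface regime, `CASE_3P`): the optimum consumes the whole budget at total
fecundity 4.12, and the second cell — whose fecundity is cheapest in
viability terms — specializes in germ while the others stay generalists.
With ample resources the budget stops mattering:

```r
classify_regime(worked_example_model("inequality", 40))
#> regime CASE_1P (inequality mode); resource-slack boundary C* = 36.0553
#>   level-set targets: B* = 10, V* = 6.66667 (not attainable)
```

`scan_resource(m, 5, 45, tol = 1e-3)` maps the full picture: level-set
regime below *C* ≈ 18.3, surface regime up to *C* ≈ 36.06 (with the
germ-specialization of cell 2 switching off at *C* ≈ 30.3), slack regime
above. A thin command-line wrapper is installed as `colonyopt`
(`colonyopt solve --config model.json --out report.json`; also `classify`,
`scan`, `oracle`, `sample`, `fixtures`).

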