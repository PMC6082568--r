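Package: colonyopt
Title: Germ-Soma Specialization in Cell Colonies Under a Resource Constraint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained-optimization model of germ-soma division of labor in a
    cell colony. Colony fitness W = B^alpha * V^beta is maximized over per-cell
    fecundity and viability allocations subject to strictly decreasing
    viability-fecundity trade-off curves (convex, linear, concave or custom,
    optionally different for every cell), box bounds, and a linear resource
    budget k1*B + k2*V <= C. Provides closed-form optima where they exist,
    attainable-viability envelopes, the complete solution-case taxonomy
    (resource-slack, level-set, resource-surface and empty-domain regimes, for
    both equality and inequality trade-off modes), a brute-force grid oracle,
    optimal-set sampling, and bisection scans that locate regime and
    specialization-pattern thresholds along the resource axis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
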