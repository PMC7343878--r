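Package: tipcascade
Title: Threshold Models of Social Tipping on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling social tipping with threshold models of
    collective behaviour. Implements the classic Granovetter recursion and
    its refinement into certainly acting, contingent and never-acting
    groups, a microscopic cascade simulator on Erdos-Renyi (or arbitrary)
    networks with a fractional activation threshold, analytic emergent
    threshold distributions (exact binomial, Poisson-limit and
    incomplete-gamma forms), and fixed-point, saddle-node, cusp and
    hysteresis analysis of the resulting low-dimensional map.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
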