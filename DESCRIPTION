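Package: yieldopt
Title: Yield Optimization, Elementary Flux Vectors and Strain Design for
    Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of metabolic networks with a focus on
    yield (as opposed to rate) optimization. Maximizes linear-fractional flux
    ratios such as product-per-substrate yields under arbitrary linear
    constraints by transformation to a linear program over an auxiliary
    polyhedron, with explicit handling of suprema that are approached but not
    attained. Enumerates elementary flux modes and elementary flux vectors of
    flux cones and flux polyhedra, characterizes rate- and yield-optimal
    solution sets in terms of these generators, computes phase planes
    (production envelopes) and yield spaces both exactly via generator hulls
    and approximately via boundary sampling, performs flux coupling analysis,
    and derives constrained minimal cut sets for growth-coupled strain design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    boot,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
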