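# yieldopt

Yield optimization, elementary flux vectors and strain design for
constraint-based metabolic models.

## What problem this solves

Flux-balance analysis (FBA) maximizes a *rate* — a linear objective
`c'x` — over the feasible flux set

```
P = { x | N x = 0,  lb <= x <= ub,  G x <= h }
```

of a metabolic network with stoichiometric matrix `N`. Biotechnology,
however, cares at least as much about *yields*: ratios

```
Y(x) = c'x / d'x
```

of product formation to substrate uptake, defined where `d'x > 0`. A yield
is scale-invariant and nonlinear, and once the model carries inhomogeneous
constraints (uptake caps, maintenance demands), rate-optimal and
yield-optimal flux distributions genuinely differ — running FBA at fixed
substrate uptake does not find the best yield. `yieldopt` is for modelers
and strain designers who need to:

* maximize yields under arbitrary linear constraints, as a
  linear-fractional program (LFP) solved via an equivalent LP over the
  auxiliary polyhedron `P' = {(x', t) | A x' <= t b, d'x' = 1, t >= 0}`,
  with explicit detection of suprema that are approached but never
  attained at finite fluxes;
* enumerate elementary flux modes (EFMs) and elementary flux vectors
  (EFVs) of small networks and use them to characterize rate- and
  yield-optimal solution sets (optimal generators plus undefined-yield
  generators such as the zero vector and internal cycles);
* compute phase planes / production envelopes and yield spaces, exactly as
  generator hulls or approximately by boundary sampling;
* run flux coupling analysis (extremal flux ratios as LFPs);
* derive constrained minimal cut sets — smallest knockout sets removing
  all undesired behaviors while preserving a desired one — for
  growth-coupled production designs.

Results come back as tibbles (or objects carrying them) with
`tidy()`/`glance()`/`autoplot()` methods, so everything composes with the
usual dplyr/ggplot2 workflow.

## Worked example

The package ships a six-metabolite, eleven-reaction example network
(substrate uptake R1, biomass R4, product R3, byproduct Q, and an internal
cycle R7/R10/R11) with six analysis scenarios. Under scenario S3 (uptake
cap `r1 <= 10` plus capacity cap `r5 <= 5`):

```r
library(yieldopt)
library(dplyr)

s3 <- scenario("S3")
glance(maximize_rate(s3$poly, "R4", model = s3$model))
#> # A tibble: 1 × 2
#>   status  objective_value
#>   <chr>             <dbl>
#> 1 optimal             7.5

specB <- yield_spec("R4", "R1", model = s3$model)   # biomass yield r4/r1
glance(maximize_yield(s3$poly, specB))
#> # A tibble: 1 × 4
#>   status           optimal_yield attained t_star
#>   <chr>                    <dbl> <lgl>     <dbl>
#> 1 optimal_attained             1 TRUE        0.2
```

The maximal biomass *rate* is 7.5 (at full uptake `r1 = 10`), while the
maximal biomass *yield* is 1 — reachable only at uptake rates `r1 <= 5`:
the rate-optimal strain is not yield-optimal. The generator table for
scenario S2 (uptake cap only) shows why:

```r
gen <- annotate_generators(enumerate_efvs(scenario("S2")$poly),
                           rate = "R4", spec = specB,
                           model = example_network())
tidy(gen) |> select(id, kind, rate, yield, yield_status)
#> # A tibble: 7 × 5
#>   id    kind       rate yield yield_status
#>   <chr> <chr>     <dbl> <dbl> <chr>
#> 1 g1    bounded      10   1   defined
#> 2 g2    bounded       5   0.5 defined
#> 3 g3    bounded      10   1   defined
#> 4 g4    bounded       0   0   defined
#> 5 g5    bounded       0   0   defined
#> 6 g6    bounded       0  NA   undefined
#> 7 g7    unbounded     0  NA   undefined
```

Seven elementary flux vectors: five pathway vertices scaled to the uptake
bound, the zero vector (g6) and the unbounded internal cycle (g7), the
last two with undefined yield. Every yield-optimal flux distribution is a
convex sum of g1/g3 (yield 1) and g6 plus a multiple of g7.

A strong-coupling strain design — eliminate every behavior with product
yield below 0.5, keep a growing one — is solved by two knockouts:

```r
des <- design_spec(data.frame(
  quantity = c("yield:R3/R1", "rate:R4"),
  op = c("<", ">"), value = c(0.5, 0),
  region = c("target", "desired")
))
gen1 <- partition_generators(enumerate_efms(example_network()), des,
                             example_network())
compute_mcs(gen1, max_size = 3)
#> # A tibble: 4 × 2
#>   reactions  size
#>   <list>    <int>
#> 1 <chr [2]>     2
#> 2 <chr [2]>     2
#> 3 <chr [3]>     3
#> 4 <chr [3]>     3
```

with `{R5, R8}` among the two smallest cut sets; `evaluate_design()`
re-enumerates the mutant and certifies that its minimum product yield over
substrate-consuming flux is 0.5.

Models load from a native JSON format, TSV stoichiometry tables or SBML
L3/fbc (`load_model()`); a thin command-line wrapper over the same
functions lives at `inst/cli/yieldopt.R`. The methods vignette
(`vignettes/yield-optimization.Rmd`) documents the mathematics, the
numerical choices and the limitations.

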