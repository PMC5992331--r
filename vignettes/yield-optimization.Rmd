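---
title: "Yield optimization, elementary flux vectors and strain design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Yield optimization, elementary flux vectors and strain design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldopt)
library(dplyr)
```

## The problem: rates versus yields

Constraint-based models describe a metabolic network by its stoichiometric
matrix $N \in \mathbb{R}^{m \times n}$ ($m$ internal metabolites, $n$
reactions). A flux distribution $r$ is feasible when it satisfies steady
state $N r = 0$, flux bounds $r_{lb} \le r \le r_{ub}$ (with $r^{lb}_i = 0$
for irreversible reactions), and optionally extra linear constraints
$G r \le h$. Collected into a single system $A x \le b$, the feasible set is
the *flux polyhedron* $P$; with only steady state and irreversibility it is
the *flux cone*.

Flux-balance analysis (FBA) maximizes a linear *rate* objective $c^\top x$
over $P$: an ordinary LP. A *yield* is a ratio of two such forms,

$$Y(x) = \frac{c^\top x}{d^\top x},$$

typically product formation over substrate uptake, evaluated where
$d^\top x > 0$. Yields are scale-invariant ($Y(\lambda x) = Y(x)$), so they
measure conversion efficiency rather than speed. Maximizing $Y$ is a
*linear-fractional program* (LFP), not an LP, and rate- and yield-optimal
flux distributions genuinely differ once inhomogeneous constraints are
present: fixing the substrate uptake at its maximum and running FBA does
*not* generally find the best yield. This package implements yield
optimization under arbitrary linear constraints, together with the
generator-based (elementary flux mode / elementary flux vector) analysis of
the optimal solution sets, phase-plane and yield-space computation, flux
coupling analysis, and cut-set-based strain design built on top of it.

## The LFP as an LP over an auxiliary polyhedron

The denominator-normalizing change of variables $x' = x / d^\top x$,
$t = 1 / d^\top x$ turns the LFP into the LP

$$\max\, c^\top x' \quad \text{over} \quad
P' = \{(x', t) \mid A x' \le t\, b,\; d^\top x' = 1,\; t \ge 0\},$$

with the same optimal value; any solution with $t > 0$ maps back to
$x = x'/t \in P$. [build_auxiliary()] constructs $P'$; [maximize_yield()]
solves the LP and post-processes:

* infeasible LP → the domain $d^\top x > 0$ is empty;
* unbounded LP → the yield itself is unbounded (usually an ill-posed model
  in which product can be made without the accounted substrate);
* optimum with $t^* > 0$ → the maximum is attained at $x'/t^*$;
* optimum with $t^* = 0$ → the optimizing vertex is a recession direction.
  The supremum may still be attained elsewhere: we first maximize $t$ over
  $P'$, fix a probe $\tilde t = \min(1, t_{\max}/2)$, re-solve with
  $t = \tilde t$, and declare the optimum attained iff the probe reaches
  the same objective (relative tolerance $10^{-7}$). Otherwise the result
  is `optimal_not_attained` with the recession direction as the limiting
  certificate. The probe value is a numerical stand-in for "a positive $t$
  away from zero"; any value in $(0, t_{\max})$ gives the same verdict in
  exact arithmetic.

All LPs are solved by a dense two-phase simplex with Bland's anti-cycling
rule implemented in the package. A hand-written solver was chosen because
the analyses need a trustworthy three-way status — `optimal`, `infeasible`,
`unbounded` — as a *result*, not an error condition: unbounded rate optima
on cones and the attainment test both hinge on it. The test suite
cross-checks the solver against an independent simplex implementation on
random bounded problems. Problems here have tens of variables, where a
dense tableau is entirely adequate.

## Generators: elementary flux modes and vectors

Every polyhedron is the sum of a polytope (convex hull of *bounded*
generators $v_i$) and its recession cone (conical hull of *unbounded*
generators $u_j$). Elementary flux vectors (EFVs) are the canonical such
generators: the conformally non-decomposable vectors of the homogenized
cone $\{(x,t) \mid Ax \le t b, t \ge 0\}$. On a flux cone they reduce to
the classical elementary flux modes (EFMs). [enumerate_efvs()] computes
them by double description on a lifted cone in which reversible fluxes are
split into forward/backward parts and every inequality row gets a
nonnegative slack, so that the lifted cone is a subspace intersected with
the nonnegative orthant and elementarity becomes plain support minimality.
Rows are scaled to integers and rays are reduced by their gcd after every
combination step, so fixture-scale generators come out as exact small
rationals. Bounded generators are reported normalized to $t = 1$, unbounded
ones as smallest-integer direction vectors. Enumeration is guarded
(`max_dim`, `max_rays`): it is a small-network tool by nature, and the
package refuses rather than thrash on genome-scale inputs, where generator
counts run into the hundreds of thousands.

Two structure theorems drive the analysis of optima:

* **Attainment.** With $Y$ bounded on a nonempty domain, the maximum fails
  to be attained precisely when *every* bounded generator has a defined
  yield and the best of them is strictly beaten by an unbounded generator
  ([yield_attained()]). Generators with undefined yield
  ($c^\top x = d^\top x = 0$: the zero vector, internal cycles) guarantee
  attainment when present among the bounded ones, because adding them to
  any flux vector never changes its yield.
* **Optimal solution sets.** When the maximum is attained, a point is
  yield-optimal iff it is a convex sum of bounded generators that are
  yield-optimal ($I^*$) or undefined-yield ($I_u$), plus a conical sum of
  unbounded generators that are yield-optimal ($J^*$) or undefined-yield
  ($J_u$), with strictly positive total weight on the starred classes
  ([classify_optimal()], [is_yield_optimal()]). The strict positivity is
  tested as $\ge \varepsilon$ with $\varepsilon = 10^{-9}$ in the
  membership LP, since strict inequalities are not LP-expressible. The
  rate-optimal analogue ([rate_optimal_set()]) is the classical result that
  optimal solutions of a bounded LP are convex sums of optimal polytope
  generators plus arbitrary recession directions.

## The built-in example network

The package ships a six-metabolite, eleven-reaction network
([example_network()]) with substrate uptake R1, biomass synthesis R4,
product excretion R3, a byproduct route to Q, and a thermodynamically
infeasible (deliberately retained) internal cycle R7/R10/R11. Six scenarios
([scenario()]) add constraints stepwise: the bare cone (S1), an uptake cap
$r_1 \le 10$ (S2), a capacity cap $r_5 \le 5$ (S3), and three engineering
variants (S4: knockout of R5; S5: knockouts of R5 and R8; S6: S5 plus an
enforced $r_6 \ge 3$).

```{r scenarios}
s3 <- scenario("S3")
maximize_rate(s3$poly, "R4", model = s3$model)$objective_value
specB <- yield_spec("R4", "R1", model = s3$model)
glance(maximize_yield(s3$poly, specB))
```

The rate optimum (7.5, at full uptake) and the yield optimum (1, requiring
$r_1 \le 5$) disagree here — the motivating phenomenon. The generator view
makes the structure explicit:

```{r generators}
tidy(annotate_generators(enumerate_efvs(scenario("S2")$poly),
                         rate = "R4", spec = specB,
                         model = example_network())) |>
  select(id, kind, rate, yield, yield_status)
```

## Phase planes and yield spaces

A phase plane (production envelope) is the projection of $P$ onto two rate
axes; a yield space is its image under two yields sharing a denominator.
The yield space is convex — the yield of a convex combination is a convex
combination of the yields, with a reweighted coefficient
$\lambda' = \lambda d^\top y / ((1-\lambda) d^\top x + \lambda d^\top y)$ —
so both objects are convex hulls of mapped generators
([hull_from_generators()]); generators with undefined yield have no
yield-space image, while they project into the phase plane (onto the
origin, for the cycle and the zero vector). For models too large to
enumerate, both boundaries are sampled ([sample_phase_plane()],
[sample_yield_space()]): the range of axis 1 is split into $n$ intervals
(inclusive endpoints, $n + 1$ slices; default $n = 20$, which resolves
these low-dimensional shadows well in practice) and axis 2 is minimized and
maximized per slice — for yield spaces with every LP running over the
auxiliary polyhedron, which is what makes the two samplers structurally
identical. Slices that hit a vertex of the range exactly and come back
infeasible from round-off are retried with a $10^{-9}$-relative inward
nudge. Points are also returned as a closed polygon trace (lower branch
left-to-right, upper branch right-to-left) for direct plotting via
`autoplot()`. Interval endpoints that are only approached, never attained
(half-open fiber segments), are flagged through the attainment test rather
than symbolically ([map_pp_point_to_ys()]).

```{r spaces, fig.width = 5, fig.height = 4}
s1 <- scenario("S1")
ys <- sample_yield_space(s1$poly, specB,
                         yield_spec("R3", "R1", model = s1$model), n = 20)
autoplot(ys)
```

## Flux coupling

Extremal flux ratios $r_i / r_j$ over the feasible set (with $r_j > 0$) are
LFPs with unit numerator and denominator ([ratio_bounds()]). Pairs classify
as fully coupled (min = max, finite nonzero), partially coupled (distinct
finite nonzero bounds), directionally coupled (exactly one degenerate
bound) or uncoupled ([classify_all()]). Degenerate bounds are *tagged*
(`"zero"` below $10^{-9}$, `"infinite"` for unbounded suprema), never
approximated by large numbers. Reversible denominators are analyzed per
orientation (the forward orientation is imposed for the query); pairs whose
denominator reaction is blocked are reported as `blocked` rather than
forced into a coupling class, since no ratio exists there.

## Strain design with constrained minimal cut sets

A design ([design_spec()]) partitions flux behaviors by linear constraints
on rates and yields into a *target* region (to eliminate) and a *desired*
region (to preserve); generators fall into target/desired/neutral
([partition_generators()]). Yield constraints are inapplicable to
undefined-yield generators (they cannot place the zero vector or a cycle
into a region); constraints use explicit strict/non-strict operators, and
generators exactly on a boundary line satisfy only the non-strict side —
so with a strict "below the line" target, boundary behavior counts as kept.
A constrained minimal cut set is an inclusion-minimal knockout set hitting
every target generator's support (a knockout removes both directions of a
reversible reaction) while leaving at least one desired generator's support
untouched. [compute_mcs()] enumerates them exactly with a Berge-style
incremental transversal construction under a cardinality cap — appropriate
at the scale where generators can be enumerated at all — and
[evaluate_design()] certifies a mutant by re-enumeration. Knockouts can
never remove the zero flux vector, so they cannot *guarantee* production;
that requires an enforced lower bound (scenario S6), expressed as a bound
override rather than an intervention primitive.

```{r design}
des <- design_spec(data.frame(
  quantity = c("yield:R3/R1", "rate:R4"),
  op = c("<", ">"), value = c(0.5, 0),
  region = c("target", "desired")
))
gen <- partition_generators(enumerate_efms(s1$model), des, s1$model)
compute_mcs(gen, max_size = 3)
```

## The random-network generator and what the tests show

Property tests run against [random_network()]: sparse integer
stoichiometries (coefficients 1–2, one or two substrates/products per
reaction) over up to 6 metabolites and 10 reactions, with a guaranteed
uptake and excretion reaction and, where requested, a 20% reversibility
rate. These sizes keep three independent brute-force oracles exhaustive:
nullspace-based support search for elementary modes, EFM-support reasoning
for coupling classes and ratio bounds, and full subset enumeration for cut
sets. The generator emulates the combinatorics of small metabolic networks
— alternative routes, blocked reactions, dead ends, occasional cycles — but
not the biological texture of real models: no compartments, no biomass
equation, no realistic bound magnitudes, and stoichiometries far smaller
than genome scale. Passing these tests therefore certifies the mathematics
(enumeration, duality between LFP and generator optima, hitting-set
minimality) rather than numerical robustness on genome-scale inputs, which
the enumeration guard deliberately keeps out of scope; the LP/LFP path
itself is dimension-agnostic but is exercised here only at small scale.

## Numerical choices

* Feasibility tolerance $10^{-6}$ absolute (LP-practice default),
  configurable per call.
* Attainment equality: $10^{-7}$ relative; zero-ratio threshold in
  coupling: $10^{-9}$; membership-LP positivity: $\varepsilon = 10^{-9}$.
* Enumeration arithmetic: rows integer-scaled (denominators up to $10^4$),
  rays gcd-reduced; annotation in doubles.
* Ties among optimal LP bases are resolved by Bland's rule (lowest index),
  making witnesses deterministic; witnesses are nevertheless documented as
  non-contractual — only objective values and stated witness properties
  are stable under degeneracy.
* Infinite bounds are a first-class sentinel, never a big-M constant, so
  every "unbounded" verdict is structural, not numerical.

## Limitations

* Generator enumeration (and hence exact hulls, Theorem-style membership
  tests and cut-set computation) is limited to small networks by design;
  the LP/LFP machinery (optimization, variability, sampling) scales to
  larger models.
* Only two-dimensional phase planes and yield spaces are computed; the
  data model does not extend to three axes.
* Cut sets are reaction-level; gene–protein–reaction rules are out of
  scope, as are MILP-based dual-network cut-set methods for genome-scale
  models.
* The general linear-fractional objective with affine offsets is not
  supported: yields here are ratios of homogeneous linear forms, which is
  exactly what makes them scale-invariant.
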