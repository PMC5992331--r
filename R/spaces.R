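# Phase planes (production envelopes) and yield spaces: boundary sampling
# over a grid of slices and exact hulls from enumerated generators.

#' Sample the boundary of a phase plane (production envelope)
#'
#' The phase plane is the projection of the flux polyhedron onto two rate
#' axes. Its boundary is traced by slicing the range of axis 1 into `n`
#' intervals (grid endpoints inclusive, `n + 1` slice values) and, per
#' slice, minimizing and maximizing axis 2 subject to the slice equality.
#'
#' @param poly a `flux_polyhedron`.
#' @param axis1,axis2 rate coefficient vectors or expressions.
#' @param n discretization parameter (default 20, usually sufficient).
#' @param model optional model for expressions.
#' @return object of class `boundary_sample`; its `points` tibble has
#'   columns `slice` (axis-1 value), `branch` (`lower`/`upper`), `value`
#'   (axis-2 value, `-Inf`/`Inf` when the slice is unbounded in axis 2) and
#'   a list-column `witness` of realizing flux vectors. The `trace` tibble
#'   orders the same points as a closed polygon (lower branch left to
#'   right, then upper branch right to left), ready for plotting.
#' @export
#' @examples
#' sc <- scenario("S3")
#' pp <- sample_phase_plane(sc$poly, "R4", "R3", n = 6, model = sc$model)
#' pp$points
sample_phase_plane <- function(poly, axis1, axis2, n = 20, model = NULL) {
  c1 <- resolve_coeff(axis1, model)
  c2 <- resolve_coeff(axis2, model)
  lo <- poly_lp(poly, c1, maximize = FALSE)
  hi <- poly_lp(poly, c1, maximize = TRUE)
  if (lo$status == "infeasible") stop("polyhedron is infeasible", call. = FALSE)
  if (lo$status == "unbounded" || hi$status == "unbounded") {
    stop("axis 1 is unbounded on the polyhedron; project a bounded pair ",
         "or add constraints", call. = FALSE)
  }
  sample_slices(poly, c1, c2, lo$value, hi$value, n,
                axes = list(axis1 = c1, axis2 = c2), type = "phase_plane")
}

#' Sample the boundary of a yield space
#'
#' Structurally identical to [sample_phase_plane()], but every optimization
#' runs over the auxiliary polyhedron
#' `{(x', t) | A x' <= t b, d'x' = 1, t >= 0}`, on which the two yields are
#' the linear functions `c1'x'` and `c2'x'`. Both yields must share the
#' same denominator (same substrate), which is what makes the yield space a
#' convex set.
#'
#' @param poly a `flux_polyhedron`.
#' @param spec1,spec2 [yield_spec]s with identical denominator.
#' @param n discretization parameter.
#' @return a `boundary_sample` (see [sample_phase_plane()]); witnesses are
#'   auxiliary-space points `(x', t)` scaled back to flux space when
#'   `t > 0`.
#' @export
#' @examples
#' sc <- scenario("S1")
#' ys <- sample_yield_space(sc$poly,
#'   yield_spec("R4", "R1", model = sc$model),
#'   yield_spec("R3", "R1", model = sc$model), n = 10)
sample_yield_space <- function(poly, spec1, spec2, n = 20) {
  if (!isTRUE(all.equal(spec1$d, spec2$d))) {
    stop("both yields must share the same denominator", call. = FALSE)
  }
  aux <- build_auxiliary(poly, spec1)
  m <- poly$n
  c1 <- c(spec1$c, 0)
  c2 <- c(spec2$c, 0)
  lo <- poly_lp(aux, c1, maximize = FALSE)
  hi <- poly_lp(aux, c1, maximize = TRUE)
  if (lo$status == "infeasible") {
    stop("empty yield domain: no feasible flux with positive denominator",
         call. = FALSE)
  }
  if (lo$status == "unbounded" || hi$status == "unbounded") {
    stop("unbounded yield: the model admits product synthesis without ",
         "substrate uptake (ill-posed model or yield)", call. = FALSE)
  }
  out <- sample_slices(aux, c1, c2, lo$value, hi$value, n,
                       axes = list(spec1 = spec1, spec2 = spec2),
                       type = "yield_space")
  # report witnesses in flux space where the slice point is attained
  out$points$witness <- lapply(out$points$witness, function(w) {
    if (is.null(w)) return(NULL)
    tt <- w[m + 1L]
    if (tt > 1e-9) w[seq_len(m)] / tt else w[seq_len(m)]
  })
  out
}

sample_slices <- function(poly, c1, c2, v_min, v_max, n, axes, type) {
  grid <- seq(v_min, v_max, length.out = n + 1L)
  rng <- v_max - v_min
  rows <- list()
  infeasible_slices <- integer(0)
  for (k in seq_along(grid)) {
    g <- grid[k]
    solve_branch <- function(maximize) {
      res <- poly_lp(poly, c2, maximize = maximize,
                     extra_eq = c1, extra_eq_rhs = g)
      if (res$status == "infeasible" && rng > 0) {
        # degenerate vertex slice: perturb inward by a relative nudge
        g2 <- g + (if (k > length(grid) / 2) -1 else 1) * 1e-9 * rng
        res <- poly_lp(poly, c2, maximize = maximize,
                       extra_eq = c1, extra_eq_rhs = g2)
      }
      res
    }
    lo <- solve_branch(FALSE)
    hi <- solve_branch(TRUE)
    if (lo$status == "infeasible" && hi$status == "infeasible") {
      infeasible_slices <- c(infeasible_slices, k)
      next
    }
    val <- function(res, maximize) {
      if (res$status == "unbounded") (if (maximize) Inf else -Inf) else res$value
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      slice = g,
      branch = c("lower", "upper"),
      value = c(val(lo, FALSE), val(hi, TRUE)),
      witness = list(lo$x, hi$x)
    )
  }
  pts <- dplyr::bind_rows(rows)
  lower <- dplyr::arrange(dplyr::filter(pts, .data$branch == "lower"),
                          .data$slice)
  upper <- dplyr::arrange(dplyr::filter(pts, .data$branch == "upper"),
                          dplyr::desc(.data$slice))
  structure(
    list(
      type = type,
      axes = axes,
      n = n,
      points = pts,
      trace = dplyr::bind_rows(lower, upper),
      infeasible_slices = infeasible_slices
    ),
    class = "boundary_sample"
  )
}

#' @export
print.boundary_sample <- function(x, ...) {
  cat("<boundary_sample> ", x$type, ", n = ", x$n, ", ",
      nrow(x$points), " boundary points\n", sep = "")
  invisible(x)
}

#' @method tidy boundary_sample
#' @export
tidy.boundary_sample <- function(x, ...) {
  dplyr::select(x$points, -"witness")
}

#' Plot a sampled phase-plane or yield-space boundary
#'
#' @param object a `boundary_sample`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot boundary_sample
#' @export
autoplot.boundary_sample <- function(object, ...) {
  tr <- dplyr::filter(object$trace, is.finite(.data$value))
  lab <- if (object$type == "phase_plane") {
    c("axis 1 (rate)", "axis 2 (rate)")
  } else {
    c("yield 1", "yield 2")
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$slice, y = .data$value)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.3,
                          color = "steelblue") +
    ggplot2::labs(x = lab[1], y = lab[2],
                  title = if (object$type == "phase_plane")
                    "Phase plane / production envelope" else "Yield space") +
    ggplot2::theme_minimal()
}

#' Convex hull of projected or mapped generators
#'
#' Phase planes are convex hulls of the rate projections of all generators
#' (unbounded generators contribute rays); yield spaces are convex hulls of
#' the yield pairs of the generators with defined yield (generators with
#' undefined yield, like internal cycles and the zero vector, have no image
#' in yield space).
#'
#' @param gen a `generator_set`.
#' @param axis1,axis2 rate coefficient vectors/expressions (phase plane),
#'   or [yield_spec]s sharing a denominator (yield space).
#' @param model optional model for expressions.
#' @return object of class `hull_polygon`: `vertices` (tibble, convex
#'   polygon in counterclockwise order), `rays` (tibble of unbounded
#'   directions, phase planes only), `points` (all mapped generator
#'   points).
#' @export
#' @examples
#' sc <- scenario("S1")
#' efms <- enumerate_efms(sc$model)
#' hull_from_generators(efms,
#'   yield_spec("R4", "R1", model = sc$model),
#'   yield_spec("R3", "R1", model = sc$model))
hull_from_generators <- function(gen, axis1, axis2, model = NULL) {
  yield_mode <- inherits(axis1, "yield_spec")
  if (yield_mode != inherits(axis2, "yield_spec")) {
    stop("axes must be both rates or both yields", call. = FALSE)
  }
  k <- nrow(gen$fluxes)
  if (yield_mode) {
    if (!isTRUE(all.equal(axis1$d, axis2$d))) {
      stop("both yields must share the same denominator", call. = FALSE)
    }
    y1 <- generator_yields(gen, axis1)
    y2 <- generator_yields(gen, axis2)
    defined <- !vapply(y1, is.character, TRUE)
    if (!any(defined)) {
      stop("no generator with defined yield", call. = FALSE)
    }
    pts <- tibble::tibble(
      id = rownames(gen$fluxes)[defined],
      a1 = unlist(y1[defined]),
      a2 = unlist(y2[defined])
    )
    rays <- tibble::tibble(a1 = numeric(0), a2 = numeric(0))
  } else {
    c1 <- resolve_coeff(axis1, model)
    c2 <- resolve_coeff(axis2, model)
    a1 <- as.vector(gen$fluxes %*% c1)
    a2 <- as.vector(gen$fluxes %*% c2)
    bounded <- gen$kind == "bounded"
    if (!any(bounded)) {
      # a cone projects to the conical hull of its projected rays through 0
      pts <- tibble::tibble(id = "origin", a1 = 0, a2 = 0)
    } else {
      pts <- tibble::tibble(id = rownames(gen$fluxes)[bounded],
                            a1 = a1[bounded], a2 = a2[bounded])
    }
    nz <- !bounded & (abs(a1) > 1e-12 | abs(a2) > 1e-12)
    rays <- tibble::tibble(a1 = a1[nz], a2 = a2[nz])
  }
  idx <- grDevices::chull(pts$a1, pts$a2)
  structure(
    list(vertices = pts[rev(idx), ], rays = rays, points = pts,
         yield_mode = yield_mode),
    class = "hull_polygon"
  )
}

#' @export
print.hull_polygon <- function(x, ...) {
  cat("<hull_polygon> ", nrow(x$vertices), " vertices",
      if (nrow(x$rays) > 0) paste0(", ", nrow(x$rays), " rays"), "\n",
      sep = "")
  invisible(x)
}

#' Signed distance test: is a point inside a hull polygon?
#'
#' @param hull a `hull_polygon`.
#' @param p length-2 numeric point.
#' @param tol tolerance.
#' @return logical (rays are taken into account for unbounded hulls).
#' @export
in_hull <- function(hull, p, tol = 1e-8) {
  V <- as.matrix(hull$vertices[, c("a1", "a2")])
  R <- as.matrix(hull$rays[, c("a1", "a2")])
  k <- nrow(V)
  nr <- nrow(R)
  # feasibility: p = V' w + R' u, sum w = 1, w,u >= 0
  eqs <- rbind(cbind(t(V), if (nr) t(R) else NULL),
               c(rep(1, k), rep(0, nr)))
  poly <- flux_polyhedron(k + nr, eq = eqs, eq_rhs = c(p, 1),
                          nonneg = rep(TRUE, k + nr))
  poly_lp(poly, numeric(k + nr))$status == "optimal"
}

#' @method autoplot hull_polygon
#' @export
autoplot.hull_polygon <- function(object, ...) {
  ggplot2::ggplot(object$vertices,
                  ggplot2::aes(x = .data$a1, y = .data$a2)) +
    ggplot2::geom_polygon(fill = "firebrick", alpha = 0.25,
                          color = "firebrick") +
    ggplot2::geom_point(data = object$points, size = 2) +
    ggplot2::labs(x = "axis 1", y = "axis 2",
                  title = if (object$yield_mode) "Yield space"
                          else "Phase plane") +
    ggplot2::theme_minimal()
}

#' Map a phase-plane point to its yield-space image
#'
#' All flux vectors projecting to one phase-plane point generally map to a
#' segment in yield space (and vice versa): the fiber over the point is
#' intersected with the yield domain and each yield is minimized and
#' maximized over it as an LFP. Open endpoints (suprema approached only in
#' the limit) are flagged via the attainment test.
#'
#' @param poly a `flux_polyhedron`.
#' @param pp_point length-2 rate point `(axis1, axis2)`.
#' @param axis1,axis2 the phase-plane rate axes (coefficients or
#'   expressions).
#' @param spec1,spec2 [yield_spec]s sharing a denominator.
#' @param model optional model for expressions.
#' @return tibble with one row per yield: `yield`, `min`, `max`,
#'   `min_attained`, `max_attained`.
#' @export
#' @examples
#' sc <- scenario("S2")
#' map_pp_point_to_ys(sc$poly, c(5, 0), "R4", "R3",
#'   yield_spec("R4", "R1", model = sc$model),
#'   yield_spec("R3", "R1", model = sc$model), model = sc$model)
map_pp_point_to_ys <- function(poly, pp_point, axis1, axis2, spec1, spec2,
                               model = NULL) {
  c1 <- resolve_coeff(axis1, model)
  c2 <- resolve_coeff(axis2, model)
  fiber <- flux_polyhedron(
    poly$n,
    eq = rbind(poly$eq, c1, c2),
    eq_rhs = c(poly$eq_rhs, pp_point),
    ineq = poly$ineq, ineq_rhs = poly$ineq_rhs,
    nonneg = poly$nonneg, var_names = poly$var_names
  )
  if (poly_lp(fiber, numeric(poly$n))$status == "infeasible") {
    stop("empty fiber: the phase-plane point is infeasible", call. = FALSE)
  }
  one <- function(spec, label) {
    lo <- maximize_yield(fiber, spec, maximize = FALSE)
    hi <- maximize_yield(fiber, spec, maximize = TRUE)
    tibble::tibble(
      yield = label,
      min = lo$optimal_yield, max = hi$optimal_yield,
      min_attained = lo$status == "optimal_attained",
      max_attained = hi$status == "optimal_attained"
    )
  }
  dplyr::bind_rows(one(spec1, "yield1"), one(spec2, "yield2"))
}
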