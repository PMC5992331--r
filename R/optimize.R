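# Rate optimization (LP), yield optimization (LFP via the auxiliary
# polyhedron) and flux variability.

#' Maximize a linear rate objective (flux-balance analysis)
#'
#' Solves `max c'x` over a flux polyhedron. Unboundedness (a feasible
#' direction of the recession cone with positive objective) is reported as a
#' status, never approximated.
#'
#' @param poly a `flux_polyhedron`.
#' @param objective coefficients (length `poly$n`) or a character expression
#'   resolved against `model`.
#' @param model optional [metabolic_model] for character objectives.
#' @param maximize logical; set `FALSE` to minimize.
#' @return list of class `lp_result`: `status`
#'   (`"optimal"`/`"unbounded"`/`"infeasible"`), `objective_value`, and `x`
#'   (an optimizer, present iff optimal). Witnesses are not unique: only the
#'   objective value is a contract.
#' @export
#' @examples
#' sc <- scenario("S2")
#' maximize_rate(sc$poly, "R4", model = sc$model)$objective_value  # 10
maximize_rate <- function(poly, objective, model = NULL, maximize = TRUE) {
  obj <- resolve_coeff(objective, model)
  res <- poly_lp(poly, obj, maximize = maximize)
  structure(
    list(
      status = res$status,
      objective_value = if (res$status == "optimal") res$value else
        if (res$status == "unbounded") (if (maximize) Inf else -Inf) else NA_real_,
      x = res$x
    ),
    class = "lp_result"
  )
}

#' @export
print.lp_result <- function(x, ...) {
  cat("<lp_result>", x$status,
      if (x$status == "optimal") paste0("value ", signif(x$objective_value, 6)),
      "\n")
  invisible(x)
}

#' Build the auxiliary polyhedron of a linear-fractional program
#'
#' The yield maximization `max c'x/d'x` over `P = {x | Ax <= b}` (with
#' `d'x > 0`) is equivalent to the LP `max c'x'` over the auxiliary
#' polyhedron `P' = {(x', t) | A x' <= t b, d'x' = 1, t >= 0}`: a feasible
#' `x` maps to `(x/d'x, 1/d'x)` and a feasible `(x', t)` with `t > 0` maps
#' back to `x'/t`, preserving the objective.
#'
#' @param poly a `flux_polyhedron` in flux space.
#' @param spec a [yield_spec].
#' @return a `flux_polyhedron` over `(x', t)` (dimension `poly$n + 1`).
#' @export
build_auxiliary <- function(poly, spec) {
  n <- poly$n
  flux_polyhedron(
    n = n + 1L,
    eq = rbind(
      cbind(poly$eq, -poly$eq_rhs),
      c(spec$d, 0)
    ),
    eq_rhs = c(rep(0, nrow(poly$eq)), 1),
    ineq = cbind(poly$ineq, -poly$ineq_rhs),
    ineq_rhs = rep(0, nrow(poly$ineq)),
    nonneg = c(poly$nonneg, TRUE),
    var_names = c(poly$var_names, "t")
  )
}

#' Maximize a yield (linear-fractional program)
#'
#' Maximizes `Y(x) = c'x / d'x` over the polyhedron restricted to
#' `d'x > 0`, via the LP over the auxiliary polyhedron (see
#' [build_auxiliary()]). The supremum of a yield need not be attained at
#' finite fluxes: it can be approached only along a recession direction.
#' When the LP optimum has homogenization coordinate `t* = 0`, attainment is
#' decided by re-solving at a fixed probe `t = min(1, t_max/2) > 0` and
#' comparing objective values.
#'
#' @param poly a `flux_polyhedron`.
#' @param spec a [yield_spec].
#' @param maximize logical; set `FALSE` to minimize the yield.
#' @param tol relative tolerance for the attainment comparison.
#' @return list of class `yield_result` with `status` (`"optimal_attained"`,
#'   `"optimal_not_attained"`, `"unbounded"`, `"infeasible_domain"`),
#'   `optimal_yield` (the optimum or supremum), `x` (witness flux vector
#'   with `d'x > 0`, iff attained), `limit_direction` (recession direction
#'   realizing the supremum, iff not attained) and `t_star`.
#' @export
#' @examples
#' sc <- scenario("S3")
#' ys <- yield_spec("R4", "R1", model = sc$model)
#' maximize_yield(sc$poly, ys)$optimal_yield  # 1
maximize_yield <- function(poly, spec, maximize = TRUE, tol = 1e-7) {
  aux <- build_auxiliary(poly, spec)
  n <- poly$n
  obj <- c(spec$c, 0)
  res <- poly_lp(aux, obj, maximize = maximize)
  if (res$status == "infeasible") {
    return(yield_result("infeasible_domain"))
  }
  if (res$status == "unbounded") {
    return(yield_result("unbounded",
                        optimal_yield = if (maximize) Inf else -Inf))
  }
  t_star <- res$x[n + 1L]
  if (t_star > tol) {
    return(yield_result("optimal_attained",
                        optimal_yield = res$value,
                        x = res$x[seq_len(n)] / t_star,
                        t_star = t_star))
  }
  # LP optimum sits on the recession cone: probe whether an equally good
  # solution exists at t > 0
  tres <- poly_lp(aux, unit_vec(n + 1L, n + 1L), maximize = TRUE)
  t_max <- if (tres$status == "unbounded") Inf else tres$value
  if (t_max <= tol) {
    # no feasible point with positive denominator
    return(yield_result("infeasible_domain"))
  }
  t_probe <- min(1, t_max / 2)
  res2 <- poly_lp(aux, obj, maximize = maximize,
                  extra_eq = unit_vec(n + 1L, n + 1L),
                  extra_eq_rhs = t_probe)
  same <- res2$status == "optimal" &&
    abs(res2$value - res$value) <= tol * max(1, abs(res$value))
  if (same) {
    yield_result("optimal_attained",
                 optimal_yield = res$value,
                 x = res2$x[seq_len(n)] / t_probe,
                 t_star = t_probe)
  } else {
    yield_result("optimal_not_attained",
                 optimal_yield = res$value,
                 limit_direction = res$x[seq_len(n)],
                 t_star = 0)
  }
}

yield_result <- function(status, optimal_yield = NA_real_, x = NULL,
                         limit_direction = NULL, t_star = NA_real_) {
  structure(
    list(status = status, optimal_yield = optimal_yield, x = x,
         limit_direction = limit_direction, t_star = t_star),
    class = "yield_result"
  )
}

#' @export
print.yield_result <- function(x, ...) {
  cat("<yield_result>", x$status,
      if (is.finite(x$optimal_yield)) paste0("yield ",
                                             signif(x$optimal_yield, 6)),
      "\n")
  invisible(x)
}

#' Evaluate a yield on a flux vector
#'
#' @param x flux vector.
#' @param spec a [yield_spec].
#' @param tol absolute tolerance below which a linear form counts as zero.
#' @return the ratio `c'x / d'x` if the denominator is nonzero; the string
#'   `"undefined"` if numerator and denominator both vanish (e.g. the zero
#'   vector or an internal cycle that neither consumes substrate nor makes
#'   product); `"infinite"` if only the denominator vanishes.
#' @export
yield_value <- function(x, spec, tol = 1e-9) {
  num <- sum(spec$c * x)
  den <- sum(spec$d * x)
  if (abs(den) > tol) return(num / den)
  if (abs(num) <= tol) "undefined" else "infinite"
}

#' Flux variability of one coordinate
#'
#' @param poly a `flux_polyhedron`.
#' @param index reaction index or id (resolved against `poly$var_names`).
#' @return named numeric `c(min, max)`; unbounded directions reported as
#'   `-Inf`/`Inf`.
#' @export
flux_variability <- function(poly, index) {
  if (is.character(index)) {
    index <- match(index, poly$var_names)
  }
  if (is.na(index) || index < 1 || index > poly$n) {
    stop("invalid reaction index", call. = FALSE)
  }
  obj <- unit_vec(poly$n, index)
  lo <- poly_lp(poly, obj, maximize = FALSE)
  hi <- poly_lp(poly, obj, maximize = TRUE)
  if (lo$status == "infeasible" || hi$status == "infeasible") {
    stop("polyhedron is infeasible", call. = FALSE)
  }
  c(min = if (lo$status == "unbounded") -Inf else lo$value,
    max = if (hi$status == "unbounded") Inf else hi$value)
}
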