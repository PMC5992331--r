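# Flux coupling analysis via extremal flux ratios (linear-fractional
# programs with unit numerator and denominator).

#' Extremal flux ratio of a reaction pair
#'
#' Computes min and max of `x_i / x_j` over the feasible set restricted to
#' `x_j > 0`, by yield optimization with `c = e_i`, `d = e_j`. Limits are
#' tagged, never approximated: a supremum reached only along a direction
#' with `x_j = 0` is `"infinite"`, a ratio bound below the zero threshold is
#' `"zero"`.
#'
#' @param poly a `flux_polyhedron`.
#' @param i,j reaction indices or ids; `j` is the denominator.
#' @param zero_tol threshold below which a bound counts as zero.
#' @return list with `min`, `max` (numeric or `"zero"`/`"infinite"`) and
#'   `blocked` (`TRUE` when `x_j` is identically zero so no ratio exists).
#' @export
#' @examples
#' sc <- scenario("S1")
#' ratio_bounds(sc$poly, "R2", "R8")  # fully coupled: min = max = 1
ratio_bounds <- function(poly, i, j, zero_tol = 1e-9) {
  i <- resolve_index(poly, i)
  j <- resolve_index(poly, j)
  fv <- flux_variability(poly, j)
  if (fv["min"] < -zero_tol) {
    stop("denominator reaction can carry negative flux; analyze each ",
         "orientation separately (restrict x_j >= 0 or flip its sign)",
         call. = FALSE)
  }
  if (fv["max"] <= zero_tol) {
    return(list(min = NA_real_, max = NA_real_, blocked = TRUE))
  }
  spec <- yield_spec(unit_vec(poly$n, i), unit_vec(poly$n, j))
  tag <- function(res) {
    if (res$status == "unbounded") return("infinite")
    v <- res$optimal_yield
    if (is.na(v)) return(NA_real_)
    if (abs(v) <= zero_tol) "zero" else v
  }
  list(
    min = tag(maximize_yield(poly, spec, maximize = FALSE)),
    max = tag(maximize_yield(poly, spec, maximize = TRUE)),
    blocked = FALSE
  )
}

classify_pair <- function(mn, mx) {
  extreme <- function(v) is.character(v)  # "zero" or "infinite"
  if (!extreme(mn) && !extreme(mx)) {
    if (isTRUE(all.equal(mn, mx, tolerance = 1e-7))) "fully" else "partially"
  } else if (extreme(mn) && extreme(mx)) {
    "uncoupled"
  } else {
    "directionally"
  }
}

#' Classify flux coupling for all reaction pairs
#'
#' Each unordered pair is classified from the extremal ratio bounds of the
#' directed ratio `x_i / x_j`:
#' * `fully` — min = max, finite nonzero (one flux a fixed multiple of the
#'   other);
#' * `partially` — min != max, both finite nonzero (each activity implies
#'   the other);
#' * `directionally` — exactly one bound degenerate (activity implication
#'   one way only);
#' * `uncoupled` — both bounds degenerate.
#'
#' Pairs involving a blocked reaction (flux identically zero) are labeled
#' `blocked`; reversible reactions are analyzed on their forward orientation
#' (`x >= 0` added for the query).
#'
#' @param poly a `flux_polyhedron`.
#' @param pairs optional two-column matrix / data frame of reaction ids or
#'   indices; default all unordered pairs.
#' @param zero_tol zero threshold for ratio bounds.
#' @return a tibble with columns `i`, `j`, `ratio_min`, `ratio_max`
#'   (list-columns holding numbers or tags) and `class`.
#' @export
#' @examples
#' sc <- scenario("S1")
#' cls <- classify_all(sc$poly)
#' dplyr::filter(cls, class == "fully")
classify_all <- function(poly, pairs = NULL, zero_tol = 1e-9) {
  n <- poly$n
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2))
  } else {
    pairs <- as.data.frame(pairs)
    pairs <- cbind(
      vapply(pairs[[1]], resolve_index, 1L, poly = poly),
      vapply(pairs[[2]], resolve_index, 1L, poly = poly)
    )
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    pj <- orient_nonneg(poly, j)
    rb <- ratio_bounds(pj, i, j, zero_tol = zero_tol)
    cls <- if (rb$blocked) "blocked" else classify_pair(rb$min, rb$max)
    tibble::tibble(
      i = poly$var_names[i], j = poly$var_names[j],
      ratio_min = list(rb$min), ratio_max = list(rb$max),
      class = cls
    )
  })
  dplyr::bind_rows(rows)
}

orient_nonneg <- function(poly, j) {
  if (poly$nonneg[j]) return(poly)
  add_constraints(poly, -unit_vec(poly$n, j), 0)
}

resolve_index <- function(poly, i) {
  if (is.character(i)) {
    k <- match(i, poly$var_names)
    if (is.na(k)) stop("unknown reaction '", i, "'", call. = FALSE)
    return(k)
  }
  i <- as.integer(i)
  if (i < 1 || i > poly$n) stop("invalid reaction index", call. = FALSE)
  i
}
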