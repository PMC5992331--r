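# Metabolic model and flux polyhedron data structures.

#' Create a metabolic model
#'
#' A metabolic network is described by its stoichiometric matrix `S`
#' (metabolites x reactions, net coefficients), per-reaction reversibility and
#' flux bounds, and optionally extra linear inequality constraints
#' `G r <= h` (e.g. capacity or resource-allocation constraints).
#'
#' @param S numeric matrix, metabolites in rows, reactions in columns.
#'   Dimnames, when present, seed `metabolite_ids` / `reaction_ids`.
#' @param reversible logical vector, one entry per reaction.
#' @param lb,ub numeric flux bounds per reaction; `-Inf`/`Inf` encode the
#'   absence of a bound and are kept as such (never replaced by a large
#'   finite number, so unboundedness detection stays exact).
#' @param metabolite_ids,reaction_ids character identifiers; defaults are
#'   taken from `dimnames(S)` or generated (`M1..`, `R1..`). Vectors are
#'   positionally indexed against `reaction_ids` throughout the package.
#' @param G,h optional extra inequality constraints `G r <= h`; `G` has one
#'   column per reaction.
#' @return an object of class `metabolic_model`.
#' @export
#' @examples
#' mod <- metabolic_model(
#'   S = matrix(c(1, -1), 1, 2, dimnames = list("M", c("up", "out"))),
#'   reversible = c(FALSE, FALSE), lb = c(0, 0), ub = c(Inf, Inf)
#' )
#' mod
metabolic_model <- function(S, reversible, lb = NULL, ub = NULL,
                            metabolite_ids = NULL, reaction_ids = NULL,
                            G = NULL, h = NULL) {
  S <- as.matrix(S)
  m <- nrow(S)
  n <- ncol(S)
  make_ids <- function(prefix, k) {
    if (k == 0L) character(0) else paste0(prefix, seq_len(k))
  }
  if (is.null(metabolite_ids)) {
    metabolite_ids <- rownames(S) %||% make_ids("M", m)
  }
  if (is.null(reaction_ids)) {
    reaction_ids <- colnames(S) %||% make_ids("R", n)
  }
  reversible <- as.logical(reversible)
  if (is.null(lb)) lb <- ifelse(reversible, -Inf, 0)
  if (is.null(ub)) ub <- rep(Inf, n)
  if (is.null(G)) {
    G <- matrix(0, 0, n)
    h <- numeric(0)
  }
  G <- matrix(as.numeric(G), ncol = n)
  model <- structure(
    list(
      metabolite_ids = as.character(metabolite_ids),
      reaction_ids = as.character(reaction_ids),
      S = unname(S),
      reversible = reversible,
      lb = as.numeric(lb), ub = as.numeric(ub),
      G = unname(G), h = as.numeric(h)
    ),
    class = "metabolic_model"
  )
  validate_model(model)
}

validate_model <- function(model) {
  m <- nrow(model$S)
  n <- ncol(model$S)
  if (length(model$metabolite_ids) != m) {
    stop("metabolite_ids must match the number of rows of S", call. = FALSE)
  }
  if (length(model$reaction_ids) != n ||
      length(model$reversible) != n ||
      length(model$lb) != n || length(model$ub) != n) {
    stop("per-reaction fields must match the number of columns of S",
         call. = FALSE)
  }
  bad <- which(model$lb > model$ub)
  if (length(bad) > 0L) {
    stop("lb > ub for reaction(s): ",
         paste(model$reaction_ids[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(!model$reversible & model$lb < 0)
  if (length(bad) > 0L) {
    stop("irreversible reaction(s) with negative lower bound: ",
         paste(model$reaction_ids[bad], collapse = ", "), call. = FALSE)
  }
  if (ncol(model$G) != n || nrow(model$G) != length(model$h)) {
    stop("G and h dimensions do not match the model", call. = FALSE)
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions (",
      sum(x$reversible), " reversible), ",
      nrow(x$G), " extra constraint row(s)\n", sep = "")
  invisible(x)
}

#' Tidy a metabolic model into a reaction table
#'
#' @param x a `metabolic_model`.
#' @param ... unused.
#' @return a tibble with one row per reaction: id, reversibility, bounds and
#'   the reaction equation.
#' @method tidy metabolic_model
#' @export
tidy.metabolic_model <- function(x, ...) {
  eqs <- vapply(seq_along(x$reaction_ids), function(j) {
    col <- x$S[, j]
    lhs <- which(col < 0)
    rhs <- which(col > 0)
    fmt <- function(idx, sgn) {
      paste(vapply(idx, function(i) {
        cf <- abs(col[i])
        paste0(if (cf != 1) paste0(cf, " ") else "", x$metabolite_ids[i])
      }, character(1)), collapse = " + ")
    }
    paste0(if (length(lhs)) fmt(lhs) else "",
           if (x$reversible[j]) " <-> " else " -> ",
           if (length(rhs)) fmt(rhs) else "")
  }, character(1))
  tibble::tibble(
    reaction = x$reaction_ids,
    equation = trimws(eqs),
    reversible = x$reversible,
    lb = x$lb, ub = x$ub
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Flux polyhedron

#' Build the flux polyhedron of a model
#'
#' Assembles the feasible set \{x | N x = 0, lb <= x <= ub, G x <= h\} from a
#' model, optionally with per-reaction bound overrides and additional
#' inequality rows (scenario constraints), without mutating the model.
#' Steady state is kept as designated equality rows; infinite bounds generate
#' no row.
#'
#' @param model a [metabolic_model].
#' @param lb,ub optional named numeric vectors of bound overrides, names are
#'   reaction ids (e.g. `c(R1 = 10)` for `ub` encodes `r1 <= 10`).
#' @param extra_ineq,extra_rhs optional additional inequality rows
#'   (matrix with one column per reaction / right-hand side vector).
#' @return an object of class `flux_polyhedron` with fields `eq`, `eq_rhs`
#'   (equality rows), `ineq`, `ineq_rhs` (inequality rows), `nonneg`
#'   (orthant constraints from irreversibility), `var_names`.
#' @export
build_polyhedron <- function(model, lb = NULL, ub = NULL,
                             extra_ineq = NULL, extra_rhs = NULL) {
  n <- length(model$reaction_ids)
  lbv <- model$lb
  ubv <- model$ub
  apply_override <- function(vec, ov, what) {
    if (is.null(ov)) return(vec)
    idx <- match(names(ov), model$reaction_ids)
    if (anyNA(idx)) {
      stop("unknown reaction in ", what, " override: ",
           paste(names(ov)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    vec[idx] <- as.numeric(ov)
    vec
  }
  lbv <- apply_override(lbv, lb, "lb")
  ubv <- apply_override(ubv, ub, "ub")
  if (any(lbv > ubv)) stop("bound overrides give lb > ub", call. = FALSE)

  nonneg <- !model$reversible & lbv == 0
  A <- matrix(0, 0, n)
  b <- numeric(0)
  add_row <- function(row, rhs) {
    A <<- rbind(A, row)
    b <<- c(b, rhs)
  }
  for (j in seq_len(n)) {
    if (is.finite(ubv[j])) add_row(unit_vec(n, j), ubv[j])
    if (is.finite(lbv[j]) && !(nonneg[j] && lbv[j] == 0)) {
      add_row(-unit_vec(n, j), -lbv[j])
    }
  }
  if (nrow(model$G) > 0L) {
    A <- rbind(A, model$G)
    b <- c(b, model$h)
  }
  if (!is.null(extra_ineq)) {
    extra_ineq <- matrix(extra_ineq, ncol = n)
    A <- rbind(A, extra_ineq)
    b <- c(b, extra_rhs)
  }
  structure(
    list(
      n = n,
      eq = unname(model$S), eq_rhs = rep(0, nrow(model$S)),
      ineq = unname(A), ineq_rhs = b,
      nonneg = nonneg,
      var_names = model$reaction_ids
    ),
    class = "flux_polyhedron"
  )
}

#' Generic polyhedron constructor
#'
#' Low-level constructor for \{x | eq x = eq_rhs, ineq x <= ineq_rhs,
#' x_i >= 0 for nonneg i\}, used where a feasible set is not derived from a
#' model (e.g. auxiliary polyhedra).
#'
#' @param n dimension.
#' @param eq,eq_rhs equality rows.
#' @param ineq,ineq_rhs inequality rows.
#' @param nonneg logical orthant flags (length n).
#' @param var_names variable names.
#' @return a `flux_polyhedron`.
#' @export
flux_polyhedron <- function(n, eq = NULL, eq_rhs = NULL,
                            ineq = NULL, ineq_rhs = NULL,
                            nonneg = rep(FALSE, n),
                            var_names = paste0("x", seq_len(n))) {
  empty <- matrix(0, 0, n)
  structure(
    list(
      n = n,
      eq = if (is.null(eq)) empty else matrix(eq, ncol = n),
      eq_rhs = eq_rhs %||% numeric(0),
      ineq = if (is.null(ineq)) empty else matrix(ineq, ncol = n),
      ineq_rhs = ineq_rhs %||% numeric(0),
      nonneg = nonneg,
      var_names = var_names
    ),
    class = "flux_polyhedron"
  )
}

#' @export
print.flux_polyhedron <- function(x, ...) {
  cat("<flux_polyhedron> dim ", x$n, ": ", nrow(x$eq), " equality row(s), ",
      nrow(x$ineq), " inequality row(s), ",
      sum(x$nonneg), " sign-constrained variable(s)\n", sep = "")
  invisible(x)
}

#' Add inequality rows to a polyhedron
#'
#' @param poly a `flux_polyhedron`.
#' @param rows matrix (or vector) of row coefficients.
#' @param rhs right-hand sides.
#' @return the extended polyhedron.
#' @export
add_constraints <- function(poly, rows, rhs) {
  rows <- matrix(rows, ncol = poly$n)
  poly$ineq <- rbind(poly$ineq, rows)
  poly$ineq_rhs <- c(poly$ineq_rhs, rhs)
  poly
}

#' Expand a polyhedron to a single inequality system
#'
#' Returns the literal `A x <= b` form with rows ordered: steady state
#' (N then -N), sign constraints, then the inequality block. Useful for
#' export and for literal checks.
#'
#' @param poly a `flux_polyhedron`.
#' @return list with matrix `A` and vector `b`.
#' @export
as_inequality_form <- function(poly) {
  n <- poly$n
  sign_rows <- -diag(n)[poly$nonneg, , drop = FALSE]
  A <- rbind(poly$eq, -poly$eq, sign_rows, poly$ineq)
  b <- c(poly$eq_rhs, -poly$eq_rhs, rep(0, sum(poly$nonneg)), poly$ineq_rhs)
  list(A = unname(A), b = unname(b))
}

#' Test feasibility of a flux vector
#'
#' @param poly a `flux_polyhedron`.
#' @param x numeric flux vector of length `poly$n`.
#' @param tol absolute tolerance (default `1e-6`, matching double-precision
#'   LP practice).
#' @return `TRUE` iff all constraints hold within `tol`.
#' @export
feasible <- function(poly, x, tol = 1e-6) {
  if (length(x) != poly$n) stop("flux vector has wrong length", call. = FALSE)
  ok_eq <- nrow(poly$eq) == 0L ||
    all(abs(poly$eq %*% x - poly$eq_rhs) <= tol)
  ok_in <- nrow(poly$ineq) == 0L ||
    all(poly$ineq %*% x - poly$ineq_rhs <= tol)
  ok_sgn <- all(x[poly$nonneg] >= -tol)
  ok_eq && ok_in && ok_sgn
}

#' Is the polyhedron a cone?
#'
#' A flux polyhedron is a cone when all right-hand sides vanish (only
#' homogeneous constraints); in that case elementary flux vectors coincide
#' with elementary flux modes.
#'
#' @param poly a `flux_polyhedron`.
#' @return logical.
#' @export
is_cone <- function(poly) {
  all(poly$eq_rhs == 0) && all(poly$ineq_rhs == 0)
}

#' Recession cone of a polyhedron
#'
#' @param poly a `flux_polyhedron`.
#' @return the `flux_polyhedron` \{x | eq x = 0, ineq x <= 0, signs\}.
#' @export
recession_cone <- function(poly) {
  poly$eq_rhs[] <- 0
  poly$ineq_rhs[] <- 0
  poly
}

unit_vec <- function(n, i, val = 1) {
  v <- numeric(n)
  v[i] <- val
  v
}

# ---------------------------------------------------------------------------
# Yield specifications

#' Define a yield as a ratio of linear flux combinations
#'
#' A yield is `Y(x) = c'x / d'x`, e.g. product formation over substrate
#' uptake, evaluated on the domain `d'x > 0`. For uptake reactions modeled
#' with negative exchange fluxes, use matching negative denominator
#' coefficients so that `d'x > 0` on the relevant flux directions.
#'
#' @param numerator,denominator numeric coefficient vectors (length n), or
#'   character expressions like `"R4"` or `"2*R3+R4"` resolved against
#'   `model`.
#' @param model a [metabolic_model], required when character expressions are
#'   used.
#' @return an object of class `yield_spec` with fields `c` and `d`.
#' @export
#' @examples
#' mod <- example_network()
#' yield_spec("R4", "R1", model = mod)  # biomass yield Y_B/S
yield_spec <- function(numerator, denominator, model = NULL) {
  cvec <- resolve_coeff(numerator, model)
  dvec <- resolve_coeff(denominator, model)
  if (length(cvec) != length(dvec)) {
    stop("numerator and denominator lengths differ", call. = FALSE)
  }
  if (all(dvec == 0)) {
    stop("denominator of a yield must not be the zero vector", call. = FALSE)
  }
  structure(list(c = cvec, d = dvec), class = "yield_spec")
}

#' @export
print.yield_spec <- function(x, ...) {
  cat("<yield_spec> Y(x) = c'x / d'x with",
      sum(x$c != 0), "numerator and", sum(x$d != 0),
      "denominator term(s)\n")
  invisible(x)
}

#' Resolve a linear flux combination against a model
#'
#' Parses expressions such as `"R4"`, `"2*R3+R4"` or `"R3-0.5*R2"` into a
#' coefficient vector positionally indexed against the model's reactions.
#'
#' @param expr numeric vector (returned as-is) or character expression.
#' @param model a [metabolic_model] (needed for character input).
#' @return numeric coefficient vector.
#' @export
resolve_coeff <- function(expr, model = NULL) {
  if (is.numeric(expr)) return(as.numeric(expr))
  if (!is.character(expr) || length(expr) != 1L) {
    stop("objective must be a numeric vector or a single string",
         call. = FALSE)
  }
  if (is.null(model)) {
    stop("a model is required to resolve '", expr, "'", call. = FALSE)
  }
  n <- length(model$reaction_ids)
  out <- numeric(n)
  s <- gsub("\\s", "", expr)
  s <- gsub("-", "+-", s, fixed = TRUE)
  terms <- strsplit(s, "+", fixed = TRUE)[[1]]
  terms <- terms[nzchar(terms)]
  for (term in terms) {
    parts <- strsplit(term, "*", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      if (grepl("^-", parts)) {
        coef <- -1
        rid <- sub("^-", "", parts)
      } else {
        coef <- 1
        rid <- parts
      }
    } else if (length(parts) == 2L) {
      coef <- suppressWarnings(as.numeric(parts[1]))
      rid <- parts[2]
      if (is.na(coef)) stop("cannot parse coefficient in '", term, "'",
                            call. = FALSE)
    } else {
      stop("cannot parse term '", term, "'", call. = FALSE)
    }
    j <- match(rid, model$reaction_ids)
    if (is.na(j)) stop("unknown reaction '", rid, "'", call. = FALSE)
    out[j] <- out[j] + coef
  }
  out
}
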