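# Elementary flux modes and elementary flux vectors.
#
# EFVs of a flux polyhedron P = {x | Ax <= b} are the elementary (conformally
# non-decomposable) vectors of the homogenized cone {(x,t) | Ax - tb <= 0,
# t >= 0}. They are computed here by double description on a lifted cone in
# which every reversible flux is split into forward/backward parts and every
# inequality row receives a nonnegative slack, so the lifted cone is the
# intersection of a linear subspace with the nonnegative orthant and
# elementarity reduces to support minimality. Generators with t > 0 are
# normalized to t = 1 ("bounded", the polytope part); generators with t = 0
# span the recession cone ("unbounded"). For a flux cone (all right-hand
# sides zero) no homogenization coordinate is needed and the EFVs coincide
# with the EFMs.

#' Enumerate the elementary flux vectors of a polyhedron
#'
#' @param poly a `flux_polyhedron`.
#' @param max_dim refuse enumeration above this flux-space dimension
#'   (default 64; enumeration is for small models, genome-scale generator
#'   sets are far beyond reach of any enumeration).
#' @param max_rays abort if an intermediate ray set exceeds this size.
#' @return an object of class `generator_set`: a flux matrix (one row per
#'   generator, exact small rationals at fixture scale), a `kind` flag
#'   (`"bounded"`/`"unbounded"`), and the source polyhedron. The zero vector
#'   is a bounded generator whenever the polyhedron is not a cone and
#'   contains it.
#' @export
#' @examples
#' sc <- scenario("S2")
#' efvs <- enumerate_efvs(sc$poly)
#' tidy(efvs)
enumerate_efvs <- function(poly, max_dim = 64, max_rays = 1e6) {
  n <- poly$n
  if (n > max_dim) {
    stop("enumeration refused: ", n, " reactions exceeds max_dim = ",
         max_dim, " (generator enumeration is not feasible at this scale)",
         call. = FALSE)
  }
  cone <- is_cone(poly)
  free <- which(!poly$nonneg)
  n_free <- length(free)
  n_iq <- nrow(poly$ineq)
  # lifted coordinates: x (n) | backward parts of free vars | t | slacks
  t_col <- if (cone) 0L else n + n_free + 1L
  d_lift <- n + n_free + (!cone) + n_iq
  lift_rows <- function(M, rhs) {
    # M x (= or <=) rhs  ->  M x+ - M x-  (- rhs t)  [+ s]
    cbind(M, -M[, free, drop = FALSE],
          if (!cone) -rhs else NULL)
  }
  slack_block <- function(k) {
    if (n_iq == 0L) return(NULL)
    out <- matrix(0, k, n_iq)
    out
  }
  Meq <- cbind(lift_rows(poly$eq, poly$eq_rhs),
               matrix(0, nrow(poly$eq), n_iq))
  if (n_iq > 0L) {
    Miq <- cbind(lift_rows(poly$ineq, poly$ineq_rhs), diag(n_iq))
    Meq <- rbind(Meq, Miq)
  }
  Meq <- t(apply(Meq, 1, int_scale))
  if (nrow(Meq) == 0L) Meq <- matrix(0, 0, d_lift)

  rays <- dd_enumerate(Meq, d_lift, max_rays)

  # map lifted rays back to flux space
  k <- ncol(rays)
  gen <- matrix(0, 0, n)
  kind <- character(0)
  for (i in seq_len(k)) {
    y <- rays[, i]
    xp <- y[seq_len(n)]
    xm <- numeric(n)
    if (n_free > 0L) xm[free] <- y[n + seq_len(n_free)]
    if (any(xp > 0 & xm > 0)) next  # futile two-cycle from variable splitting
    x <- xp - xm
    tt <- if (cone) 0 else y[t_col]
    if (tt > 0) {
      gen <- rbind(gen, x / tt)
      kind <- c(kind, "bounded")
    } else {
      gen <- rbind(gen, ray_normalize(x))
      kind <- c(kind, "unbounded")
    }
  }
  ord <- order(kind != "bounded",
               -rowSums(abs(gen) > 1e-12),
               apply(gen, 1, function(r) paste(signif(r, 10), collapse = ",")))
  # deterministic order: bounded generators first, wider supports first
  gen <- gen[ord, , drop = FALSE]
  kind <- kind[ord]
  new_generator_set(gen, kind, poly)
}

#' Enumerate the elementary flux modes of a model
#'
#' EFMs are the support-minimal nonzero steady-state flux vectors under
#' irreversibility alone, i.e. the EFVs of the model's flux cone (bounds and
#' extra constraints are ignored); all generators are unbounded rays.
#'
#' @param model a [metabolic_model].
#' @inheritParams enumerate_efvs
#' @return a `generator_set`.
#' @export
#' @examples
#' efms <- enumerate_efms(example_network())
#' nrow(efms$fluxes)  # 6
enumerate_efms <- function(model, max_dim = 64, max_rays = 1e6) {
  cone <- flux_polyhedron(
    n = length(model$reaction_ids),
    eq = model$S, eq_rhs = rep(0, nrow(model$S)),
    nonneg = !model$reversible,
    var_names = model$reaction_ids
  )
  enumerate_efvs(cone, max_dim = max_dim, max_rays = max_rays)
}

new_generator_set <- function(fluxes, kind, poly, annotations = NULL) {
  if (nrow(fluxes) > 0L) {
    rownames(fluxes) <- paste0("g", seq_len(nrow(fluxes)))
  }
  colnames(fluxes) <- poly$var_names
  structure(
    list(fluxes = fluxes, kind = kind, poly = poly,
         annotations = annotations),
    class = "generator_set"
  )
}

#' @export
print.generator_set <- function(x, ...) {
  cat("<generator_set> ", nrow(x$fluxes), " generator(s): ",
      sum(x$kind == "bounded"), " bounded, ",
      sum(x$kind == "unbounded"), " unbounded",
      if (!is.null(x$annotations)) " (annotated)", "\n", sep = "")
  invisible(x)
}

#' Tidy a generator set
#'
#' @param x a `generator_set`.
#' @param ... unused.
#' @return a tibble with one row per generator: `id`, `kind`, annotation
#'   columns when present (`rate`, `yield`, `yield_status`), and one column
#'   per reaction.
#' @method tidy generator_set
#' @export
tidy.generator_set <- function(x, ...) {
  base <- tibble::tibble(
    id = rownames(x$fluxes) %||% character(0),
    kind = x$kind
  )
  if (!is.null(x$annotations)) {
    base <- dplyr::bind_cols(base, x$annotations)
  }
  dplyr::bind_cols(base, tibble::as_tibble(x$fluxes))
}

#' Annotate generators with rate and yield values
#'
#' Mirrors the usual generator-table layout: each generator gets its linear
#' rate value `c'x` and its yield status (a defined value, `"undefined"`
#' when numerator and denominator both vanish, `"infinite"` when only the
#' denominator does).
#'
#' @param gen a `generator_set`.
#' @param rate rate objective (coefficients or expression; optional).
#' @param spec a [yield_spec] (optional).
#' @param model optional model for resolving expressions.
#' @return the annotated `generator_set`.
#' @export
annotate_generators <- function(gen, rate = NULL, spec = NULL, model = NULL) {
  k <- nrow(gen$fluxes)
  ann <- gen$annotations %||% tibble::tibble(.rows = k)
  if (!is.null(rate)) {
    cvec <- resolve_coeff(rate, model)
    ann$rate <- as.vector(gen$fluxes %*% cvec)
  }
  if (!is.null(spec)) {
    vals <- lapply(seq_len(k), function(i) yield_value(gen$fluxes[i, ], spec))
    ann$yield <- vapply(vals, function(v) {
      if (is.character(v)) NA_real_ else v
    }, numeric(1))
    ann$yield_status <- vapply(vals, function(v) {
      if (is.character(v)) v else "defined"
    }, character(1))
    gen$spec <- spec
  }
  gen$annotations <- ann
  gen
}

generator_yields <- function(gen, spec) {
  lapply(seq_len(nrow(gen$fluxes)),
         function(i) yield_value(gen$fluxes[i, ], spec))
}

#' Is the maximum yield attained?
#'
#' Decides attainment of the yield supremum from an enumerated generator
#' set: the maximum is not attained precisely when every bounded generator
#' has a defined yield and the best of them is beaten by an unbounded
#' (recession-cone) generator. Adding generators with undefined yield (the
#' zero vector, internal cycles) never changes a yield, which is why their
#' presence among the bounded generators guarantees attainment.
#'
#' @param gen a `generator_set`.
#' @param spec a [yield_spec].
#' @param tol comparison tolerance.
#' @return list with `attained` (logical) and `supremum` (the optimal
#'   yield; the supremum over defined-yield generators).
#' @export
yield_attained <- function(gen, spec, tol = 1e-9) {
  ys <- generator_yields(gen, spec)
  if (any(vapply(ys, identical, TRUE, "infinite"))) {
    stop("yield is unbounded on this polyhedron ",
         "(a generator has nonzero numerator and zero denominator)",
         call. = FALSE)
  }
  defined <- !vapply(ys, is.character, TRUE)
  if (!any(defined)) {
    stop("no generator with defined yield: the domain d'x > 0 is empty",
         call. = FALSE)
  }
  yv <- rep(NA_real_, length(ys))
  yv[defined] <- unlist(ys[defined])
  bounded <- gen$kind == "bounded"
  supremum <- max(yv[defined])
  if (!any(bounded)) {
    # flux cone: the polytope part of P is {0} (undefined yield), so the
    # not-attained criterion can never hold
    return(list(attained = TRUE, supremum = supremum))
  }
  I_d_is_I <- all(defined[bounded])
  best_bounded <- if (any(bounded & defined)) max(yv[bounded & defined]) else -Inf
  best_unbounded <- if (any(!bounded & defined)) max(yv[!bounded & defined]) else -Inf
  not_attained <- I_d_is_I && best_bounded < best_unbounded - tol
  list(attained = !not_attained,
       supremum = if (not_attained) best_unbounded else supremum)
}

#' Partition generators into yield-optimality classes
#'
#' Given that the maximum yield is attained, every yield-optimal flux vector
#' is a convex sum of bounded generators that are either yield-optimal
#' (`I_star`) or have undefined yield (`I_u`), plus a conical sum of
#' unbounded generators that are yield-optimal (`J_star`) or have undefined
#' yield (`J_u`) — with a strictly positive total weight on the optimal ones.
#'
#' @param gen a `generator_set`.
#' @param spec a [yield_spec].
#' @param tol tolerance for yield equality.
#' @return list with the four index vectors (`I_star`, `I_u`, `J_star`,
#'   `J_u`, indices into the generator rows), `Y_star`, and `other`
#'   (generators in neither class).
#' @export
classify_optimal <- function(gen, spec, tol = 1e-9) {
  att <- yield_attained(gen, spec, tol = tol)
  if (!att$attained) {
    stop("maximum yield is not attained; see yield_attained()",
         call. = FALSE)
  }
  ys <- generator_yields(gen, spec)
  defined <- !vapply(ys, is.character, TRUE)
  undef <- vapply(ys, identical, TRUE, "undefined")
  yv <- rep(NA_real_, length(ys))
  yv[defined] <- unlist(ys[defined])
  is_opt <- defined & abs(yv - att$supremum) <= tol * max(1, abs(att$supremum))
  bounded <- gen$kind == "bounded"
  idx <- seq_along(ys)
  list(
    I_star = idx[bounded & is_opt],
    I_u = idx[bounded & undef],
    J_star = idx[!bounded & is_opt],
    J_u = idx[!bounded & undef],
    other = idx[!(is_opt | undef)],
    Y_star = att$supremum
  )
}

#' Test a flux vector for yield optimality by decomposition
#'
#' Decides via a feasibility LP whether `x` is a convex/conical combination
#' of the optimal-class generators (see [classify_optimal()]) with strictly
#' positive weight on the yield-optimal ones. For points with `d'x > 0`
#' this is equivalent to `Y(x) = Y*`.
#'
#' @param gen a `generator_set`.
#' @param spec a [yield_spec].
#' @param x flux vector.
#' @param eps stand-in for the strict positivity constraint on optimal
#'   weights (tested as `>= eps`).
#' @param tol feasibility tolerance passed to the LP.
#' @return logical.
#' @export
is_yield_optimal <- function(gen, spec, x, eps = 1e-9, tol = 1e-6) {
  cls <- classify_optimal(gen, spec)
  use <- c(cls$I_star, cls$I_u, cls$J_star, cls$J_u)
  if (length(use) == 0L) return(FALSE)
  conv <- use %in% c(cls$I_star, cls$I_u)   # convex-sum weights
  star <- use %in% c(cls$I_star, cls$J_star)
  decompose_feasible(gen$fluxes[use, , drop = FALSE], conv, x,
                     star = star, eps = eps, tol = tol,
                     force_convex_row = any(gen$kind == "bounded"))
}

#' Decompose a point over the full generator set
#'
#' Feasibility of `x = sum_i alpha_i v_i + sum_j beta_j u_j` with
#' `alpha, beta >= 0` and `sum alpha = 1` (over bounded generators); for a
#' cone only the conical part is used. Every feasible point of the
#' polyhedron must admit such a decomposition when the generator set is
#' complete.
#'
#' @param gen a `generator_set`.
#' @param x flux vector.
#' @param tol feasibility tolerance.
#' @return logical.
#' @export
decomposable <- function(gen, x, tol = 1e-6) {
  decompose_feasible(gen$fluxes, gen$kind == "bounded", x,
                     star = NULL, eps = 0, tol = tol,
                     force_convex_row = any(gen$kind == "bounded"))
}

decompose_feasible <- function(V, conv, x, star = NULL, eps = 0,
                               tol = 1e-6, force_convex_row = TRUE) {
  k <- nrow(V)
  n <- ncol(V)
  eqs <- t(V)                       # n rows: V' w = x
  rhs <- as.numeric(x)
  if (force_convex_row && any(conv)) {
    eqs <- rbind(eqs, as.numeric(conv))
    rhs <- c(rhs, 1)
  }
  ineq <- NULL
  ineq_rhs <- NULL
  if (!is.null(star) && eps > 0) {
    ineq <- matrix(-as.numeric(star), 1)
    ineq_rhs <- -eps
  }
  p <- flux_polyhedron(k, eq = eqs, eq_rhs = rhs,
                       ineq = ineq, ineq_rhs = ineq_rhs,
                       nonneg = rep(TRUE, k))
  res <- poly_lp(p, numeric(k))
  res$status == "optimal"
}

#' Rate-optimal generators
#'
#' For a bounded linear objective, the rate-optimal solution set is spanned
#' by the optimal bounded generators plus the whole recession cone (whose
#' generators all have zero objective).
#'
#' @param gen a `generator_set`.
#' @param objective rate coefficients or expression.
#' @param model optional model for expressions.
#' @param tol tolerance.
#' @return list with `optimal` (indices of optimal bounded generators),
#'   `max_rate`, and `recession` (indices of unbounded generators, freely
#'   addable to any optimal solution).
#' @export
rate_optimal_set <- function(gen, objective, model = NULL, tol = 1e-9) {
  cvec <- resolve_coeff(objective, model)
  vals <- as.vector(gen$fluxes %*% cvec)
  unb <- gen$kind == "unbounded"
  if (any(unb & vals > tol)) {
    stop("rate unbounded: objective is positive on an unbounded generator",
         call. = FALSE)
  }
  bounded <- which(gen$kind == "bounded")
  if (length(bounded) == 0L) {
    stop("no bounded generators: rate optimization on a cone is unbounded ",
         "or trivial", call. = FALSE)
  }
  mx <- max(vals[bounded])
  list(
    optimal = bounded[vals[bounded] >= mx - tol * max(1, abs(mx))],
    max_rate = mx,
    recession = which(unb & abs(vals) <= tol)
  )
}

# ---------------------------------------------------------------------------
# double description on {y >= 0 | M y = 0}

dd_enumerate <- function(M, d, max_rays) {
  R <- diag(d)
  for (i in seq_len(nrow(M))) {
    v <- as.vector(M[i, ] %*% R)
    v[abs(v) < 1e-9] <- 0
    zero <- which(v == 0)
    pos <- which(v > 0)
    neg <- which(v < 0)
    if (length(pos) * length(neg) + length(zero) > max_rays) {
      stop("enumeration aborted: intermediate ray count exceeds max_rays",
           call. = FALSE)
    }
    new <- matrix(0, d, length(pos) * length(neg))
    k <- 0L
    for (p in pos) {
      for (q in neg) {
        k <- k + 1L
        new[, k] <- ray_reduce(v[p] * R[, q] - v[q] * R[, p])
      }
    }
    cand <- cbind(R[, zero, drop = FALSE], new)
    if (ncol(cand) == 0L) {
      R <- cand
      break
    }
    keep_new <- support_minimal_new(cand, n_old = length(zero))
    R <- cand[, keep_new, drop = FALSE]
  }
  R
}

# keep old rays; keep a new ray iff no other candidate's support is strictly
# contained in it and no earlier candidate shares its support
support_minimal_new <- function(cand, n_old) {
  k <- ncol(cand)
  S <- t(cand > 1e-12)           # k x d logical support matrix
  sizes <- rowSums(S)
  C <- S %*% t(S)                # C[i, j] = |supp_i \cap supp_j|
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    if (i <= n_old) next
    contained <- C[i, ] == sizes            # supp_j subseteq supp_i
    contained[i] <- FALSE
    proper <- contained & sizes < sizes[i]
    dup <- contained & sizes == sizes[i] & seq_len(k) < i
    if (any(proper) || any(dup)) keep[i] <- FALSE
  }
  which(keep)
}

# divide an integer-valued ray by the gcd of its entries
ray_reduce <- function(y) {
  nz <- abs(y) > 1e-9
  if (!any(nz)) return(y)
  if (all(abs(y[nz] - round(y[nz])) < 1e-9)) {
    g <- Reduce(gcd2, abs(round(y[nz])))
    if (g > 1) y <- y / g
  } else {
    y <- y / max(abs(y[nz]))
  }
  y
}

gcd2 <- function(a, b) {
  while (b > 0.5) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

# normalize an unbounded generator to the smallest integer vector when the
# entries are rational, else to unit max-norm
ray_normalize <- function(x) {
  nz <- abs(x) > 1e-9
  if (!any(nz)) return(x)
  sc <- int_scale(x)
  if (!is.null(attr(sc, "failed"))) return(x / max(abs(x[nz])))
  g <- Reduce(gcd2, abs(round(sc[nz])))
  if (g > 1) sc <- sc / g
  sc
}

# scale a numeric row to (small) integers; falls back to the original row
# with attr "failed" when entries are not close to small rationals
int_scale <- function(v, max_den = 1e4, tol = 1e-8) {
  nz <- v[abs(v) > 1e-12]
  if (length(nz) == 0L) return(v)
  for (k in 1:max_den) {
    w <- v * k
    if (all(abs(w - round(w)) < tol * k)) return(round(w))
  }
  out <- v
  attr(out, "failed") <- TRUE
  out
}
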