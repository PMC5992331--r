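# Dense two-phase simplex with Bland's anti-cycling rule.
#
# This is the numerical core behind every rate (LP) and yield (LFP via the
# auxiliary polyhedron) optimization in the package. A hand-rolled solver is
# used because the analyses here need a trustworthy three-way status
# (optimal / infeasible / unbounded): unbounded rate optima on flux cones and
# the attainment test for yield suprema are first-class outcomes, not errors.
# Problems are small (tens of variables); clarity and exact status reporting
# beat speed.

#' Solve a linear program in standard form
#'
#' Maximizes (or minimizes) `obj' x` subject to `A x (<= or =) b` and
#' `x >= 0`. Row senses are given per row; `>=` rows must be passed as
#' negated `<=` rows by the caller.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand side (length m), any sign.
#' @param sense character vector of row senses, `"<="` or `"="`.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol numerical tolerance for pivoting and feasibility.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `value` and `x` (present when optimal).
#' @keywords internal
#' @noRd
lp_standard <- function(obj, A, b, sense, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(sense) == m)
  if (m == 0L) {
    # only x >= 0: optimum at 0 unless an improving coordinate exists
    improving <- if (maximize) any(obj > tol) else any(obj < -tol)
    if (improving) return(list(status = "unbounded"))
    return(list(status = "optimal", value = 0, x = numeric(n)))
  }

  n_slack <- sum(sense == "<=")
  slack_of_row <- integer(m)
  S <- matrix(0, m, n_slack)
  k <- 0L
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      k <- k + 1L
      S[i, k] <- 1
      slack_of_row[i] <- n + k
    }
  }
  Afull <- cbind(A, S)
  bfull <- b
  neg <- bfull < 0
  if (any(neg)) {
    Afull[neg, ] <- -Afull[neg, , drop = FALSE]
    bfull[neg] <- -bfull[neg]
  }

  # rows whose slack survived the sign flip provide an initial basic column;
  # the rest get artificials
  has_slack_basis <- sense == "<=" & !neg
  n_art <- sum(!has_slack_basis)
  Art <- matrix(0, m, n_art)
  art_cols <- integer(0)
  basis <- integer(m)
  k <- 0L
  for (i in seq_len(m)) {
    if (has_slack_basis[i]) {
      basis[i] <- slack_of_row[i]
    } else {
      k <- k + 1L
      Art[i, k] <- 1
      basis[i] <- n + n_slack + k
    }
  }
  tab <- cbind(Afull, Art, bfull)
  n_tot <- n + n_slack + n_art
  rhs_col <- n_tot + 1L

  pivot <- function(tab, r, c) {
    tab[r, ] <- tab[r, ] / tab[r, c]
    other <- setdiff(seq_len(nrow(tab)), r)
    tab[other, ] <- tab[other, ] - outer(tab[other, c], tab[r, ])
    tab
  }

  # minimize cost' y over current tableau using Bland's rule
  run_phase <- function(tab, basis, cost, usable) {
    repeat {
      cb <- cost[basis]
      # reduced costs for usable, nonbasic columns
      rc <- cost[usable] - as.vector(cb %*% tab[, usable, drop = FALSE])
      rc[match(basis, usable, nomatch = 0)] <- 0  # basic columns exactly 0
      cand <- usable[rc < -tol]
      if (length(cand) == 0L) {
        return(list(tab = tab, basis = basis, status = "optimal"))
      }
      j <- min(cand)  # Bland: lowest index enters
      col <- tab[, j]
      rows <- which(col > tol)
      if (length(rows) == 0L) {
        return(list(tab = tab, basis = basis, status = "unbounded", enter = j))
      }
      ratio <- tab[rows, rhs_col] / col[rows]
      best <- rows[ratio <= min(ratio) + tol]
      r <- best[which.min(basis[best])]  # Bland: lowest basic index leaves
      tab <- pivot(tab, r, j)
      basis[r] <- j
    }
  }

  # Phase 1
  if (n_art > 0L) {
    cost1 <- c(rep(0, n + n_slack), rep(1, n_art))
    ph1 <- run_phase(tab, basis, cost1, seq_len(n_tot))
    tab <- ph1$tab
    basis <- ph1$basis
    if (sum(cost1[basis] * tab[, rhs_col]) > 1e-7) {
      return(list(status = "infeasible"))
    }
    # drive remaining artificials out of the basis
    drop_rows <- integer(0)
    for (r in which(basis > n + n_slack)) {
      piv <- which(abs(tab[r, seq_len(n + n_slack)]) > tol)
      if (length(piv) > 0L) {
        j <- piv[1L]
        tab <- pivot(tab, r, j)
        basis[r] <- j
      } else {
        drop_rows <- c(drop_rows, r)  # redundant row
      }
    }
    if (length(drop_rows) > 0L) {
      tab <- tab[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      rhs_col <- ncol(tab)
    }
  }

  # Phase 2 over structural + slack columns only
  cost2 <- c(if (maximize) -obj else obj, rep(0, n_slack), rep(0, n_art))
  ph2 <- run_phase(tab, basis, cost2, seq_len(n + n_slack))
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded"))
  }
  tab <- ph2$tab
  basis <- ph2$basis
  x <- numeric(n)
  in_x <- basis <= n
  x[basis[in_x]] <- tab[in_x, ncol(tab)]
  list(status = "optimal", value = sum(obj * x), x = x)
}

#' Solve an LP over a flux polyhedron
#'
#' Handles free (sign-unrestricted) variables by splitting, equality rows and
#' inequality rows; reports unboundedness and infeasibility as statuses.
#'
#' @param poly a [flux_polyhedron].
#' @param obj objective coefficients in flux space (length `poly$n`).
#' @param maximize logical.
#' @param extra_eq,extra_eq_rhs optional additional equality rows (matrix /
#'   vector) appended for this solve only.
#' @param extra_ineq,extra_ineq_rhs optional additional `<=` rows.
#' @return list with `status`, `value`, `x` (flux-space optimizer if optimal).
#' @keywords internal
#' @noRd
poly_lp <- function(poly, obj, maximize = TRUE,
                    extra_eq = NULL, extra_eq_rhs = NULL,
                    extra_ineq = NULL, extra_ineq_rhs = NULL) {
  n <- poly$n
  E <- poly$eq
  be <- poly$eq_rhs
  A <- poly$ineq
  bi <- poly$ineq_rhs
  if (!is.null(extra_eq)) {
    extra_eq <- matrix(extra_eq, ncol = n)
    E <- rbind(E, extra_eq)
    be <- c(be, extra_eq_rhs)
  }
  if (!is.null(extra_ineq)) {
    extra_ineq <- matrix(extra_ineq, ncol = n)
    A <- rbind(A, extra_ineq)
    bi <- c(bi, extra_ineq_rhs)
  }
  free <- !poly$nonneg
  # variable layout: x (all coords, nonneg part) then negative parts of free
  expand <- function(M) {
    if (is.null(M) || nrow(M) == 0L) return(matrix(0, 0, n + sum(free)))
    cbind(M, -M[, free, drop = FALSE])
  }
  Mall <- rbind(expand(E), expand(A))
  ball <- c(be, bi)
  senses <- c(rep("=", length(be)), rep("<=", length(bi)))
  obj_lp <- c(obj, -obj[free])
  res <- lp_standard(obj_lp, Mall, ball, senses, maximize = maximize)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    if (any(free)) x[free] <- x[free] - res$x[n + seq_len(sum(free))]
    res$x <- x
  }
  res
}
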