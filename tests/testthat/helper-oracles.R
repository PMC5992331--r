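# Independent brute-force oracles used by the property tests. These are
# deliberately naive (exhaustive subset enumeration, dense nullspaces) and
# share no code with the package's double-description / LP machinery.

# All elementary flux modes of a model by exhaustive support search: a
# signed support T is an EFM support iff the nullspace of S restricted to T
# is one-dimensional, the basis vector has full support on T, it can be
# oriented to satisfy the irreversibility signs, and no feasible nonzero
# vector has a properly contained support.
oracle_efms <- function(model, tol = 1e-8) {
  S <- model$S
  n <- ncol(S)
  irr <- !model$reversible
  cand <- list()
  for (size in 1:n) {
    for (T in utils::combn(n, size, simplify = FALSE)) {
      ST <- S[, T, drop = FALSE]
      ns <- MASS::Null(t(ST))
      if (ncol(ns) != 1L) next
      v <- ns[, 1]
      if (any(abs(v) < tol)) next          # support not full on T
      x <- numeric(n)
      x[T] <- v
      neg <- any(x[irr] < -tol)
      pos <- any(x[irr] > tol)
      if (neg && pos) next                 # no feasible orientation
      if (neg) x <- -x
      cand[[length(cand) + 1L]] <- x / max(abs(x))
    }
  }
  if (length(cand) == 0L) return(cand)
  # reversible-only candidates are feasible in both orientations: keep both
  full <- cand
  for (x in cand) {
    if (all(abs(x[irr]) < tol)) full[[length(full) + 1L]] <- -x
  }
  # support-minimality over signed supports
  ssupp <- lapply(full, function(x) {
    c(which(x > tol), -which(x < -tol))
  })
  keep <- vapply(seq_along(full), function(i) {
    !any(vapply(seq_along(full), function(j) {
      j != i && length(ssupp[[j]]) < length(ssupp[[i]]) &&
        all(ssupp[[j]] %in% ssupp[[i]])
    }, TRUE))
  }, TRUE)
  dedupe_rays(full[keep])
}

dedupe_rays <- function(xs, tol = 1e-8) {
  out <- list()
  for (x in xs) {
    xn <- x / max(abs(x))
    dup <- any(vapply(out, function(y) max(abs(y - xn)) < tol, TRUE))
    if (!dup) out[[length(out) + 1L]] <- xn
  }
  out
}

# Extremal ratio x_i / x_j over the flux cone restricted to x_j > 0, from an
# EFM list: the supremum is infinite iff some feasible mode has x_i > 0 with
# x_j = 0 (it can be added at any scale); otherwise extremal ratios are
# achieved at modes with x_j > 0.
oracle_ratio_bounds <- function(efms, i, j, tol = 1e-8) {
  with_j <- Filter(function(x) x[j] > tol, efms)
  if (length(with_j) == 0L) return(list(blocked = TRUE))
  without_j <- Filter(function(x) abs(x[j]) <= tol, efms)
  hi_inf <- any(vapply(without_j, function(x) x[i] > tol, TRUE))
  lo_inf <- any(vapply(without_j, function(x) x[i] < -tol, TRUE))
  ratios <- vapply(with_j, function(x) x[i] / x[j], numeric(1))
  list(
    blocked = FALSE,
    min = if (lo_inf) -Inf else min(ratios),
    max = if (hi_inf) Inf else max(ratios)
  )
}

oracle_coupling_class <- function(efms, i, j, zero_tol = 1e-7) {
  rb <- oracle_ratio_bounds(efms, i, j)
  if (rb$blocked) return("blocked")
  lo_x <- !is.finite(rb$min) || abs(rb$min) <= zero_tol
  hi_x <- !is.finite(rb$max) || abs(rb$max) <= zero_tol
  if (!lo_x && !hi_x) {
    if (abs(rb$min - rb$max) <= 1e-6 * max(1, abs(rb$max))) "fully"
    else "partially"
  } else if (lo_x && hi_x) "uncoupled" else "directionally"
}

# Exhaustive constrained-MCS search: all reaction subsets up to max_size
# that intersect every target support and miss at least one desired
# support, reduced to inclusion-minimal ones.
oracle_mcs <- function(targets, desired, n, max_size) {
  hits <- list()
  for (size in 1:max_size) {
    for (C in utils::combn(n, size, simplify = FALSE)) {
      ok_t <- all(vapply(targets, function(T) length(intersect(T, C)) > 0, TRUE))
      ok_d <- length(desired) == 0L ||
        any(vapply(desired, function(D) length(intersect(D, C)) == 0, TRUE))
      if (ok_t && ok_d) hits[[length(hits) + 1L]] <- C
    }
  }
  keep <- vapply(seq_along(hits), function(i) {
    !any(vapply(seq_along(hits), function(j) {
      j != i && length(hits[[j]]) < length(hits[[i]]) &&
        all(hits[[j]] %in% hits[[i]])
    }, TRUE))
  }, TRUE)
  hits[keep]
}

# random point of the polyhedron from its generator decomposition
random_generator_point <- function(gen, seed_offset = 0, scale = 3) {
  V <- gen$fluxes[gen$kind == "bounded", , drop = FALSE]
  U <- gen$fluxes[gen$kind == "unbounded", , drop = FALSE]
  x <- numeric(ncol(gen$fluxes))
  if (nrow(V) > 0L) {
    a <- stats::runif(nrow(V))
    a <- a / sum(a)
    x <- x + as.vector(a %*% V)
  }
  if (nrow(U) > 0L) {
    b <- stats::runif(nrow(U), 0, scale)
    x <- x + as.vector(b %*% U)
  }
  x
}

canon_set <- function(sets) {
  unique(sort(vapply(sets, function(s) paste(sort(s), collapse = ","),
                     character(1))))
}
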