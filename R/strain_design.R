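# Constrained minimal cut sets: partition generators into target / desired /
# neutral behaviors and compute minimal knockout sets that block every
# target generator while keeping at least one desired one.

#' Specify a strain design by target and desired regions
#'
#' A design is a set of linear constraints on rates and yields of flux
#' distributions. Constraints with `region = "target"` define the undesired
#' behaviors (all of which a cut set must eliminate); constraints with
#' `region = "desired"` define the behaviors to preserve (at least one must
#' survive). A generator belongs to a region when it satisfies all of the
#' region's constraints; otherwise it is neutral.
#'
#' @param constraints a data frame with columns `quantity` (strings like
#'   `"rate:R4"` or `"yield:R3/R1"`, each side an expression understood by
#'   [resolve_coeff()]), `op` (`"<="`, `"<"`, `">="`, `">"`), `value`
#'   (numeric), `region` (`"target"` or `"desired"`).
#' @param notes free-text description.
#' @return object of class `design_spec`.
#' @export
#' @examples
#' design_spec(data.frame(
#'   quantity = c("yield:R3/R1", "rate:R4"),
#'   op = c("<", ">="), value = c(0.5, 0),
#'   region = c("target", "desired")
#' ))
design_spec <- function(constraints, notes = "") {
  constraints <- tibble::as_tibble(constraints)
  stopifnot(all(c("quantity", "op", "value", "region") %in%
                  names(constraints)))
  if (!all(constraints$op %in% c("<=", "<", ">=", ">"))) {
    stop("op must be one of <=, <, >=, >", call. = FALSE)
  }
  if (!all(constraints$region %in% c("target", "desired"))) {
    stop("region must be 'target' or 'desired'", call. = FALSE)
  }
  structure(list(constraints = constraints, notes = notes),
            class = "design_spec")
}

#' Read a design specification from JSON
#'
#' The document is an array of objects with fields `quantity`, `op`,
#' `value`, `region` (see [design_spec()]).
#'
#' @param path file path.
#' @return a `design_spec`.
#' @export
read_design <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  design_spec(tibble::as_tibble(doc))
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec> ", sum(x$constraints$region == "target"),
      " target / ", sum(x$constraints$region == "desired"),
      " desired constraint(s)\n", sep = "")
  invisible(x)
}

design_quantity_value <- function(quantity, x, model, tol = 1e-9) {
  parts <- strsplit(quantity, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("rate", "yield")) {
    stop("quantity must look like 'rate:<expr>' or 'yield:<expr>/<expr>'",
         call. = FALSE)
  }
  if (parts[1] == "rate") {
    return(sum(resolve_coeff(parts[2], model) * x))
  }
  nd <- strsplit(parts[2], "/", fixed = TRUE)[[1]]
  if (length(nd) != 2L) {
    stop("yield quantity must be '<numerator>/<denominator>'", call. = FALSE)
  }
  v <- yield_value(x, yield_spec(nd[1], nd[2], model = model), tol = tol)
  if (is.character(v)) NA_real_ else v
}

satisfies <- function(value, op, rhs, tol = 1e-9) {
  if (is.na(value)) return(NA)  # undefined yield: constraint not applicable
  switch(op,
    "<=" = value <= rhs + tol,
    "<"  = value < rhs - tol,    # boundary points land on the desired side
    ">=" = value >= rhs - tol,
    ">"  = value > rhs + tol
  )
}

#' Partition generators into target, desired and neutral sets
#'
#' A generator is assigned to the target region if it satisfies every
#' target constraint, else to the desired region if it satisfies every
#' desired constraint, else it is neutral. Yield constraints do not apply
#' to generators with undefined yield (the zero vector, internal cycles):
#' such a constraint can never place them in a region, so they are neutral
#' unless the region is decided by rate constraints alone.
#'
#' @param gen a `generator_set`.
#' @param design a [design_spec].
#' @param model the [metabolic_model] the generators refer to.
#' @return the `generator_set` with a `region` annotation column; access
#'   the assignment via `tidy()`.
#' @export
partition_generators <- function(gen, design, model) {
  cs <- design$constraints
  region_of <- function(x) {
    member <- function(region) {
      rows <- which(cs$region == region)
      if (length(rows) == 0L) return(FALSE)
      ok <- vapply(rows, function(r) {
        v <- design_quantity_value(cs$quantity[r], x, model)
        satisfies(v, cs$op[r], cs$value[r])
      }, NA)
      all(!is.na(ok) & ok)
    }
    if (member("target")) "target"
    else if (member("desired")) "desired"
    else "neutral"
  }
  k <- nrow(gen$fluxes)
  reg <- vapply(seq_len(k), function(i) region_of(gen$fluxes[i, ]),
                character(1))
  ann <- gen$annotations %||% tibble::tibble(.rows = k)
  ann$region <- reg
  gen$annotations <- ann
  gen
}

generator_supports <- function(gen, tol = 1e-9) {
  lapply(seq_len(nrow(gen$fluxes)),
         function(i) which(abs(gen$fluxes[i, ]) > tol))
}

#' Compute constrained minimal cut sets
#'
#' Enumerates all inclusion-minimal reaction sets (up to `max_size`) whose
#' knockout blocks every target generator (the set hits every target
#' support; a knockout removes both directions of a reversible reaction)
#' while leaving at least one desired generator intact (support disjoint
#' from the set). Exact Berge-style transversal enumeration; intended for
#' fixture-scale generator sets.
#'
#' @param gen a partitioned `generator_set` (see [partition_generators()]),
#'   or `NULL` when `targets`/`desired` are given directly.
#' @param max_size maximum cut-set cardinality.
#' @param allowed optional reaction ids/indices eligible for knockout
#'   (e.g. to exclude exchange reactions); default all.
#' @param targets,desired optional lists of support index vectors,
#'   overriding the partition in `gen`.
#' @return tibble with list-column `reactions` (knocked-out reaction ids),
#'   `size`, sorted by cardinality. Empty (with a message) when no cut set
#'   up to `max_size` exists.
#' @export
compute_mcs <- function(gen = NULL, max_size = 5, allowed = NULL,
                        targets = NULL, desired = NULL) {
  if (is.null(targets)) {
    if (is.null(gen$annotations$region)) {
      stop("generator set is not partitioned; run partition_generators()",
           call. = FALSE)
    }
    supports <- generator_supports(gen)
    targets <- supports[gen$annotations$region == "target"]
    desired <- supports[gen$annotations$region == "desired"]
  }
  if (length(targets) == 0L) {
    stop("target set is empty: nothing to cut", call. = FALSE)
  }
  var_names <- if (!is.null(gen)) gen$poly$var_names else
    paste0("R", seq_len(max(unlist(c(targets, desired)), 0)))
  n <- length(var_names)
  allowed_idx <- if (is.null(allowed)) seq_len(n) else
    vapply(allowed, function(a) {
      if (is.character(a)) match(a, var_names) else as.integer(a)
    }, 1L)

  hs <- list(integer(0))
  for (target in targets) {
    tr <- intersect(target, allowed_idx)
    if (length(tr) == 0L) {
      message("a target generator has no knockable reaction; no cut set")
      return(tibble::tibble(reactions = list(), size = integer(0)))
    }
    nxt <- list()
    for (h in hs) {
      if (length(intersect(h, tr)) > 0L) {
        nxt[[length(nxt) + 1L]] <- h
      } else {
        for (r in tr) {
          cand <- sort(c(h, r))
          if (length(cand) <= max_size) nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    hs <- minimal_sets(nxt)
  }
  keep <- vapply(hs, function(h) {
    length(desired) == 0L ||
      any(vapply(desired, function(d) length(intersect(d, h)) == 0L, TRUE))
  }, TRUE)
  hs <- hs[keep]
  if (length(hs) == 0L) {
    message("no constrained cut set up to size ", max_size)
    return(tibble::tibble(reactions = list(), size = integer(0)))
  }
  ord <- order(lengths(hs))
  tibble::tibble(
    reactions = lapply(hs[ord], function(h) var_names[h]),
    size = lengths(hs)[ord]
  )
}

minimal_sets <- function(sets) {
  if (length(sets) <= 1L) return(unique(sets))
  sets <- unique(sets)
  keep <- rep(TRUE, length(sets))
  ord <- order(lengths(sets))
  sets <- sets[ord]
  for (i in seq_along(sets)) {
    if (!keep[i]) next
    for (j in seq_along(sets)) {
      if (i == j || !keep[j]) next
      if (length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]])) {
        keep[j] <- FALSE
      }
    }
  }
  sets[keep]
}

#' Apply reaction knockouts to a model
#'
#' @param model a [metabolic_model].
#' @param reactions reaction ids or indices to remove (bounds set to zero).
#' @return the modified model copy.
#' @export
apply_knockouts <- function(model, reactions) {
  idx <- vapply(reactions, function(r) {
    if (is.character(r)) {
      k <- match(r, model$reaction_ids)
      if (is.na(k)) stop("unknown reaction '", r, "'", call. = FALSE)
      k
    } else as.integer(r)
  }, 1L)
  model$lb[idx] <- 0
  model$ub[idx] <- 0
  validate_model(model)
}

#' Evaluate a knockout design on a mutant model
#'
#' Re-enumerates the mutant's generators and re-partitions them against the
#' design: the design passes when no target-region generator remains and at
#' least one desired-region generator survives. Since phase planes and
#' yield spaces are generator hulls, this certifies the designed envelope
#' shape.
#'
#' @param model the mutant [metabolic_model] (after knockouts).
#' @param design a [design_spec].
#' @param lb,ub optional scenario bound overrides (as in
#'   [build_polyhedron()]).
#' @return list with `pass` (logical), `n_target_remaining`, `n_desired`,
#'   `partition` (tibble of generators and regions) and `violations`
#'   (tibble of surviving target generators, empty when passing).
#' @export
evaluate_design <- function(model, design, lb = NULL, ub = NULL) {
  poly <- build_polyhedron(model, lb = lb, ub = ub)
  gen <- enumerate_efvs(poly)
  gen <- partition_generators(gen, design, model)
  tab <- tidy(gen)
  violations <- dplyr::filter(tab, .data$region == "target")
  n_desired <- sum(tab$region == "desired")
  list(
    pass = nrow(violations) == 0L && n_desired >= 1L,
    n_target_remaining = nrow(violations),
    n_desired = n_desired,
    partition = tab,
    violations = violations
  )
}
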