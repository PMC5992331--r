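# Built-in example network, analysis scenarios and random test networks.

#' The built-in example network
#'
#' A small network with six internal metabolites (S, A, B, C, P, Q) and
#' eleven reactions: substrate uptake (R1), excretion of the byproduct Q
#' (R2), of the product P (R3) and of biomass B (R4), the internal
#' conversions R5 (S -> A), R6 (2 S -> C + P), R7 (A -> C), R8 (S -> Q),
#' R9 (S -> P), R10 (C -> B), and the reversible R11 (A <-> B). All
#' stoichiometric coefficients are one except the substrate coefficient of
#' R6, which is two. The flux cone of this network has six elementary flux
#' modes, one of which is the (thermodynamically infeasible, deliberately
#' retained) internal cycle over R7, R10 and R11 (backward).
#'
#' @return a [metabolic_model].
#' @export
#' @examples
#' mod <- example_network()
#' tidy(mod)
example_network <- function() {
  mets <- c("S", "A", "B", "C", "P", "Q")
  rxn <- list(
    R1  = c(S = 1),
    R2  = c(Q = -1),
    R3  = c(P = -1),
    R4  = c(B = -1),
    R5  = c(S = -1, A = 1),
    R6  = c(S = -2, C = 1, P = 1),
    R7  = c(A = -1, C = 1),
    R8  = c(S = -1, Q = 1),
    R9  = c(S = -1, P = 1),
    R10 = c(C = -1, B = 1),
    R11 = c(A = -1, B = 1)
  )
  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, names(rxn)))
  for (j in seq_along(rxn)) S[names(rxn[[j]]), j] <- rxn[[j]]
  metabolic_model(S, reversible = names(rxn) == "R11")
}

#' Analysis scenarios for the example network
#'
#' Returns the example network together with the flux polyhedron of one of
#' six nested scenarios:
#' * `S1` — steady state and irreversibility only (the flux cone);
#' * `S2` — `S1` plus the substrate-uptake cap `r1 <= 10`;
#' * `S3` — `S2` plus the capacity constraint `r5 <= 5`;
#' * `S4` — `S2` with reaction R5 knocked out;
#' * `S5` — `S2` with reactions R5 and R8 knocked out;
#' * `S6` — `S5` plus the enforced lower bound `r6 >= 3`.
#'
#' S4–S6 are the strain-design variants: S4 couples growth to product
#' synthesis in the production envelope, S5 additionally removes the
#' zero-yield substrate-to-Q route (strong yield coupling), and S6 models an
#' upregulation that guarantees a minimum production rate.
#'
#' @param id one of `"S1"`..`"S6"`.
#' @return list with elements `model` (knockouts applied where relevant) and
#'   `poly` (the scenario's flux polyhedron).
#' @export
#' @examples
#' sc <- scenario("S3")
#' maximize_rate(sc$poly, resolve_coeff("R4", sc$model))
scenario <- function(id = c("S1", "S2", "S3", "S4", "S5", "S6")) {
  id <- match.arg(id)
  base <- example_network()
  model <- switch(id,
    S1 = base, S2 = base, S3 = base,
    S4 = apply_knockouts(base, "R5"),
    S5 = ,
    S6 = apply_knockouts(base, c("R5", "R8"))
  )
  poly <- switch(id,
    S1 = build_polyhedron(model),
    S2 = ,
    S4 = ,
    S5 = build_polyhedron(model, ub = c(R1 = 10)),
    S3 = build_polyhedron(model, ub = c(R1 = 10, R5 = 5)),
    S6 = build_polyhedron(model, ub = c(R1 = 10), lb = c(R6 = 3))
  )
  list(id = id, model = model, poly = poly)
}

#' Generate a random small network for property tests
#'
#' Draws a sparse integer stoichiometry with at least one uptake
#' (source) and one excretion (sink) reaction, suitable for exhaustive
#' oracle checks (elementary-mode enumeration, coupling brute force).
#'
#' @param n_mets number of internal metabolites.
#' @param n_rxns number of reactions (values up to ~10 keep exhaustive
#'   oracles cheap).
#' @param seed integer seed; the same seed reproduces the same model.
#' @param p_rev probability that an internal reaction is reversible.
#' @return a [metabolic_model].
#' @export
random_network <- function(n_mets, n_rxns, seed, p_rev = 0.2) {
  stopifnot(n_rxns >= 2, n_mets >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  S <- matrix(0, n_mets, n_rxns)
  # first reaction: uptake of metabolite 1; last: excretion of a random one
  S[1, 1] <- 1
  S[sample.int(n_mets, 1), n_rxns] <- -1
  for (j in seq_len(n_rxns)[-c(1, n_rxns)]) {
    k <- sample(1:2, 1)
    cons <- sample.int(n_mets, k)
    prod <- sample.int(n_mets, sample(1:2, 1))
    S[cons, j] <- S[cons, j] - sample(1:2, length(cons), replace = TRUE)
    S[prod, j] <- S[prod, j] + sample(1:2, length(prod), replace = TRUE)
    if (all(S[, j] == 0)) S[sample.int(n_mets, 1), j] <- 1
  }
  rev <- stats::runif(n_rxns) < p_rev
  rev[c(1, n_rxns)] <- FALSE
  metabolic_model(S, rev)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
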