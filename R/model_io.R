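# Model input/output: native JSON, TSV stoichiometry, SBML (Level 3 + fbc).

#' Read a metabolic model from file
#'
#' Supported dialects:
#' * `json` — the native format: a document with keys `metabolites` (array of
#'   ids), `reactions` (array of objects `id`, `reversible`, `lb`, `ub`,
#'   `stoichiometry` as a metabolite-to-coefficient map; `"-inf"`/`"inf"` or
#'   missing bounds encode infinite bounds) and optional `constraints`
#'   (array of objects `coefficients` as a reaction-to-coefficient map and
#'   `rhs`), read as `G r <= h`.
#' * `tsv` — a metabolite x reaction stoichiometry table (first column =
#'   metabolite id); reversibility and bounds from an optional sidecar
#'   `<path>.bounds.tsv` with columns `reaction`, `reversible`, `lb`, `ub`.
#' * `sbml` — SBML Level 3 with the fbc package; flux bounds are resolved
#'   from the fbc bound parameters, boundary-condition species are dropped.
#'
#' @param path file path.
#' @param format `"json"`, `"tsv"` or `"sbml"`; default guessed from the
#'   file extension.
#' @return a validated [metabolic_model]; reaction and metabolite order is
#'   the file order.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      json = "json", xml = "sbml", sbml = "sbml", tsv = "tsv",
      stop("cannot guess model format from '", path, "'", call. = FALSE)
    )
  }
  switch(format,
    json = load_model_json(path),
    tsv = load_model_tsv(path),
    sbml = load_model_sbml(path)
  )
}

num_or_inf <- function(x, default) {
  if (is.null(x)) return(default)
  if (is.character(x)) {
    return(switch(tolower(x),
                  "inf" = Inf, "+inf" = Inf, "-inf" = -Inf,
                  as.numeric(x)))
  }
  as.numeric(x)
}

load_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- vapply(doc$metabolites, function(m) {
    if (is.list(m)) as.character(m$id) else as.character(m)
  }, character(1))
  n <- length(doc$reactions)
  m <- length(mets)
  S <- matrix(0, m, n)
  rids <- character(n)
  rev <- logical(n)
  lb <- numeric(n)
  ub <- numeric(n)
  for (j in seq_len(n)) {
    rx <- doc$reactions[[j]]
    rids[j] <- as.character(rx$id)
    rev[j] <- isTRUE(rx$reversible)
    lb[j] <- num_or_inf(rx$lb, if (rev[j]) -Inf else 0)
    ub[j] <- num_or_inf(rx$ub, Inf)
    for (met in names(rx$stoichiometry)) {
      i <- match(met, mets)
      if (is.na(i)) {
        stop("reaction ", rids[j], " references unknown metabolite '",
             met, "'", call. = FALSE)
      }
      S[i, j] <- as.numeric(rx$stoichiometry[[met]])
    }
  }
  G <- matrix(0, 0, n)
  h <- numeric(0)
  for (cs in doc$constraints) {
    row <- numeric(n)
    for (rid in names(cs$coefficients)) {
      j <- match(rid, rids)
      if (is.na(j)) stop("constraint references unknown reaction '", rid,
                         "'", call. = FALSE)
      row[j] <- as.numeric(cs$coefficients[[rid]])
    }
    G <- rbind(G, row)
    h <- c(h, as.numeric(cs$rhs))
  }
  metabolic_model(S, rev, lb, ub, metabolite_ids = mets, reaction_ids = rids,
                  G = G, h = h)
}

#' Write a metabolic model to the native JSON format
#'
#' Round-trips exactly through [load_model()]: stoichiometry, bounds
#' (including infinities), reversibility and extra constraints.
#'
#' @param model a [metabolic_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  fmt_bound <- function(x) {
    if (x == Inf) "inf" else if (x == -Inf) "-inf" else x
  }
  reactions <- lapply(seq_along(model$reaction_ids), function(j) {
    nz <- which(model$S[, j] != 0)
    st <- as.list(model$S[nz, j])
    names(st) <- model$metabolite_ids[nz]
    list(
      id = model$reaction_ids[j],
      reversible = model$reversible[j],
      lb = fmt_bound(model$lb[j]),
      ub = fmt_bound(model$ub[j]),
      stoichiometry = st
    )
  })
  constraints <- lapply(seq_along(model$h), function(i) {
    nz <- which(model$G[i, ] != 0)
    cf <- as.list(model$G[i, nz])
    names(cf) <- model$reaction_ids[nz]
    list(coefficients = cf, rhs = model$h[i])
  })
  doc <- list(
    metabolites = as.list(model$metabolite_ids),
    reactions = reactions,
    constraints = constraints
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

load_model_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  mets <- as.character(tab[[1]])
  S <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(S) <- "double"
  rids <- colnames(S)
  rev <- rep(FALSE, ncol(S))
  lb <- rep(0, ncol(S))
  ub <- rep(Inf, ncol(S))
  sidecar <- paste0(path, ".bounds.tsv")
  if (file.exists(sidecar)) {
    bt <- utils::read.delim(sidecar)
    idx <- match(bt$reaction, rids)
    if (anyNA(idx)) stop("bounds sidecar names unknown reactions",
                         call. = FALSE)
    if (!is.null(bt$reversible)) rev[idx] <- as.logical(bt$reversible)
    if (!is.null(bt$lb)) lb[idx] <- vapply(bt$lb, num_or_inf, 1, default = 0)
    if (!is.null(bt$ub)) ub[idx] <- vapply(bt$ub, num_or_inf, 1, default = Inf)
    lb[rev & lb == 0] <- ifelse(is.null(bt$lb), -Inf, lb[rev & lb == 0])
  }
  metabolic_model(S, rev, lb, ub, metabolite_ids = mets, reaction_ids = rids)
}

load_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_boundary]
  rxns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rxns)
  S <- matrix(0, length(mets), n)
  rids <- xml2::xml_attr(rxns, "id")
  rev <- xml2::xml_attr(rxns, "reversible") %in% "true"
  lb <- ifelse(rev, -Inf, 0)
  ub <- rep(Inf, n)
  fbc_attr <- function(node, what) {
    v <- xml2::xml_attr(node, paste0("fbc:", what))
    if (is.na(v)) v <- xml2::xml_attr(node, what)
    v
  }
  for (j in seq_len(n)) {
    rx <- rxns[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rx, paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        i <- match(sp, mets)
        if (is.na(i)) next  # boundary species
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        S[i, j] <- S[i, j] + sgn * st
      }
    }
    lb_ref <- fbc_attr(rx, "lowerFluxBound")
    ub_ref <- fbc_attr(rx, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(pval)) lb[j] <- pval[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(pval)) ub[j] <- pval[[ub_ref]]
  }
  rev <- rev | lb < 0
  metabolic_model(S, rev, lb, ub, metabolite_ids = mets, reaction_ids = rids)
}

#' Export a polyhedron as a two-file TSV
#'
#' Writes the expanded inequality system (see [as_inequality_form()]) to
#' `<stem>.A.tsv` (coefficient matrix with variable-name header) and
#' `<stem>.b.tsv` (one right-hand side per line).
#'
#' @param poly a `flux_polyhedron`.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
export_polyhedron <- function(poly, stem) {
  sys <- as_inequality_form(poly)
  pa <- paste0(stem, ".A.tsv")
  pb <- paste0(stem, ".b.tsv")
  colnames(sys$A) <- poly$var_names
  utils::write.table(sys$A, pa, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(b = sys$b), pb, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pa, pb))
}
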