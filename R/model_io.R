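#' Construct a constraint-based metabolic model
#'
#' The container used throughout the package: a stoichiometric matrix `S`
#' (metabolites x reactions), per-reaction flux bounds in
#' mmol/gDW/hr, an objective vector (1 on the biomass reaction, 0
#' elsewhere) and per-reaction subsystem annotations.
#'
#' @param id model identifier string.
#' @param S stoichiometric matrix, metabolites in rows and reactions in
#'   columns; coerced to a sparse `Matrix::dgCMatrix`. Must carry row and
#'   column names (metabolite and reaction identifiers).
#' @param lower_bounds,upper_bounds numeric vectors, one entry per reaction.
#' @param objective_coeffs numeric vector, one entry per reaction; the
#'   biomass reaction carries a nonzero weight.
#' @param subsystem character vector of per-reaction subsystem annotations
#'   (empty string when unknown).
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, S, lower_bounds, upper_bounds,
                            objective_coeffs, subsystem = NULL) {
  S <- methods::as(methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("S must have metabolite row names and reaction column names")
  n <- ncol(S)
  if (is.null(subsystem)) subsystem <- rep("", n)
  stopifnot(length(lower_bounds) == n, length(upper_bounds) == n,
            length(objective_coeffs) == n, length(subsystem) == n)
  if (any(!is.finite(lower_bounds)) || any(!is.finite(upper_bounds)))
    stop("flux bounds must be finite (use the model's large-bound sentinel, e.g. 1000)")
  bad <- which(lower_bounds > upper_bounds)
  if (length(bad))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(colnames(S)[bad], collapse = ", "))
  model <- structure(
    list(id = as.character(id)[1],
         metabolite_ids = rownames(S),
         reaction_ids = colnames(S),
         S = S,
         lower_bounds = stats::setNames(as.numeric(lower_bounds), colnames(S)),
         upper_bounds = stats::setNames(as.numeric(upper_bounds), colnames(S)),
         objective_coeffs = stats::setNames(as.numeric(objective_coeffs), colnames(S)),
         subsystem = stats::setNames(as.character(subsystem), colnames(S))),
    class = "metabolic_model")
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  ", length(x$metabolite_ids), " metabolites x ",
      length(x$reaction_ids), " reactions\n", sep = "")
  obj <- names(which(x$objective_coeffs != 0))
  cat("  objective: ", if (length(obj)) paste(obj, collapse = ", ") else "<none>",
      "\n", sep = "")
  invisible(x)
}

#' Read a metabolic model from disk
#'
#' Supports BiGG-style JSON and SBML Level 3 with the FBC extension. The
#' format is inferred from the file extension unless given explicitly.
#'
#' @param path path to the model file.
#' @param format one of `"auto"`, `"bigg_json"`, `"sbml"`.
#' @return A [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "bigg_json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "bigg_json"
  }
  switch(format,
         bigg_json = read_bigg_json(path),
         sbml = read_sbml_model(path))
}

#' Read a BiGG JSON metabolic model
#'
#' @param path path to a BiGG-format JSON file (fields `metabolites`,
#'   `reactions` with per-reaction `metabolites` coefficient maps, bounds,
#'   `subsystem` and `objective_coefficient`).
#' @return A [metabolic_model()].
#' @export
read_bigg_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("failed to parse BiGG JSON '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    stop("BiGG JSON '", path, "' lacks a 'reactions' or 'metabolites' element")
  met_ids <- vapply(doc$metabolites, function(m) as.character(m$id), "")
  rxn_ids <- vapply(doc$reactions, function(r) as.character(r$id), "")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids in ", path)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  for (j in seq_along(doc$reactions)) {
    mets <- doc$reactions[[j]]$metabolites
    if (length(mets)) {
      idx <- met_index[names(mets)]
      if (anyNA(idx))
        stop("reaction '", rxn_ids[j], "' references unknown metabolite(s): ",
             paste(names(mets)[is.na(idx)], collapse = ", "))
      ii <- c(ii, idx)
      jj <- c(jj, rep.int(j, length(mets)))
      xx <- c(xx, vapply(mets, as.numeric, 0))
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  num_or <- function(v, d) if (is.null(v)) d else as.numeric(v)
  lb <- vapply(doc$reactions, function(r) num_or(r$lower_bound, -1000), 0)
  ub <- vapply(doc$reactions, function(r) num_or(r$upper_bound, 1000), 0)
  obj <- vapply(doc$reactions, function(r) num_or(r$objective_coefficient, 0), 0)
  sub <- vapply(doc$reactions,
                function(r) if (is.null(r$subsystem)) "" else as.character(r$subsystem), "")
  if (all(obj == 0))
    stop("model '", path, "' declares no objective reaction")
  metabolic_model(id = if (is.null(doc$id)) basename(path) else doc$id,
                  S = S, lower_bounds = lb, upper_bounds = ub,
                  objective_coeffs = obj, subsystem = sub)
}

#' Write a metabolic model as BiGG JSON
#'
#' Inverse of [read_bigg_json()]; `read_bigg_json(write_bigg_json(m, f))`
#' reproduces `S`, bounds, objective and subsystems exactly.
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bigg_json <- function(model, path) {
  St <- as(model$S, "TsparseMatrix")
  coef_by_rxn <- split(data.frame(m = model$metabolite_ids[St@i + 1L], x = St@x,
                                  stringsAsFactors = FALSE),
                       factor(St@j + 1L, levels = seq_along(model$reaction_ids)))
  reactions <- lapply(seq_along(model$reaction_ids), function(j) {
    cf <- coef_by_rxn[[j]]
    list(id = model$reaction_ids[j],
         metabolites = stats::setNames(as.list(cf$x), cf$m),
         lower_bound = model$lower_bounds[[j]],
         upper_bound = model$upper_bounds[[j]],
         objective_coefficient = model$objective_coeffs[[j]],
         subsystem = model$subsystem[[j]])
  })
  metabolites <- lapply(model$metabolite_ids, function(m)
    list(id = m, compartment = metabolite_compartment(m)))
  doc <- list(id = model$id, metabolites = metabolites, reactions = reactions,
              genes = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# BiGG convention: compartment is the suffix after the last underscore
# ("_c" cytosol, "_e" extracellular, "_p" periplasm).
metabolite_compartment <- function(met_ids,
                                   compartment_regex = "_([a-z][a-z0-9]?)$") {
  m <- regmatches(met_ids, regexpr(compartment_regex, met_ids))
  out <- rep(NA_character_, length(met_ids))
  hit <- grepl(compartment_regex, met_ids)
  out[hit] <- sub("^_", "", m)
  out
}

metabolite_species <- function(met_ids,
                               compartment_regex = "_([a-z][a-z0-9]?)$") {
  sub(compartment_regex, "", met_ids)
}

#' Read an SBML Level 3 (FBC) metabolic model
#'
#' Parses species, reactions, flux bounds (FBC `lowerFluxBound` /
#' `upperFluxBound` parameter references), the active FBC objective, and,
#' when present, SBML `groups` as subsystem annotations. Leading `M_` / `R_`
#' identifier prefixes are stripped to recover BiGG-style identifiers.
#'
#' @param path path to an SBML file.
#' @return A [metabolic_model()].
#' @export
read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("failed to parse SBML '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          g = "http://www.sbml.org/sbml/level3/version1/groups/version1")
  strip <- function(x, p) sub(paste0("^", p, "_"), "", x)

  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(species)) stop("SBML '", path, "' contains no species")
  met_ids <- strip(xml2::xml_attr(species, "id"), "M")

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rxns)) stop("SBML '", path, "' contains no reactions")
  raw_ids <- xml2::xml_attr(rxns, "id")
  rxn_ids <- strip(raw_ids, "R")

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  for (j in seq_along(rxns)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rxns[[j]],
                                 paste0("./s:", side, "/s:speciesReference"), ns)
      if (!length(refs)) next
      sp <- strip(xml2::xml_attr(refs, "species"), "M")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      idx <- met_index[sp]
      if (anyNA(idx))
        stop("reaction '", rxn_ids[j], "' references unknown species: ",
             paste(sp[is.na(idx)], collapse = ", "))
      ii <- c(ii, idx); jj <- c(jj, rep.int(j, length(sp))); xx <- c(xx, st)
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))

  lb_ref <- xml2::xml_attr(rxns, "lowerFluxBound")
  ub_ref <- xml2::xml_attr(rxns, "upperFluxBound")
  rev <- xml2::xml_attr(rxns, "reversible") %in% c("true", "1")
  lb <- ifelse(is.na(lb_ref), ifelse(rev, -1000, 0), pval[lb_ref])
  ub <- ifelse(is.na(ub_ref), 1000, pval[ub_ref])

  fobj <- xml2::xml_find_all(doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  obj <- stats::setNames(rep(0, length(rxn_ids)), raw_ids)
  if (!length(fobj))
    stop("SBML '", path, "' declares no FBC objective reaction")
  obj[xml2::xml_attr(fobj, "reaction")] <-
    as.numeric(xml2::xml_attr(fobj, "coefficient"))

  sub <- rep("", length(rxn_ids))
  groups <- xml2::xml_find_all(doc, ".//g:listOfGroups/g:group", ns)
  for (grp in groups) {
    gname <- xml2::xml_attr(grp, "name")
    members <- xml2::xml_find_all(grp, "./g:listOfMembers/g:member", ns)
    refs <- xml2::xml_attr(members, "idRef")
    sub[match(refs, raw_ids, nomatch = 0L)] <- gname
  }

  metabolic_model(id = xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id"),
                  S = S, lower_bounds = as.numeric(lb), upper_bounds = as.numeric(ub),
                  objective_coeffs = as.numeric(obj), subsystem = sub)
}

#' Partition reactions into exchange, transport, biomass and internal sets
#'
#' Exchange reactions are boundary pseudo-reactions touching exactly one
#' metabolite (BiGG prefix `EX_`). Transport reactions are flagged either by
#' a subsystem annotation matching `transport_regex` (case-insensitively) or
#' structurally, by moving the same chemical species between compartments.
#' The biomass reaction is the unique reaction with a nonzero objective
#' coefficient. Everything else is internal: the predictor set for inverse
#' environment prediction.
#'
#' @param model a [metabolic_model()].
#' @param transport_regex pattern matched against subsystem annotations.
#' @param compartment_regex pattern extracting the compartment suffix from
#'   metabolite identifiers (BiGG convention `"_c"`, `"_e"`, `"_p"`).
#' @return An object of class `reaction_partition`: a list with
#'   `exchange_ids`, `transport_ids`, `internal_ids` and `biomass_id`.
#' @export
classify_reactions <- function(model, transport_regex = "transport",
                               compartment_regex = "_([a-z][a-z0-9]?)$") {
  obj_rxns <- names(which(model$objective_coeffs != 0))
  if (length(obj_rxns) == 0L)
    stop("no objective (biomass) reaction in model '", model$id, "'")
  if (length(obj_rxns) > 1L)
    stop("several reactions carry a nonzero objective coefficient: ",
         paste(obj_rxns, collapse = ", "))
  biomass_id <- obj_rxns

  n_mets <- Matrix::colSums(model$S != 0)
  exchange <- model$reaction_ids[n_mets == 1L]

  species <- metabolite_species(model$metabolite_ids, compartment_regex)
  comp <- metabolite_compartment(model$metabolite_ids, compartment_regex)
  St <- as(model$S, "TsparseMatrix")
  cross <- tapply(seq_along(St@x), factor(St@j + 1L,
                                          levels = seq_along(model$reaction_ids)),
                  function(k) {
                    sp <- species[St@i[k] + 1L]
                    cm <- comp[St@i[k] + 1L]
                    sgn <- sign(St@x[k])
                    any(vapply(unique(sp), function(s) {
                      sel <- sp == s
                      any(sgn[sel] < 0) && any(sgn[sel] > 0) &&
                        length(unique(cm[sel])) > 1L
                    }, TRUE))
                  })
  cross[is.na(cross)] <- FALSE
  by_subsystem <- grepl(transport_regex, model$subsystem, ignore.case = TRUE)
  transport <- model$reaction_ids[(as.logical(cross) | by_subsystem)]
  transport <- setdiff(transport, c(exchange, biomass_id))
  exchange <- setdiff(exchange, biomass_id)

  internal <- setdiff(model$reaction_ids, c(exchange, transport, biomass_id))
  if (length(internal) == 0L)
    stop("degenerate model: no internal reactions remain after classification")
  structure(list(exchange_ids = exchange, transport_ids = transport,
                 internal_ids = internal, biomass_id = biomass_id),
            class = "reaction_partition")
}

#' @export
print.reaction_partition <- function(x, ...) {
  cat("<reaction_partition>\n")
  cat("  exchange:", length(x$exchange_ids),
      " transport:", length(x$transport_ids),
      " internal:", length(x$internal_ids),
      " biomass:", x$biomass_id, "\n")
  invisible(x)
}
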