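#' Construct a stoichiometric metabolic model
#'
#' A `metabolic_model` couples metabolites, reactions with flux bounds
#' (mmol/(g CDW h)), an objective reaction (typically a growth/demand
#' flux) and optional annotation lists used by the model-editing
#' operations (glycolysis/gluconeogenesis tags, amino-acid exchange tags,
#' proton and bicarbonate exchange ids).
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `compartment` and
#'   optionally `carbon` (carbon atoms, used by [check_carbon_balance()]).
#' @param reactions list; each element a list with `id`, `stoich` (named
#'   numeric, negative = consumed), `lb`, `ub`.
#' @param objective id of the reaction whose flux is maximised.
#' @param annotations named list of annotation vectors.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective,
                            annotations = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!"carbon" %in% names(metabolites)) metabolites$carbon <- NA_real_
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  names(reactions) <- rids
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions, objective = objective,
                      annotations = annotations),
                 class = "metabolic_model")
  validate_model(m)
}

#' Validate a metabolic model
#'
#' Checks that every stoichiometric entry references an existing
#' metabolite, that `lb <= ub` for every reaction and that the objective
#' reaction exists. Returns the model invisibly so it can be chained.
#' @param model a `metabolic_model`.
#' @export
validate_model <- function(model) {
  mids <- model$metabolites$id
  for (r in model$reactions) {
    bad <- setdiff(names(r$stoich), mids)
    if (length(bad))
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   r$id, paste(bad, collapse = ", ")))
    if (!length(r$stoich) || is.null(names(r$stoich)))
      stop(sprintf("reaction '%s' has malformed stoichiometry", r$id))
    if (r$lb > r$ub)
      stop(sprintf("reaction '%s' has lower bound above upper bound", r$id))
  }
  if (!model$objective %in% names(model$reactions))
    stop("objective reaction not present in model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, objective %s>\n",
              x$id, nrow(x$metabolites), length(x$reactions), x$objective))
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense matrix, metabolites x reactions.
#' @export
model_matrix <- function(model) {
  mids <- model$metabolites$id
  S <- matrix(0, nrow = length(mids), ncol = length(model$reactions),
              dimnames = list(mids, names(model$reactions)))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Reaction bounds of a model
#' @param model a `metabolic_model`.
#' @return two-column matrix (`lb`, `ub`) with reaction ids as rownames.
#' @export
model_bounds <- function(model) {
  cbind(lb = vapply(model$reactions, `[[`, 0, "lb"),
        ub = vapply(model$reactions, `[[`, 0, "ub"))
}

#' Set flux bounds on one reaction
#' @param model a `metabolic_model`.
#' @param rxn reaction id.
#' @param lb,ub new bounds; `NULL` leaves the current value.
#' @export
set_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  if (!rxn %in% names(model$reactions)) stop("unknown reaction: ", rxn)
  if (!is.null(lb)) model$reactions[[rxn]]$lb <- lb
  if (!is.null(ub)) model$reactions[[rxn]]$ub <- ub
  validate_model(model)
  model
}

#' Exchange reactions of a model
#'
#' An exchange reaction touches exactly one metabolite and moves it
#' across the system boundary; positive flux is secretion, negative flux
#' uptake.
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  names(model$reactions)[vapply(model$reactions, function(r)
    length(r$stoich) == 1L, TRUE)]
}

#' Check carbon conservation of internal reactions
#'
#' Every internal reaction (not an exchange, not tagged in
#' `annotations$carbon_exempt`, e.g. lumped biomass assembly) must
#' conserve carbon given the per-metabolite carbon counts. This is the
#' stoichiometric consistency check run on the bundled toy network.
#' @param model a `metabolic_model` with `carbon` metabolite annotation.
#' @param tol numeric tolerance.
#' @return `TRUE` invisibly; errors with the offending reaction otherwise.
#' @export
check_carbon_balance <- function(model, tol = 1e-9) {
  carbon <- stats::setNames(model$metabolites$carbon, model$metabolites$id)
  exempt <- c(exchange_reactions(model),
              model$annotations$carbon_exempt)
  for (r in model$reactions) {
    if (r$id %in% exempt) next
    bal <- sum(r$stoich * carbon[names(r$stoich)])
    if (is.na(bal))
      stop(sprintf("reaction '%s': metabolite without carbon annotation", r$id))
    if (abs(bal) > tol)
      stop(sprintf("reaction '%s' is not carbon balanced (imbalance %.3g)",
                   r$id, bal))
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# JSON serialisation (documented schema: metabolites, reactions with
# stoichiometry and bounds, objective, annotations)

#' Write a metabolic model to JSON
#' @param model a `metabolic_model`.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    id = model$id,
    metabolites = model$metabolites,
    reactions = lapply(unname(model$reactions), function(r)
      list(id = r$id, stoichiometry = as.list(r$stoich),
           lower_bound = r$lb, upper_bound = r$ub)),
    objective = model$objective,
    annotations = model$annotations
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Load a metabolic model from JSON or SBML
#'
#' JSON follows the package's documented schema (see
#' [write_model_json()]); SBML Level 3 with FBC-style flux bounds is
#' read via its `fbc` attributes so externally curated genome-scale
#' models can be used in place of the bundled toy network.
#'
#' @param path model file.
#' @param format `"json"` or `"sbml"`; guessed from the extension by
#'   default.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (format == "json") .load_model_json(path) else .load_model_sbml(path)
}

.load_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, compartment = m$compartment,
               carbon = if (is.null(m$carbon)) NA_real_ else
                 as.numeric(m$carbon),
               stringsAsFactors = FALSE)))
  reactions <- lapply(obj$reactions, function(r) {
    st <- vapply(r$stoichiometry, as.numeric, 0)
    list(id = r$id, stoich = st, lb = as.numeric(r$lower_bound),
         ub = as.numeric(r$upper_bound))
  })
  ann <- lapply(obj$annotations, function(a) {
    v <- unlist(a)
    if (is.null(v)) character(0) else v
  })
  metabolic_model(id = obj$id %||% "model",
                  metabolites = mets,
                  reactions = reactions,
                  objective = obj$objective,
                  annotations = ann)
}

.load_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rxn_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    get_side <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp, ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side("./s:listOfReactants/s:speciesReference", -1),
            get_side("./s:listOfProducts/s:speciesReference", +1))
    st <- tapply(st, names(st), sum)   # merge duplicated species refs
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lb_ref)) pval[[lb_ref]] else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref)) pval[[ub_ref]] else 1000
    list(id = rid, stoich = stats::setNames(as.numeric(st), names(st)),
         lb = lb, ub = ub)
  })
  obj_ref <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(obj_ref, "xml_missing"))
    stop("SBML file has no fbc objective")
  objective <- xml2::xml_attr(obj_ref, "reaction")
  metabolic_model(id = xml2::xml_attr(
                    xml2::xml_find_first(doc, ".//s:model", ns), "id"),
                  metabolites = mets, reactions = reactions,
                  objective = objective)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
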