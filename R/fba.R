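#' Flux balance analysis
#'
#' Maximises the model's objective flux subject to steady-state mass
#' balance (S v = 0) and the reaction bounds, via the package LP solver.
#' Infeasibility and unboundedness are reported through `status`, not as
#' errors, so screening loops can proceed.
#'
#' @param model a `metabolic_model`.
#' @return a `flux_solution`: list with `status`, `objective` and named
#'   `fluxes` (mmol/(g CDW h)).
#' @export
run_fba <- function(model) {
  S <- model_matrix(model)
  bounds <- model_bounds(model)
  obj <- as.numeric(names(model$reactions) == model$objective)
  sol <- solve_lp(obj, S, lb = bounds[, "lb"], ub = bounds[, "ub"],
                  maximize = TRUE)
  fluxes <- stats::setNames(sol$x, names(model$reactions))
  structure(list(status = sol$status, objective = sol$objective,
                 fluxes = fluxes, model_id = model$id),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution [%s] objective %.6g, %d reactions>\n",
              x$status, x$objective, length(x$fluxes)))
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimal and maximal flux subject to
#' mass balance, bounds, and the optimality constraint
#' `objective >= objective_fraction * FBA optimum`.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids (default all).
#' @param objective_fraction fraction of the FBA optimum that must be
#'   retained (1 = only the optimal face).
#' @return data.frame with `reaction`, `min`, `max`.
#' @export
run_fva <- function(model, reactions = names(model$reactions),
                    objective_fraction = 1.0) {
  base <- run_fba(model)
  if (base$status != "optimal")
    stop("FVA requires a feasible base model (status: ", base$status, ")")
  S <- model_matrix(model)
  bounds <- model_bounds(model)
  n <- ncol(S)
  cvec <- as.numeric(names(model$reactions) == model$objective)
  ## append row c'v - t = fraction * z*, slack t in [0, BIG]
  S2 <- rbind(cbind(S, 0), c(cvec, -1))
  b2 <- c(rep(0, nrow(S)), objective_fraction * base$objective)
  lb2 <- c(bounds[, "lb"], 0)
  ub2 <- c(bounds[, "ub"], 1e6)
  out <- lapply(reactions, function(r) {
    j <- match(r, names(model$reactions))
    if (is.na(j)) stop("unknown reaction: ", r)
    e <- rep(0, n + 1); e[j] <- 1
    lo <- solve_lp(e, S2, b = b2, lb = lb2, ub = ub2, maximize = FALSE)
    hi <- solve_lp(e, S2, b = b2, lb = lb2, ub = ub2, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for reaction ", r)
    c(lo$objective, hi$objective)
  })
  out <- do.call(rbind, out)
  data.frame(reaction = reactions, min = out[, 1], max = out[, 2],
             stringsAsFactors = FALSE)
}

#' Add sodium and potassium exchange reactions
#'
#' Genome-scale HEK293 reconstructions have been distributed without
#' Na+/K+ exchange reactions even though ion-utilising reactions are
#' present; in their absence those reactions can carry no steady-state
#' flux. This adds open `EX_na` / `EX_k` exchanges on the extracellular
#' ion metabolites (idempotent).
#'
#' @param model a `metabolic_model` whose annotations name the
#'   extracellular ion metabolites (`annotations$ion_metabolites`).
#' @return the extended model.
#' @export
add_ion_exchanges <- function(model) {
  ions <- model$annotations$ion_metabolites
  if (is.null(ions) || !all(c("na", "k") %in% names(ions)))
    stop("model does not annotate extracellular Na+/K+ metabolites")
  if (!all(ions %in% model$metabolites$id))
    stop("annotated ion metabolites are absent from the model")
  for (nm in c(na = "EX_na", k = "EX_k")[c("na", "k")]) {
    if (nm %in% names(model$reactions)) next   # idempotent
    ion <- ions[[if (nm == "EX_na") "na" else "k"]]
    model$reactions[[nm]] <- list(id = nm,
                                  stoich = stats::setNames(-1, ion),
                                  lb = -1000, ub = 1000)
  }
  validate_model(model)
  model
}

#' Constrain the model to block gluconeogenesis
#'
#' Reactions shared by glycolysis and gluconeogenesis are restricted to
#' the glycolytic direction; triosephosphate isomerase remains
#' bidirectional; phosphoenolpyruvate carboxykinase and fructose
#' bisphosphatase are constrained to zero flux. Applied when the culture
#' never starves for glucose, in which case gluconeogenic flux would be
#' a modelling artefact.
#'
#' @param model a `metabolic_model` with `shared_glycolysis`, `pepck`
#'   and `fbpase` annotations (shared reactions written in the
#'   glycolytic direction).
#' @return the constrained model.
#' @export
block_gluconeogenesis <- function(model) {
  ann <- model$annotations
  if (is.null(ann$shared_glycolysis) || is.null(ann$pepck) ||
      is.null(ann$fbpase))
    stop("model lacks glycolysis/gluconeogenesis annotations")
  for (r in ann$shared_glycolysis) {
    if (identical(r, ann$tpi)) next
    model <- set_bounds(model, r, lb = 0)
  }
  for (r in c(ann$pepck, ann$fbpase))
    model <- set_bounds(model, r, lb = 0, ub = 0)
  model
}

#' Iteratively tighten amino-acid exchange bounds
#'
#' Media composition is usually proprietary, so feasible amino-acid
#' exchange fluxes are found by FVA: whenever the feasible range of a
#' tagged amino-acid exchange exceeds the flux equivalent of typical
#' media concentrations, that exchange is clamped and the FVA repeated
#' until no range exceeds the cap. Defaults are +/-1 mmol/(g CDW h) and
#' +/-0.5 for a tagged subset (branched-chain amino acids in the
#' original application).
#'
#' @param model a `metabolic_model` with `amino_acid_exchanges` (and
#'   optionally `amino_acid_exchanges_tight`) annotations.
#' @param cap default symmetric cap, mmol/(g CDW h).
#' @param cap_tight cap for the tagged subset.
#' @param objective_fraction passed to [run_fva()].
#' @param max_iter iteration guard.
#' @return list with the tightened `model` and an `iterations` log
#'   (one data.frame per clamping round).
#' @export
tighten_amino_acid_bounds <- function(model, cap = 1, cap_tight = 0.5,
                                      objective_fraction = 0,
                                      max_iter = 10) {
  aa <- model$annotations$amino_acid_exchanges
  if (is.null(aa)) stop("model lacks amino-acid exchange annotations")
  tight <- model$annotations$amino_acid_exchanges_tight %||% character(0)
  caps <- stats::setNames(ifelse(aa %in% tight, cap_tight, cap), aa)
  log <- list()
  for (it in seq_len(max_iter)) {
    fva <- run_fva(model, aa, objective_fraction = objective_fraction)
    lim <- caps[fva$reaction]
    offend <- fva$min < -lim - 1e-9 | fva$max > lim + 1e-9
    if (!any(offend)) {
      return(list(model = model, iterations = log,
                  fva = fva, converged = TRUE))
    }
    round_log <- fva[offend, , drop = FALSE]
    round_log$cap <- lim[offend]
    log[[length(log) + 1L]] <- round_log
    for (r in fva$reaction[offend])
      model <- set_bounds(model, r, lb = -caps[[r]], ub = caps[[r]])
  }
  stop("amino-acid bound tightening did not converge; see iteration log")
}

#' Derive the extracellular-pH constraint
#'
#' Implements the pH simulation strategy: the culture pH is converted to
#' a molar proton concentration A = 10^-pH; the fixed per-cell proton
#' export flux is converted to a molar concentration
#' B = q_H * X * dt * 1e-3 (biomass density X in g CDW/L over a
#' reference interval dt); since B must exceed A, the surplus protons
#' are neutralised (1 mol base per mol acid) by bicarbonate export whose
#' flux is the A-B difference converted back to flux units.
#'
#' @param ph culture pH at the time point of interest.
#' @param proton_export_flux fixed proton export, mmol/(g CDW h), > 0.
#' @param biomass_density culture biomass density, g CDW/L.
#' @param delta_t reference interval, h.
#' @return a `ph_constraint`: list with `ph`, `proton_export_flux`,
#'   `conc_A`, `conc_B` (mol/L) and `bicarbonate_efflux`
#'   (mmol/(g CDW h)).
#' @export
derive_ph_constraint <- function(ph, proton_export_flux,
                                 biomass_density = 0.5, delta_t = 1) {
  if (proton_export_flux <= 0) stop("proton export flux must be positive")
  if (biomass_density <= 0 || delta_t <= 0)
    stop("biomass density and interval must be positive")
  conc_A <- 10^(-ph)
  conv <- biomass_density * delta_t * 1e-3     # mmol/(g h) -> mol/L
  conc_B <- proton_export_flux * conv
  if (conc_B <= conc_A)
    stop(sprintf(paste("proton-export concentration B (%.3g mol/L) does not",
                       "exceed the proton concentration A (%.3g mol/L) at",
                       "pH %.2f; increase the proton export flux"),
                 conc_B, conc_A, ph))
  structure(list(ph = ph, proton_export_flux = proton_export_flux,
                 conc_A = conc_A, conc_B = conc_B,
                 biomass_density = biomass_density, delta_t = delta_t,
                 bicarbonate_efflux = (conc_B - conc_A) / conv),
            class = "ph_constraint")
}

#' @export
print.ph_constraint <- function(x, ...) {
  cat(sprintf(paste0("<ph_constraint pH %.2f: A = %.4g mol/L, ",
                     "B = %.4g mol/L, HCO3- efflux %.6g mmol/(g CDW h)>\n"),
              x$ph, x$conc_A, x$conc_B, x$bicarbonate_efflux))
  invisible(x)
}

#' Apply a pH constraint to a model
#'
#' Fixes the proton exchange at the proton export flux and the
#' bicarbonate exchange at the derived bicarbonate efflux (equality
#' bounds), simulating HCO3- export that holds the culture at the given
#' pH.
#'
#' @param model a `metabolic_model` with `proton_exchange` and
#'   `bicarbonate_exchange` annotations.
#' @param constraint a `ph_constraint` from [derive_ph_constraint()]
#'   (or a hand-built list with the same fields, e.g. to explore
#'   bicarbonate uptake scenarios).
#' @return the constrained model.
#' @export
apply_ph_constraint <- function(model, constraint) {
  ann <- model$annotations
  if (is.null(ann$proton_exchange) || is.null(ann$bicarbonate_exchange))
    stop("model lacks proton/bicarbonate exchange annotations")
  model <- set_bounds(model, ann$proton_exchange,
                      lb = constraint$proton_export_flux,
                      ub = constraint$proton_export_flux)
  set_bounds(model, ann$bicarbonate_exchange,
             lb = constraint$bicarbonate_efflux,
             ub = constraint$bicarbonate_efflux)
}

#' Exchange flux from offline concentration measurements
#'
#' Converts a concentration change between two offline samples into a
#' culture-specific exchange flux per g cell dry weight, using the
#' log-mean of the endpoint biomass densities as the time-averaged
#' biomass (exact under exponential growth). Consumption is negative.
#'
#' @param conc_t1,conc_t2 metabolite concentrations, mmol/L.
#' @param vcc_t1,vcc_t2 viable cell concentrations, cells/mL.
#' @param t1,t2 sample times, h (`t2 > t1`).
#' @param cdw_pg cell dry weight, pg/cell (default 514).
#' @return flux q, mmol/(g CDW h).
#' @export
exchange_flux_from_offline <- function(conc_t1, conc_t2, vcc_t1, vcc_t2,
                                       t1, t2, cdw_pg = 514) {
  if (t2 <= t1) stop("t2 must exceed t1")
  if (vcc_t1 <= 0 || vcc_t2 <= 0) stop("VCC must be positive")
  ## cells/mL * pg/cell -> g CDW/L
  x1 <- vcc_t1 * cdw_pg * 1e-9
  x2 <- vcc_t2 * cdw_pg * 1e-9
  xbar <- if (abs(x2 - x1) < 1e-12 * max(x1, x2)) x1 else
    (x2 - x1) / log(x2 / x1)
  (conc_t2 - conc_t1) / (xbar * (t2 - t1))
}

#' Compare two flux solutions
#'
#' Absolute per-reaction flux differences between two solutions on the
#' same reaction set, with the count of reactions differing beyond a
#' tolerance; the report is sorted by decreasing difference.
#'
#' @param a,b `flux_solution` objects over the same reactions.
#' @param tol difference threshold, mmol/(g CDW h).
#' @return list with `table` (reaction, flux_a, flux_b, abs_diff) and
#'   `n_differing`.
#' @export
compare_solutions <- function(a, b, tol = 1e-6) {
  if (!identical(sort(names(a$fluxes)), sort(names(b$fluxes))))
    stop("flux solutions cover different reaction sets")
  fb <- b$fluxes[names(a$fluxes)]
  d <- abs(a$fluxes - fb)
  tab <- data.frame(reaction = names(a$fluxes), flux_a = unname(a$fluxes),
                    flux_b = unname(fb), abs_diff = unname(d),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$abs_diff), ]
  rownames(tab) <- NULL
  list(table = tab, n_differing = sum(d > tol))
}

#' Export a flux map and a flux-constrained model copy
#'
#' Writes the optimal flux vector as a JSON reaction-to-flux map (the
#' format flux-map viewers such as Escher consume as reaction data) and
#' returns a copy of the model with every reaction fixed at its solution
#' flux, so re-solving reproduces the identical distribution.
#'
#' @param solution an optimal `flux_solution`.
#' @param model the `metabolic_model` it was computed on.
#' @param path output JSON path.
#' @return invisibly, a list with the `path` and the flux-`constrained`
#'   model copy.
#' @export
export_flux_map <- function(solution, model, path) {
  if (solution$status != "optimal")
    stop("flux map export requires an optimal solution")
  jsonlite::write_json(as.list(solution$fluxes), path, auto_unbox = TRUE,
                       digits = NA)
  constrained <- model
  for (r in names(model$reactions)) {
    f <- solution$fluxes[[r]]
    constrained$reactions[[r]]$lb <- f
    constrained$reactions[[r]]$ub <- f
  }
  invisible(list(path = path, constrained = constrained))
}
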