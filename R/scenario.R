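# Growth scenarios: a scenario fixes the environment (maximum uptake rates
# on exchange reactions), the non-growth-associated maintenance (NGAM, an
# equality-constrained ATP-hydrolysis flux), and any fixed fluxes (e.g. the
# EPS export rate), then asks for the maximal-growth flux state and its
# variability.
#
# Exchange convention: exchange reactions are written `met_e -->` (flux > 0
# secretes, flux < 0 takes up); an uptake bound u maps to lower bound -u.

#' Construct a scenario configuration
#'
#' @param name scenario label.
#' @param uptake_bounds named numeric vector: exchange reaction id ->
#'   maximum uptake (mmol gDW^-1 h^-1, non-negative).
#' @param ngam_flux fixed ATP-hydrolysis flux (mmol ATP gDW^-1 h^-1, >= 0)
#'   applied to `ngam_id`.
#' @param fixed_fluxes named numeric vector: reaction id -> fixed flux value.
#' @param objective_id objective override (default: model objective).
#' @param ngam_id id of the ATP-hydrolysis maintenance reaction.
#' @return object of class `"scenario_config"`.
#' @export
scenario_config <- function(name, uptake_bounds = numeric(0), ngam_flux = 0,
                            fixed_fluxes = numeric(0),
                            objective_id = NA_character_,
                            ngam_id = "R_ngam") {
  stopifnot(ngam_flux >= 0)
  if (length(uptake_bounds) && any(uptake_bounds < 0))
    stop("uptake bounds must be non-negative")
  structure(list(name = name, uptake_bounds = uptake_bounds,
                 ngam_flux = ngam_flux, fixed_fluxes = fixed_fluxes,
                 objective_id = objective_id, ngam_id = ngam_id),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML
#'
#' Fields: `name`, `uptakes` (map exchange -> max uptake), `ngam`, `fixed`
#' (map reaction -> value), `objective`.
#' @param path YAML file.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario_config(name = y$name %||% basename(path),
                  uptake_bounds = unlist(y$uptakes %||% list()),
                  ngam_flux = as.numeric(y$ngam %||% 0),
                  fixed_fluxes = unlist(y$fixed %||% list()),
                  objective_id = y$objective %||% NA_character_)
}

#' Bound overrides implementing a scenario
#' @param model a `metabolic_model`.
#' @param config a `scenario_config`.
#' @return named list `reaction id -> c(lb, ub)` for [solve_fba].
#' @export
scenario_constraints <- function(model, config) {
  cons <- list()
  for (id in names(config$uptake_bounds)) {
    r <- model$reactions[[id]]
    if (is.null(r)) stop("scenario uptake on unknown reaction: ", id)
    cons[[id]] <- c(-config$uptake_bounds[[id]], r$upper_bound)
  }
  if (config$ngam_flux > 0 || !is.null(model$reactions[[config$ngam_id]])) {
    if (is.null(model$reactions[[config$ngam_id]]))
      stop("model has no maintenance reaction '", config$ngam_id, "'")
    cons[[config$ngam_id]] <- c(config$ngam_flux, config$ngam_flux)
  }
  for (id in names(config$fixed_fluxes)) {
    if (is.null(model$reactions[[id]]))
      stop("scenario fixes unknown reaction: ", id)
    cons[[id]] <- rep(config$fixed_fluxes[[id]], 2)
  }
  cons
}

#' Uptake rate normalized to 1 mmol carbon per gDW per hour
#'
#' @param model a `metabolic_model`.
#' @param met_id carbon-source metabolite id (carbon count must be known and
#'   positive).
#' @return mmol gDW^-1 h^-1, i.e. `1 / carbon_count`.
#' @export
normalized_uptake <- function(model, met_id) {
  cc <- carbon_count(model, met_id)
  if (cc == 0) stop("zero-carbon source: ", met_id)
  1 / cc
}

#' Round half-up to a number of decimals (printed-value convention)
#' @param x numeric. @param digits decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' EPS export flux routing a carbon fraction into exopolysaccharide
#'
#' Returns the flux f such that f x (carbon atoms per EPS unit) equals
#' `eps_carbon_fraction` x (uptake x carbons per substrate molecule).
#'
#' @param glucose_uptake substrate uptake rate (mmol gDW^-1 h^-1).
#' @param eps_carbon_fraction fraction of imported carbon routed to EPS.
#' @param eps_stoichiometry named vector: EPS monomer -> mmol per EPS unit.
#' @param monomer_carbons named vector: monomer -> carbon atoms (all six
#'   for the documented hexose EPS unit).
#' @param substrate_carbons carbons per substrate molecule (glucose: 6).
#' @return mmol gDW^-1 h^-1 (unrounded; apply [round_half_up] for printed
#'   precision).
#' @export
compute_eps_flux <- function(glucose_uptake, eps_carbon_fraction,
                             eps_stoichiometry, monomer_carbons,
                             substrate_carbons = 6) {
  cc <- monomer_carbons[names(eps_stoichiometry)]
  if (anyNA(cc)) stop("missing carbon count for EPS monomer(s): ",
                      paste(names(eps_stoichiometry)[is.na(cc)], collapse = ", "))
  unit_c <- sum(eps_stoichiometry * cc)
  if (unit_c <= 0) stop("zero-carbon EPS unit")
  eps_carbon_fraction * glucose_uptake * substrate_carbons / unit_c
}

carbon_of <- function(model) {
  stats::setNames(model$metabolites$carbon, model$metabolites$id)
}

#' Run a growth scenario
#'
#' Solves parsimonious FBA under the scenario constraints and summarizes:
#' biomass flux, CO2 exchange, carbon usage ratio (carbon into biomass /
#' carbon imported), active reaction count, and (optionally) FVA intervals.
#'
#' @param model a `metabolic_model`.
#' @param config a `scenario_config`.
#' @param fva run FVA as part of the report.
#' @param fva_fraction objective fraction for the report FVA.
#' @param co2_exchange id of the CO2 exchange reaction.
#' @return object of class `"scenario_report"`.
#' @export
run_scenario <- function(model, config, fva = TRUE, fva_fraction = 1,
                         co2_exchange = "EX_co2_e") {
  cons <- scenario_constraints(model, config)
  fd <- solve_fba(model, cons, objective_id =
                    if (is.na(config$objective_id)) NULL else config$objective_id,
                  parsimonious = TRUE)
  if (fd$status != "optimal") {
    return(structure(list(config = config, status = fd$status, fba = fd,
                          solver = SOLVER_META),
                     class = "scenario_report"))
  }
  carb <- carbon_of(model)
  imported <- 0; secreted_c <- 0
  for (r in model$reactions) {
    if (!r$is_exchange) next
    met <- names(r$stoichiometry)
    f <- fd$flux[[r$id]]  # exchanges are written `met_e -->`: f < 0 imports
    cc <- carb[[met]]
    if (is.na(cc) || cc == 0) next
    if (f < 0) imported <- imported - f * cc else secreted_c <- secreted_c + f * cc
  }
  bm <- model$reactions[[fd$objective_id]]
  bio_c <- 0
  for (met in names(bm$stoichiometry)) {
    cc <- carb[[met]]
    if (!is.na(cc)) bio_c <- bio_c - bm$stoichiometry[[met]] * cc
  }
  biomass_carbon_flux <- bio_c * fd$objective_value
  out <- list(config = config, status = "optimal", fba = fd,
              biomass_flux = fd$objective_value,
              co2_flux = unname(fd$flux[co2_exchange]),
              carbon_imported = imported,
              biomass_carbon = biomass_carbon_flux,
              carbon_usage_ratio = if (imported > 0)
                biomass_carbon_flux / imported else NA_real_,
              active_reactions = sum(abs(fd$flux) > 1e-6),
              solver = SOLVER_META)
  if (fva) {
    out$fva <- run_fva(model, cons, objective_fraction = fva_fraction,
                       reference = fd)
    out$fva <- classify_variability(out$fva)
  }
  class(out) <- "scenario_report"
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("scenario '", x$config$name, "': ", x$status, sep = "")
  if (x$status == "optimal")
    cat(sprintf(": mu = %.4f h^-1, carbon usage %.1f%%, %d active reactions",
                x$biomass_flux, 100 * x$carbon_usage_ratio, x$active_reactions))
  cat("\n")
  invisible(x)
}

#' Carbon-source growth scan at 1 mmol C gDW^-1 h^-1
#'
#' For each catalogue entry with a curated route, opens only that source's
#' exchange at `1/carbons` uptake, fixes NGAM, and records the biomass flux
#' and its value relative to glucose (= 100 by construction). Sources
#' without a route are reported with status `"unsupported"`, infeasible ones
#' with `"infeasible"`; the output has exactly one row per catalogue source.
#'
#' @param model a `metabolic_model`.
#' @param catalogue data frame with columns source, exchange_id, carbons,
#'   entry_point, supported (see [read_carbon_source_catalogue]).
#' @param ngam fixed maintenance flux for the scan (0.67, fitted to the
#'   observed 25% carbon usage ratio on glucose).
#' @param reference_source source against which percentages are computed.
#' @return data frame: source, entry_point, carbons, uptake, status,
#'   biomass_flux, relative_to_glucose.
#' @export
run_carbon_source_scan <- function(model, catalogue, ngam = 0.67,
                                   reference_source = "glucose") {
  run_one <- function(row) {
    if (!isTRUE(row$supported) || is.na(row$exchange_id))
      return(list(status = "unsupported", uptake = NA_real_, mu = NA_real_))
    up <- 1 / row$carbons
    cfg <- scenario_config(paste0("scan_", row$source),
                           uptake_bounds = stats::setNames(up, row$exchange_id),
                           ngam_flux = ngam)
    fd <- tryCatch(solve_fba(model, scenario_constraints(model, cfg)),
                   error = function(e) NULL)
    if (is.null(fd) || fd$status != "optimal" || fd$objective_value <= 1e-9)
      return(list(status = "infeasible", uptake = up, mu = 0))
    list(status = "ok", uptake = up, mu = fd$objective_value)
  }
  res <- lapply(seq_len(nrow(catalogue)), function(i) run_one(catalogue[i, ]))
  mu <- vapply(res, function(r) r$mu %||% NA_real_, 0)
  ref <- mu[match(reference_source, catalogue$source)]
  if (is.na(ref) || ref <= 0) stop("reference source '", reference_source,
                                   "' did not grow")
  data.frame(source = catalogue$source,
             entry_point = catalogue$entry_point,
             carbons = catalogue$carbons,
             uptake = vapply(res, function(r) r$uptake %||% NA_real_, 0),
             status = vapply(res, `[[`, "", "status"),
             biomass_flux = mu,
             relative_to_glucose = 100 * mu / ref)
}

#' Read the carbon-source catalogue
#'
#' Tab-separated file: source, formula, carbons, entry_point, exchange_id,
#' supported (TRUE/FALSE), notes.
#' @param path TSV file (default: the catalogue shipped with the package).
#' @export
read_carbon_source_catalogue <- function(path = system.file(
  "extdata", "carbon_sources.tsv", package = "sulfoflux")) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  ct$supported <- as.logical(ct$supported)
  ct
}

#' Serialize a scenario report
#'
#' Writes the flux distribution (and FVA intervals, if present) as TSV and a
#' JSON summary carrying the run metadata (scenario configuration echo and
#' solver backend/tolerances), making outputs traceable and hash-comparable.
#'
#' @param report a `scenario_report`.
#' @param prefix output path prefix; writes `<prefix>_fluxes.tsv` and
#'   `<prefix>_summary.json`.
#' @return invisibly, the paths written.
#' @export
write_scenario_report <- function(report, prefix) {
  paths <- character(0)
  if (report$status == "optimal") {
    tab <- data.frame(id = names(report$fba$flux),
                      flux = round(unname(report$fba$flux), 9))
    if (!is.null(report$fva)) {
      m <- match(tab$id, report$fva$id)
      tab$min_flux <- round(report$fva$min_flux[m], 9)
      tab$max_flux <- round(report$fva$max_flux[m], 9)
      tab$category <- report$fva$category[m]
    }
    p1 <- paste0(prefix, "_fluxes.tsv")
    utils::write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p1)
  }
  summ <- list(scenario = report$config[c("name", "uptake_bounds", "ngam_flux",
                                          "fixed_fluxes")],
               status = report$status,
               biomass_flux = report$biomass_flux,
               co2_flux = report$co2_flux,
               carbon_usage_ratio = report$carbon_usage_ratio,
               active_reactions = report$active_reactions,
               solver = report$solver)
  p2 <- paste0(prefix, "_summary.json")
  jsonlite::write_json(summ, p2, auto_unbox = TRUE, digits = 9, pretty = TRUE)
  invisible(c(paths, p2))
}
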