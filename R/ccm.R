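# Curated Sulfolobus solfataricus central-carbon-metabolism fixture.
# The reaction list, figure-enzyme manifest, biomass composition and
# scenario configurations ship as plain-text files under inst/extdata; this
# module assembles them into a ready-to-solve model.

ccm_file <- function(...) system.file("extdata", ..., package = "sulfoflux")

#' Build the curated S. solfataricus central-carbon model
#'
#' Parses the shipped reaction list, builds the proxy biomass reaction from
#' the shipped composition, and returns the assembled model. Options toggle
#' optional subsystems.
#'
#' @param include_hphb include the hydroxypropionate-hydroxybutyrate cycle
#'   (bicarbonate fixation); if FALSE its fluxes are clamped to zero.
#' @param include_phenol include the phenol degradation route.
#' @param pentose_route `"oxoglutarate"` (default oxidative route to
#'   2-oxoglutarate), `"malate"` (alternative entry), or `"both"`.
#' @param biomass_composition optional `biomass_composition` override.
#' @return a `metabolic_model` with objective `R_biomass`.
#' @export
build_ccm_model <- function(include_hphb = TRUE, include_phenol = TRUE,
                            pentose_route = c("oxoglutarate", "malate", "both"),
                            biomass_composition = NULL) {
  pentose_route <- match.arg(pentose_route)
  model <- parse_model_text(ccm_file("sso_ccm.txt"))
  comp <- biomass_composition %||%
    read_biomass_composition(ccm_file("sso_biomass.yml"))
  bm <- build_biomass_reaction(comp, id = "R_biomass")
  model$reactions[["R_biomass"]] <- bm
  model$objective_id <- "R_biomass"
  clamp <- function(model, ids) {
    for (id in ids) {
      model$reactions[[id]]$lower_bound <- 0
      model$reactions[[id]]$upper_bound <- 0
    }
    model
  }
  if (!include_hphb) model <- clamp(model, ccm_subsystem_reactions(
    model, "Hydroxypropionate-hydroxybutyrate cycle"))
  if (!include_phenol) model <- clamp(model, c(
    ccm_subsystem_reactions(model, "Phenol degradation"), "R_t_phenol"))
  if (pentose_route == "oxoglutarate") {
    # file default already clamps R_pentmal
  } else if (pentose_route == "malate") {
    model$reactions[["R_pentmal"]]$upper_bound <- Inf
    model <- clamp(model, c("R_kdxd", "R_asadh"))
  } else {
    model$reactions[["R_pentmal"]]$upper_bound <- Inf
  }
  # biomass references metabolites absent from the parsed reaction set only
  # if the composition was overridden; re-validate
  missing <- setdiff(names(bm$stoichiometry), model$metabolites$id)
  if (length(missing))
    stop("biomass uses metabolites absent from the fixture: ",
         paste(missing, collapse = ", "))
  metabolic_model(model$metabolites, model$reactions, "R_biomass")
}

#' Reactions of a fixture subsystem
#' @param model a `metabolic_model`.
#' @param subsystem prefix-matched subsystem label.
#' @export
ccm_subsystem_reactions <- function(model, subsystem) {
  hits <- vapply(model$reactions, function(r)
    !is.na(r$subsystem) && startsWith(r$subsystem, subsystem), TRUE)
  names(model$reactions)[hits]
}

#' Figure-enzyme manifest of the fixture
#'
#' Maps every numbered enzyme of the fixture's pathway maps (central carbon
#' metabolism 1-48, phenol 49-55, bicarbonate-fixation cycle 1-16) to its
#' fixture reaction(s), gene id, and any merge/pooling note.
#' @return data frame: figure, index, enzyme, reaction_ids, gene, note.
#' @export
fixture_manifest <- function() {
  utils::read.delim(ccm_file("sso_manifest.tsv"), stringsAsFactors = FALSE,
                    fill = TRUE)
}

#' Shipped scenario configurations
#' @param name one of `"glucose"`, `"glucose_eps"`, `"hco3"`, `"phenol"`,
#'   `"carbon_scan"`.
#' @return a `scenario_config`.
#' @export
ccm_scenario <- function(name = c("glucose", "glucose_eps", "hco3", "phenol",
                                  "carbon_scan")) {
  name <- match.arg(name)
  read_scenario_config(ccm_file("scenarios", paste0(name, ".yml")))
}

#' Curated reaction sets for per-pathway energy accounting
#'
#' @return named list of character vectors: `glycolysis_semi` (glucose ->
#'   pyruvate via the semi-phosphorylative branch), `glycolysis_nonp`
#'   (non-phosphorylative branch), `glycerol` (glycerol -> pyruvate),
#'   `hphb` (bicarbonate-fixation cycle), `pentose_ox` (xylose ->
#'   2-oxoglutarate), `phenol` (phenol -> pyruvate + acetyl-CoA).
#' @export
ccm_routes <- function() {
  list(
    glycolysis_semi = c("R_gdh", "R_gnl", "R_gad", "R_kdgk", "R_kdpga",
                        "R_gapn", "R_pgm", "R_eno", "R_pk"),
    glycolysis_nonp = c("R_gdh", "R_gnl", "R_gad", "R_kdga", "R_aldh",
                        "R_glyk", "R_eno", "R_pk"),
    glycerol = c("R_glk", "R_g3pd", "R_tpi", "R_gapn", "R_pgm", "R_eno",
                 "R_pk"),
    hphb = c("R_acat", "R_acc", "R_mcr", "R_msr", "R_hpcl", "R_hpcd",
             "R_acrr", "R_pcc", "R_mce", "R_mcm", "R_scr", "R_ssr",
             "R_hbcl", "R_hbcd", "R_ech", "R_hbd"),
    pentose_ox = c("R_xdh", "R_xlh", "R_xad", "R_kdxd", "R_asadh"),
    phenol = c("R_pmo", "R_c23d", "R_hmsh", "R_opeh", "R_hkva", "R_aldd",
               "R_acs", "R_adk", "R_ppa")
  )
}

#' Genes of the reverse ribulose-monophosphate pathway
#' @param model the fixture model.
#' @export
ccm_rump_genes <- function(model) {
  ids <- ccm_subsystem_reactions(model, "Reverse ribulose monophosphate")
  sort(unique(unlist(lapply(model$reactions[ids], function(r)
    gpr_genes_of(r$gpr)))))
}

#' EPS unit stoichiometry and monomer carbon counts of the fixture
#' @return list(stoichiometry, carbons) for [compute_eps_flux].
#' @export
ccm_eps_unit <- function() {
  list(stoichiometry = c(glc = 1.2, man = 1, nsg = 0.18, gal = 0.13),
       carbons = c(glc = 6, man = 6, nsg = 6, gal = 6))
}
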