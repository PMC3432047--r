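# Minimal SBML Level 3 Version 1 + fbc v2 interchange, written directly on
# xml2. Covers what the model contract needs: compartments, species (with
# chemical formulas), reactions with stoichiometry, flux bounds as fbc
# parameters, gene-product associations, and the active objective.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

bound_param_value <- function(x) {
  if (is.infinite(x)) sign(x) * FLUX_BOUND_SENTINEL * 10 else x
}

gpr_to_xml <- function(parent, expr) {
  add_assoc <- function(node, e) {
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "(") return(add_assoc(node, e[[2]]))
      tag <- if (op == "&") "fbc:and" else if (op == "|") "fbc:or"
             else stop("unsupported GPR operator: ", op)
      sub <- xml2::xml_add_child(node, tag)
      add_assoc(sub, e[[2]]); add_assoc(sub, e[[3]])
    } else {
      xml2::xml_add_child(node, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", as.character(e)))
    }
    invisible(NULL)
  }
  e <- parse_gpr(expr)
  if (is.null(e)) return(invisible(NULL))
  node <- xml2::xml_add_child(parent, "fbc:geneProductAssociation")
  add_assoc(node, e)
}

#' Export a model as SBML Level 3 (fbc v2)
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "sulfoflux_model",
                             "fbc:strict" = "true")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in c("c", "e"))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    node <- xml2::xml_add_child(sps, "species",
      id = paste0("M_", mt$id),
      name = mt$name,
      compartment = if (mt$compartment == "external") "e" else "c",
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(mt$formula))
      xml2::xml_set_attr(node, "fbc:chemicalFormula", mt$formula)
  }
  bnd <- model_bounds(model)
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  pvals <- sort(unique(vapply(c(bnd$lb, bnd$ub), bound_param_value, 0)))
  pid_of <- function(v) sprintf("bnd_%s", gsub("[^0-9A-Za-z]", "_",
                                               format(v, scientific = FALSE)))
  for (v in pvals)
    xml2::xml_add_child(pars, "parameter", id = pid_of(v),
                        value = format(v, digits = 15, scientific = FALSE),
                        constant = "true")
  gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model_genes(model))
    xml2::xml_add_child(gps, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                        "fbc:label" = g)
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    node <- xml2::xml_add_child(rl, "reaction",
      id = paste0("R_", r$id),
      reversible = tolower(as.character(is_reversible(r))),
      fast = "false",
      "fbc:lowerFluxBound" = pid_of(bound_param_value(r$lower_bound)),
      "fbc:upperFluxBound" = pid_of(bound_param_value(r$upper_bound)))
    if (!is.na(r$subsystem)) xml2::xml_set_attr(node, "sfx_subsystem", r$subsystem)
    if (!is.na(r$confidence))
      xml2::xml_set_attr(node, "sfx_confidence", as.character(r$confidence))
    if (r$is_exchange) xml2::xml_set_attr(node, "sfx_exchange", "true")
    st <- r$stoichiometry
    lhs <- st[st < 0]; rhs <- st[st > 0]
    if (length(lhs)) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (k in seq_along(lhs))
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", names(lhs)[k]),
                            stoichiometry = format(-lhs[[k]], digits = 15, scientific = FALSE),
                            constant = "true")
    }
    if (length(rhs)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (k in seq_along(rhs))
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", names(rhs)[k]),
                            stoichiometry = format(rhs[[k]], digits = 15, scientific = FALSE),
                            constant = "true")
    }
    gpr_to_xml(node, r$gpr)
  }
  if (!is.na(model$objective_id)) {
    objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lof <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lof, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", model$objective_id),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

xml_gpr_to_string <- function(node) {
  walk <- function(nd) {
    nm <- xml2::xml_name(nd)
    if (nm == "geneProductRef") {
      g <- xml2::xml_attr(nd, "geneProduct")
      return(sub("^G_", "", g))
    }
    kids <- xml2::xml_children(nd)
    parts <- vapply(kids, walk, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }
  kids <- xml2::xml_children(node)
  if (!length(kids)) return(NA_character_)
  walk(kids[[1]])
}

#' Import a model from SBML Level 3 (fbc v2)
#'
#' Unprefixed species/reaction ids (`M_`/`R_` stripped) become model ids.
#' Species without a compartment are an error. Reactions lacking fbc flux
#' bounds default to reversibility-based sentinels with a warning.
#'
#' @param path SBML file.
#' @return a `metabolic_model`.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  strip <- function(x, pre) sub(paste0("^", pre), "", x)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sentinelize <- function(v) {
    if (is.na(v)) return(v)
    if (abs(v) >= FLUX_BOUND_SENTINEL * 10 * (1 - 1e-12)) sign(v) * Inf else v
  }
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(species, function(sp) {
    comp <- xml2::xml_attr(sp, "compartment")
    if (is.na(comp)) stop("SBML species without compartment: ",
                          xml2::xml_attr(sp, "id"))
    metabolite(strip(xml2::xml_attr(sp, "id"), "M_"),
               name = xml2::xml_attr(sp, "name") %|na|%
                 strip(xml2::xml_attr(sp, "id"), "M_"),
               compartment = if (comp == "e") "external" else "cytosol",
               formula = xml2::xml_attr(sp, "chemicalFormula"))
  }))
  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(rn) {
    id <- strip(xml2::xml_attr(rn, "id"), "R_")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)) {
      met <- strip(xml2::xml_attr(sr, "species"), "M_")
      st[met] <- (if (is.na(st[met])) 0 else st[met]) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)) {
      met <- strip(xml2::xml_attr(sr, "species"), "M_")
      st[met] <- (if (is.na(st[met])) 0 else st[met]) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp)) {
      warning("reaction ", id, ": missing flux bounds; defaulting from ",
              "reversible attribute")
      rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
      lb <- if (rev) -Inf else 0; ub <- Inf
    } else {
      lb <- sentinelize(pval[[lbp]]); ub <- sentinelize(pval[[ubp]])
    }
    gnode <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gnode, "xml_missing")) NA_character_
           else xml_gpr_to_string(gnode)
    conf <- xml2::xml_attr(rn, "sfx_confidence")
    ex <- xml2::xml_attr(rn, "sfx_exchange")
    reaction(id, st, lower_bound = lb, upper_bound = ub, gpr = gpr,
             subsystem = xml2::xml_attr(rn, "sfx_subsystem"),
             confidence = if (is.na(conf)) NA_integer_ else as.integer(conf),
             is_exchange = if (identical(ex, "true")) TRUE else NULL)
  })
  obj <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  objective <- if (inherits(obj, "xml_missing")) NA_character_
               else strip(xml2::xml_attr(obj, "reaction"), "R_")
  metabolic_model(mets, rxns, objective_id = objective)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a
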