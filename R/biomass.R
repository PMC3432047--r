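# Biomass objective construction. A biomass composition lists macromolecule
# classes (mass fraction of dry weight) with their monomers (molar percentage
# within the class, molecular weight in g mmol^-1), a soluble pool given as
# molar amounts, and the growth-associated maintenance (GAM) ATP demand. The
# built reaction consumes mmol of each monomer per gram dry weight, plus
# GAM ATP + water hydrolysed to ADP + phosphate, so that total consumed mass
# is ~1 g per flux unit and the objective flux reads as the specific growth
# rate mu in h^-1.

#' Read a biomass composition from a YAML file
#'
#' Expected structure: `gam:`, `classes:` (name -> `mass_fraction`,
#' `monomers:` list of `{id, percent, mw, byproducts?}`), optional
#' `soluble:` list of `{id, amount, byproducts?}`. `byproducts` is a map of
#' metabolite -> coefficient produced per mmol of monomer consumed (used for
#' cofactor moieties that are returned to their pools, e.g. NADP from NADPH).
#'
#' @param path YAML file.
#' @return object of class `"biomass_composition"`.
#' @export
read_biomass_composition <- function(path) {
  y <- yaml::read_yaml(path)
  comp <- list(gam = as.numeric(y$gam %||% 0),
               classes = lapply(y$classes, function(cl) {
                 list(mass_fraction = as.numeric(cl$mass_fraction),
                      monomers = lapply(cl$monomers, function(m)
                        list(id = m$id, percent = as.numeric(m$percent),
                             mw = as.numeric(m$mw),
                             byproducts = m$byproducts %||% list())))
               }),
               soluble = lapply(y$soluble %||% list(), function(m)
                 list(id = m$id, amount = as.numeric(m$amount),
                      mw = if (is.null(m$mw)) NULL else as.numeric(m$mw),
                      byproducts = m$byproducts %||% list())))
  class(comp) <- "biomass_composition"
  validate_biomass_composition(comp)
  comp
}

validate_biomass_composition <- function(comp) {
  stopifnot(comp$gam >= 0)
  for (nm in names(comp$classes)) {
    cl <- comp$classes[[nm]]
    if (cl$mass_fraction <= 0) stop("class '", nm, "': mass fraction must be positive")
    if (!length(cl$monomers)) stop("class '", nm, "': empty monomer list")
    pct <- vapply(cl$monomers, `[[`, 0, "percent")
    if (any(pct <= 0)) stop("class '", nm, "': non-positive molar percentage")
  }
  invisible(comp)
}

#' Mean monomer weight of a macromolecule class
#'
#' Molar-fraction-weighted mean molecular weight, i.e. the weight per mole of
#' polymerized class obtained by adding the individual monomer contributions.
#' Percentages are normalized internally, so scaling all of them by a common
#' constant does not change the result.
#'
#' @param monomers list of `{id, percent, mw}` entries.
#' @return g mmol^-1.
#' @export
compute_class_weight <- function(monomers) {
  if (!length(monomers)) stop("empty monomer list")
  pct <- vapply(monomers, `[[`, 0, "percent")
  mw <- vapply(monomers, `[[`, 0, "mw")
  sum(pct / sum(pct) * mw)
}

#' Build the biomass reaction from a composition
#'
#' Monomer coefficients are `mass_fraction / class_weight * molar_fraction`
#' (mmol per gDW); soluble-pool entries enter at their stated molar amounts;
#' GAM adds `gam` ATP + water consumed and `gam` ADP + phosphate produced.
#' Byproduct coefficients (e.g. returned cofactor moieties) are added on the
#' product side.
#'
#' @param composition a `biomass_composition`.
#' @param id reaction id.
#' @return an `sfx_reaction` (irreversible, not an exchange) suitable for use
#'   as the model objective.
#' @export
build_biomass_reaction <- function(composition, id = "R_biomass") {
  validate_biomass_composition(composition)
  st <- numeric(0)
  add <- function(st, met, coeff) {
    st[met] <- (st[met] %||% 0)
    st[met] <- ifelse(is.na(st[met]), 0, st[met]) + coeff
    st
  }
  for (cl in composition$classes) {
    w <- compute_class_weight(cl$monomers)
    pct <- vapply(cl$monomers, `[[`, 0, "percent")
    frac <- pct / sum(pct)
    total_mmol <- cl$mass_fraction / w
    for (k in seq_along(cl$monomers)) {
      m <- cl$monomers[[k]]
      coeff <- total_mmol * frac[k]
      st <- add(st, m$id, -coeff)
      for (bp in names(m$byproducts))
        st <- add(st, bp, coeff * as.numeric(m$byproducts[[bp]]))
    }
  }
  for (m in composition$soluble) {
    st <- add(st, m$id, -m$amount)
    for (bp in names(m$byproducts))
      st <- add(st, bp, m$amount * as.numeric(m$byproducts[[bp]]))
  }
  if (composition$gam > 0) {
    st <- add(st, "atp", -composition$gam)
    st <- add(st, "h2o", -composition$gam)
    st <- add(st, "adp", composition$gam)
    st <- add(st, "pi", composition$gam)
  }
  reaction(id, st, lower_bound = 0, upper_bound = Inf,
           subsystem = "Biomass", confidence = 4L, is_exchange = FALSE)
}

#' Residual of the 1 gDW mass convention
#'
#' Sums the consumed monomer and soluble-pool mass of a built biomass
#' reaction using the composition's molecular weights and reports
#' `|mass - 1|` in grams. GAM ATP/water and cofactor byproducts are excluded
#' (they are regenerated, not incorporated).
#'
#' @param rxn the biomass `sfx_reaction`.
#' @param composition the `biomass_composition` it was built from.
#' @return residual in g per gDW.
#' @export
mass_normalization_check <- function(rxn, composition) {
  mw <- list()
  for (cl in composition$classes)
    for (m in cl$monomers) mw[[m$id]] <- m$mw
  for (m in composition$soluble)
    if (!is.null(m$mw)) mw[[m$id]] <- as.numeric(m$mw)
  mass <- 0
  for (met in names(rxn$stoichiometry)) {
    cf <- rxn$stoichiometry[[met]]
    if (cf < 0 && !is.null(mw[[met]])) mass <- mass - cf * mw[[met]]
  }
  abs(mass - 1)
}
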