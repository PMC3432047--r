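# Gene-level single-deletion scan. Gene-protein-reaction (GPR) associations
# are boolean and/or expressions over gene ids: OR joins isozymes (the
# reaction survives as long as one gene remains), AND joins complex subunits
# (losing any kills the reaction). The scan deletes one gene at a time,
# constrains the fluxes of all reactions whose GPR evaluates false to zero,
# re-solves (MOMA by default, plain FBA optionally), and bins the achieved
# biomass relative to wild type: lethal < 2%, impaired 2-89%, unaffected
# >= 90% (half-open partition covering [0, 1]).

parse_gpr <- function(expr) {
  if (is.na(expr) || !nzchar(trimws(expr))) return(NULL)
  txt <- gsub("\\bAND\\b", "&", expr, ignore.case = TRUE)
  txt <- gsub("\\bOR\\b", "|", txt, ignore.case = TRUE)
  if (grepl("[^A-Za-z0-9_()&| .]", txt))
    stop("malformed gene association: ", expr)
  e <- tryCatch(str2lang(txt), error = function(err)
    stop("malformed gene association: ", expr))
  e
}

gpr_genes_of <- function(expr) {
  e <- parse_gpr(expr)
  if (is.null(e)) return(character(0))
  vars <- all.vars(e)
  sort(unique(vars))
}

#' Evaluate a gene association under deletions
#'
#' @param expr GPR string, e.g. `"(gA and gB) or gC"`; NA means no
#'   association (always active).
#' @param deleted_genes character vector of deleted gene ids.
#' @param expressed_genes optional whitelist; genes outside it count as
#'   absent (models transcriptome filtering). Default: all genes expressed.
#' @return TRUE iff the reaction remains active.
#' @export
evaluate_gene_association <- function(expr, deleted_genes = character(0),
                                      expressed_genes = NULL) {
  e <- parse_gpr(expr)
  if (is.null(e)) return(TRUE)
  genes <- all.vars(e)
  present <- !(genes %in% deleted_genes)
  if (!is.null(expressed_genes)) present <- present & (genes %in% expressed_genes)
  env <- list2env(stats::setNames(as.list(present), genes), parent = baseenv())
  isTRUE(eval(e, envir = env))
}

#' All genes referenced by a model's GPRs
#' @param model a `metabolic_model`.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$reactions, function(r) gpr_genes_of(r$gpr)))))
}

#' Reactions disabled by deleting a set of genes
#' @param model a `metabolic_model`.
#' @param deleted_genes character vector of gene ids.
#' @param expressed_genes optional whitelist as in
#'   [evaluate_gene_association].
#' @return character vector of reaction ids whose GPR evaluates false.
#' @export
reactions_disabled_by <- function(model, deleted_genes,
                                  expressed_genes = NULL) {
  ids <- vapply(model$reactions, function(r) {
    !evaluate_gene_association(r$gpr, deleted_genes, expressed_genes)
  }, TRUE)
  names(model$reactions)[ids]
}

#' Single-gene deletion scan
#'
#' @param model a `metabolic_model`.
#' @param constraints scenario bound overrides (as in [solve_fba]) defining
#'   the growth condition.
#' @param method `"moma"` (default; minimal flux redistribution, the more
#'   realistic mutant prediction) or `"fba"` (re-optimized mutant).
#' @param genes genes to scan; default all genes in any association.
#' @param expressed_genes optional whitelist (unexpressed genes are treated
#'   as deleted throughout, including in the wild type).
#' @param wildtype optional precomputed wild-type `flux_distribution`
#'   (parsimonious FBA is used by default so the MOMA reference is a
#'   reproducible representative of the optimal set).
#' @return data frame of class `"knockout_scan"`: gene, reactions (comma
#'   separated), biomass_fraction, category. Solver failures for single genes
#'   are recorded as status "error" without aborting the scan.
#' @export
single_gene_deletion_scan <- function(model, constraints = NULL,
                                      method = c("moma", "fba"),
                                      genes = NULL, expressed_genes = NULL,
                                      wildtype = NULL) {
  method <- match.arg(method)
  base_off <- if (is.null(expressed_genes)) character(0)
              else reactions_disabled_by(model, character(0), expressed_genes)
  wt_constraints <- constraints
  if (length(base_off)) {
    wt_constraints <- c(constraints %||% list(),
                        stats::setNames(rep(list(c(0, 0)), length(base_off)), base_off))
  }
  wt <- wildtype %||% solve_fba(model, wt_constraints, parsimonious = TRUE)
  if (wt$status != "optimal") stop("wild-type problem is ", wt$status)
  wt_biomass <- wt$objective_value
  genes <- genes %||% model_genes(model)
  rows <- lapply(genes, function(g) {
    res <- tryCatch({
      off <- reactions_disabled_by(model, g, expressed_genes)
      off <- union(off, base_off)
      if (!length(off)) {
        bf <- 1
      } else if (method == "moma") {
        sol <- solve_moma(model, wt, knockout_constraints = off,
                          constraints = constraints)
        bf <- if (sol$status != "optimal") 0 else sol$objective_value / wt_biomass
      } else {
        kc <- c(constraints %||% list(),
                stats::setNames(rep(list(c(0, 0)), length(off)), off))
        sol <- solve_fba(model, kc)
        bf <- if (sol$status != "optimal") 0 else sol$objective_value / wt_biomass
      }
      bf <- max(0, bf)
      data.frame(gene = g, reactions = paste(off, collapse = ","),
                 biomass_fraction = bf,
                 category = knockout_category(bf), status = "ok")
    }, error = function(e) {
      data.frame(gene = g, reactions = NA_character_,
                 biomass_fraction = NA_real_, category = NA_character_,
                 status = paste("error:", conditionMessage(e)))
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "wildtype_biomass") <- wt_biomass
  class(out) <- c("knockout_scan", "data.frame")
  out
}

knockout_category <- function(biomass_fraction) {
  if (is.na(biomass_fraction)) return(NA_character_)
  if (biomass_fraction < 0.02) "lethal"
  else if (biomass_fraction < 0.90) "impaired"
  else "unaffected"
}

#' Essentiality summary of a knockout scan
#' @param results a `knockout_scan`.
#' @return named numeric vector of fractions (lethal, impaired, unaffected);
#'   sums to 1 over the successfully scanned genes.
#' @export
essentiality_summary <- function(results) {
  ok <- results[results$status == "ok", ]
  if (!nrow(ok)) stop("no successful knockout results to summarize")
  tab <- table(factor(ok$category, levels = c("lethal", "impaired", "unaffected")))
  stats::setNames(as.numeric(tab) / nrow(ok), names(tab))
}
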