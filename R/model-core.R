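# Core domain types: metabolites, reactions, models, and the stoichiometric
# matrix S (m x n; rows = metabolites, columns = reactions; a positive entry
# means the compound appears on the right-hand side of the reaction).

#' Sentinel used for unbounded fluxes at solve time
#'
#' Models store unbounded fluxes as +/-Inf; the solver layer substitutes this
#' artificial constraint (|v| < 100000) when building linear programs, so that
#' model files stay solver-agnostic.
#' @export
FLUX_BOUND_SENTINEL <- 1e5

#' Construct a metabolite
#'
#' @param id short unique token; ids ending in `"_e"` denote the external
#'   compartment, everything else is cytosolic.
#' @param name free-text name.
#' @param compartment `"cytosol"` or `"external"`; defaults from the id suffix.
#' @param formula optional elemental formula (e.g. `"C6H12O6"`).
#' @param carbon optional explicit carbon count; when both formula and carbon
#'   are given they must agree.
#' @return a one-row data frame.
#' @export
metabolite <- function(id, name = id, compartment = NULL, formula = NA_character_,
                       carbon = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(compartment)) {
    compartment <- if (grepl("_e$", id)) "external" else "cytosol"
  }
  compartment <- match.arg(compartment, c("cytosol", "external"))
  if (!is.na(formula)) {
    fc <- formula_carbon_count(formula)
    if (!is.na(carbon) && fc != carbon) {
      stop("metabolite '", id, "': carbon count ", carbon,
           " disagrees with formula ", formula, " (", fc, " C)")
    }
    carbon <- fc
  }
  data.frame(id = id, name = name, compartment = compartment,
             formula = formula, carbon = as.integer(carbon),
             stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' Stoichiometric coefficients are signed: negative = consumed (left-hand
#' side), positive = produced (right-hand side). Flux bounds are in
#' mmol gDW^-1 h^-1 (the biomass reaction in h^-1). A reaction is reversible
#' iff `lower_bound < 0 < upper_bound`.
#'
#' @param id short unique token.
#' @param stoichiometry named numeric vector, names are metabolite ids.
#' @param lower_bound,upper_bound flux bounds; use `-Inf`/`Inf` for
#'   unconstrained (substituted by [FLUX_BOUND_SENTINEL] at solve time).
#' @param gpr optional gene association: a boolean expression over gene ids
#'   using `and`/`or` and parentheses (see [evaluate_gene_association]).
#' @param subsystem free-text pathway label.
#' @param confidence integer evidence score in 1..4 (4 = biochemically
#'   proven, 1 = gap fill), or NA.
#' @param is_exchange boundary pseudo-reaction flag; exchange reactions must
#'   touch exactly one metabolite.
#' @return an object of class `"sfx_reaction"`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = Inf,
                     gpr = NA_character_, subsystem = NA_character_,
                     confidence = NA_integer_, is_exchange = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) && (is.null(names(stoichiometry)) ||
                                any(!nzchar(names(stoichiometry)))))
    stop("reaction '", id, "': stoichiometry must be a named vector")
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  if (!is.na(confidence) && !(confidence %in% 1:4))
    stop("reaction '", id, "': confidence must be in 1..4")
  if (is.null(is_exchange)) is_exchange <- length(stoichiometry) == 1L
  if (is_exchange && length(stoichiometry) != 1L)
    stop("reaction '", id, "': an exchange reaction touches exactly one metabolite")
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr, subsystem = subsystem,
                 confidence = as.integer(confidence),
                 is_exchange = is_exchange),
            class = "sfx_reaction")
}

#' Is a reaction reversible?
#' @param rxn an `sfx_reaction`.
#' @export
is_reversible <- function(rxn) rxn$lower_bound < 0 && rxn$upper_bound > 0

#' Construct a metabolic model
#'
#' @param metabolites data frame of metabolites (rbind of [metabolite] rows).
#' @param reactions list of [reaction] objects.
#' @param objective_id id of the objective (biomass) reaction, or NA.
#' @return an object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, objective_id = NA_character_) {
  stopifnot(is.data.frame(metabolites), is.list(reactions))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id(s): ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(reactions) <- rids
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  missing <- setdiff(used, metabolites$id)
  if (length(missing))
    stop("model-integrity error: reaction(s) reference unknown metabolite(s): ",
         paste(missing, collapse = ", "))
  if (!is.na(objective_id) && !(objective_id %in% rids))
    stop("objective reaction '", objective_id, "' not in model")
  structure(list(metabolites = metabolites, reactions = reactions,
                 objective_id = objective_id),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic model: ", length(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites", sep = "")
  if (!is.na(x$objective_id)) cat(", objective ", x$objective_id, sep = "")
  cat("\n")
  invisible(x)
}

#' Reaction ids of a model
#' @param model a `metabolic_model`.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Metabolite ids of a model
#' @param model a `metabolic_model`.
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' Lower/upper bound vectors of a model (named by reaction)
#' @param model a `metabolic_model`.
#' @export
model_bounds <- function(model) {
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  list(lb = lb, ub = ub)
}

#' Assemble the stoichiometric matrix
#'
#' Builds the sparse m x n matrix S of a model; column j reproduces reaction
#' j's stoichiometry and row order follows the metabolite table. Assembly is
#' linear: concatenating two models with disjoint metabolites and reactions
#' block-concatenates their matrices.
#'
#' @param model a `metabolic_model`.
#' @return a `Matrix::sparseMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
build_stoichiometric_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- length(model$reactions)
  if (m == 0L || n == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(m, n),
                                dimnames = list(model$metabolites$id,
                                                names(model$reactions))))
  }
  row_of <- seq_len(m)
  names(row_of) <- model$metabolites$id
  ii <- jj <- xx <- vector("list", n)
  for (j in seq_len(n)) {
    st <- model$reactions[[j]]$stoichiometry
    r <- row_of[names(st)]
    if (anyNA(r))
      stop("model-integrity error: unknown metabolite in reaction ",
           model$reactions[[j]]$id)
    ii[[j]] <- unname(r)
    jj[[j]] <- rep.int(j, length(st))
    xx[[j]] <- unname(st)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(m, n),
                       dimnames = list(model$metabolites$id,
                                       names(model$reactions)))
}

#' Carbon atoms in an elemental formula
#' @param formula e.g. `"C6H12O6"`; element tokens are `[A-Z][a-z]?` followed
#'   by an optional count, so Cl/Ca/Co/Cu are not miscounted as carbon.
#' @return non-negative integer.
#' @export
formula_carbon_count <- function(formula) {
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  n <- 0L
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    if (el == "C") {
      cnt <- sub("^[A-Za-z]+", "", t)
      n <- n + if (nzchar(cnt)) as.integer(cnt) else 1L
    }
  }
  n
}

#' Carbon atoms per molecule of a model metabolite
#'
#' Needed to normalize carbon-source uptake to 1 mmol of carbon atoms per
#' gDW per hour.
#'
#' @param model a `metabolic_model`.
#' @param met_id metabolite id.
#' @return non-negative integer.
#' @export
carbon_count <- function(model, met_id) {
  i <- match(met_id, model$metabolites$id)
  if (is.na(i)) stop("unknown metabolite: ", met_id)
  carb <- model$metabolites$carbon[i]
  if (is.na(carb))
    stop("unknown-carbon error: metabolite '", met_id,
         "' has neither formula nor explicit carbon count")
  carb
}

#' Model integrity report
#'
#' Report-only checks: duplicate ids (cannot occur in a constructed model but
#' reported for parsed input), dangling metabolites (consumed but never
#' produced, or produced but never consumed, and not exchanged), reactions
#' blocked by their bounds (lb = ub = 0), and carbon-unbalanced internal
#' reactions among those whose participants all have known carbon counts.
#'
#' @param model a `metabolic_model`.
#' @return list with elements `dangling`, `blocked`, `carbon_imbalance`
#'   (data frame id/imbalance), `duplicate_ids`, and logical `ok`.
#' @export
check_model_integrity <- function(model) {
  S <- build_stoichiometric_matrix(model)
  rxns <- model$reactions
  exch <- vapply(rxns, `[[`, TRUE, "is_exchange")
  blocked <- names(rxns)[vapply(rxns, function(r)
    r$lower_bound == 0 && r$upper_bound == 0, TRUE)]
  Sint <- S[, !exch, drop = FALSE]
  exch_mets <- unique(unlist(lapply(rxns[exch], function(r) names(r$stoichiometry))))
  prod_possible <- cons_possible <- rep(FALSE, nrow(Sint))
  for (j in seq_len(ncol(Sint))) {
    r <- rxns[!exch][[j]]
    st <- Sint[, j]
    nz <- which(st != 0)
    rev <- is_reversible(r)
    prod_possible[nz] <- prod_possible[nz] | (st[nz] > 0) | rev
    cons_possible[nz] <- cons_possible[nz] | (st[nz] < 0) | rev
  }
  touched <- Matrix::rowSums(Sint != 0) > 0
  dangling <- model$metabolites$id[touched & !(model$metabolites$id %in% exch_mets) &
                                     !(prod_possible & cons_possible)]
  carb <- model$metabolites$carbon
  names(carb) <- model$metabolites$id
  imb <- lapply(rxns[!exch], function(r) {
    # the biomass drain is a carbon boundary like the exchanges
    if (!is.na(model$objective_id) && r$id == model$objective_id) return(NULL)
    cc <- carb[names(r$stoichiometry)]
    if (anyNA(cc)) return(NULL)
    b <- sum(r$stoichiometry * cc)
    if (abs(b) > 1e-9) data.frame(id = r$id, imbalance = b) else NULL
  })
  imb <- do.call(rbind, imb[!vapply(imb, is.null, TRUE)])
  if (is.null(imb)) imb <- data.frame(id = character(), imbalance = numeric())
  out <- list(dangling = dangling, blocked = blocked, carbon_imbalance = imb,
              duplicate_ids = character(0))
  out$ok <- !length(dangling) && !nrow(imb)
  out
}
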