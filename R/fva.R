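# Flux variability analysis: with the objective flux held at (a fraction of)
# its optimum, each flux is separately minimized and maximized. The interval
# width max - min measures the flexibility of the flux with respect to the
# goal of (near-)maximal objective. Intervals of the same reaction from two
# scenarios that do not overlap identify significant differences, because the
# reaction can never assume the same flux in both.

#' Run flux variability analysis
#'
#' Solves 2n LPs. `objective_fraction = 1` is optimal FVA; the suboptimal
#' variant (paper threshold 0.95) requires only that fraction of the optimal
#' objective, widening (never narrowing) every interval.
#'
#' @param model a `metabolic_model`.
#' @param constraints optional bound overrides as in [solve_fba].
#' @param objective_fraction number in (0, 1]; the objective's lower bound is
#'   set to `fraction * optimum`.
#' @param reactions optional subset of reaction ids to analyse.
#' @param reference optional `flux_distribution` used to fill the
#'   `reference_flux` column (defaults to the FBA solution computed here).
#' @return data frame of class `"fva_result"`: id, min_flux, max_flux,
#'   reference_flux; attribute `optimum` holds the FBA optimum.
#' @export
run_fva <- function(model, constraints = NULL, objective_fraction = 1,
                    reactions = NULL, reference = NULL) {
  stopifnot(objective_fraction > 0, objective_fraction <= 1)
  fba <- reference %||% solve_fba(model, constraints)
  if (fba$status != "optimal")
    stop("FVA base problem is ", fba$status)
  opt <- fba$objective_value
  dat <- lp_data_for(model, constraints)
  jobj <- match(fba$objective_id, dat$rxn_ids)
  # floor the objective; tiny backoff keeps the fixed-optimum problem feasible
  # against simplex round-off when fraction = 1
  floor_val <- objective_fraction * opt - 1e-9 * max(1, abs(opt))
  lb <- dat$lb; ub <- dat$ub
  lb[jobj] <- max(lb[jobj], floor_val)
  sel <- reactions %||% dat$rxn_ids
  m0 <- numeric(nrow(dat$S))
  # seed a warm-startable basis under the floored bounds, then reuse the
  # previous optimal basis for each of the 2n subproblems
  jb <- match(fba$objective_id, dat$rxn_ids)
  seed_obj <- numeric(length(dat$rxn_ids)); seed_obj[jb] <- 1
  seed <- solve_lp(seed_obj, dat$S, m0, lb, ub, maximize = TRUE)
  warm <- seed$basis
  out <- lapply(sel, function(id) {
    j <- match(id, dat$rxn_ids)
    if (is.na(j)) stop("unknown reaction in FVA selection: ", id)
    obj <- numeric(length(dat$rxn_ids)); obj[j] <- 1
    lo <- solve_lp(obj, dat$S, m0, lb, ub, maximize = FALSE, warm = warm)
    if (lo$status == "optimal") warm <<- lo$basis
    hi <- solve_lp(obj, dat$S, m0, lb, ub, maximize = TRUE, warm = warm)
    if (hi$status == "optimal") warm <<- hi$basis
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem failed for ", id, " (", lo$status, "/", hi$status, ")")
    data.frame(id = id, min_flux = lo$value, max_flux = hi$value,
               reference_flux = unname(fba$flux[id]))
  })
  res <- do.call(rbind, out)
  # clamp tiny numerical inversions
  res$min_flux <- pmin(res$min_flux, res$max_flux)
  attr(res, "optimum") <- opt
  attr(res, "objective_fraction") <- objective_fraction
  class(res) <- c("fva_result", "data.frame")
  res
}

#' Classify flux variability against a reference distribution
#'
#' Bins follow the standard reporting convention: reactions whose variability exceeds
#' 100% of the predicted flux, 30-100%, reactions with a predicted flux of
#' zero that can assume non-zero values, and fixed reactions (width below
#' threshold).
#'
#' @param intervals an `fva_result`.
#' @param reference a `flux_distribution` from the same constraints (defaults
#'   to the `reference_flux` column).
#' @param zero_tol flux magnitude treated as zero.
#' @return the intervals with a `category` column added, one of
#'   `"gt100"`, `"30to100"`, `"lt30"`, `"zero_flexible"`, `"fixed"`.
#' @export
classify_variability <- function(intervals, reference = NULL, zero_tol = 1e-6) {
  ref <- if (is.null(reference)) intervals$reference_flux
         else unname(reference$flux[intervals$id])
  width <- intervals$max_flux - intervals$min_flux
  cat <- character(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    if (width[i] <= zero_tol) {
      cat[i] <- "fixed"
    } else if (abs(ref[i]) <= zero_tol) {
      cat[i] <- "zero_flexible"
    } else {
      rel <- width[i] / abs(ref[i])
      cat[i] <- if (rel > 1) "gt100" else if (rel >= 0.3) "30to100" else "lt30"
    }
  }
  intervals$category <- cat
  intervals
}

#' Per-reaction significance calls between two scenario FVA results
#'
#' A flux difference is significant iff the two variability intervals are
#' disjoint (the reaction can never assume the same flux in both scenarios).
#'
#' @param fva_a,fva_b `fva_result` objects (or data frames with id, min_flux,
#'   max_flux). Restricted to the shared reaction set with a warning when the
#'   sets differ.
#' @param tol overlap tolerance.
#' @return data frame: id, min/max for both scenarios, `significant` flag;
#'   suitable for scenario-vs-scenario scatter plots.
#' @export
compare_scenarios_fva <- function(fva_a, fva_b, tol = 1e-6) {
  shared <- intersect(fva_a$id, fva_b$id)
  if (length(shared) < length(fva_a$id) || length(shared) < length(fva_b$id))
    warning("reaction sets differ; restricting comparison to the intersection")
  a <- fva_a[match(shared, fva_a$id), ]
  b <- fva_b[match(shared, fva_b$id), ]
  disjoint <- (a$max_flux < b$min_flux - tol) | (b$max_flux < a$min_flux - tol)
  data.frame(id = shared,
             min_a = a$min_flux, max_a = a$max_flux,
             min_b = b$min_flux, max_b = b$max_flux,
             ref_a = a$reference_flux, ref_b = b$reference_flux,
             significant = disjoint)
}
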