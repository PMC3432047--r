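# Flux balance analysis: maximize the objective flux subject to the
# steady-state condition S v = 0 and the flux bounds (dx/dt = S v; at steady
# state all internal metabolite concentrations are constant). The system is
# underdetermined (n > m), so the optimum is generally one vertex among many
# alternative optimal flux distributions.

#' Solve a flux balance analysis problem
#'
#' Maximizes the flux through the model's objective reaction subject to
#' S v = 0 and the (possibly overridden) flux bounds. Infinite bounds are
#' replaced by the artificial constraint |v| < 100000 at solve time. When the
#' optimum rides that artificial bound on the objective while the model bound
#' was infinite, the problem is reported as unbounded.
#'
#' @param model a `metabolic_model` with an objective reaction.
#' @param constraints optional named list `reaction id -> c(lb, ub)`
#'   overriding model bounds for this solve.
#' @param objective_id override the model's objective reaction.
#' @param parsimonious if TRUE, post-process by minimizing the sum of
#'   absolute fluxes at the fixed optimal objective value, which removes
#'   non-productive fluxes (those not contributing to the objective) from
#'   the reported distribution. Default off for raw FBA.
#' @return object of class `"flux_distribution"`: list(flux = named vector,
#'   objective_value, status, objective_id, solver).
#' @export
solve_fba <- function(model, constraints = NULL, objective_id = NULL,
                      parsimonious = FALSE) {
  objective_id <- objective_id %||% model$objective_id
  if (is.na(objective_id)) stop("model has no objective reaction")
  dat <- lp_data_for(model, constraints)
  j <- match(objective_id, dat$rxn_ids)
  if (is.na(j)) stop("objective reaction '", objective_id, "' not in model")
  obj <- numeric(length(dat$rxn_ids)); obj[j] <- 1
  m0 <- numeric(nrow(dat$S))
  res <- solve_lp(obj, dat$S, m0, dat$lb, dat$ub, maximize = TRUE)
  if (res$status != "optimal") {
    return(structure(list(flux = NULL, objective_value = NA_real_,
                          status = if (res$status == "maxiter") "maxiter" else "infeasible",
                          objective_id = objective_id, solver = SOLVER_META),
                     class = "flux_distribution"))
  }
  status <- "optimal"
  if (is.infinite(model$reactions[[objective_id]]$upper_bound) &&
      res$value >= FLUX_BOUND_SENTINEL * (1 - 1e-6)) {
    status <- "unbounded"
  }
  flux <- stats::setNames(res$x, dat$rxn_ids)
  if (parsimonious && status == "optimal") {
    flux <- minimize_total_flux(dat, j, res$value) %||% flux
  }
  structure(list(flux = flux, objective_value = res$value, status = status,
                 objective_id = objective_id, solver = SOLVER_META),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("flux distribution: status ", x$status, sep = "")
  if (!is.na(x$objective_value))
    cat(", ", x$objective_id, " = ", signif(x$objective_value, 6), sep = "")
  cat("\n")
  invisible(x)
}

# Minimize sum |v| at fixed objective value via the split v = p - q,
# p, q >= 0. Returns a named flux vector or NULL on solver failure.
minimize_total_flux <- function(dat, obj_idx, obj_value) {
  n <- length(dat$rxn_ids)
  s <- substitute_sentinels(dat$lb, dat$ub)
  # variables: p (n), q (n); v = p - q; p <= max(ub,0), q <= max(-lb,0)
  A <- cbind(dat$S, -dat$S)
  A <- rbind(A, c(replace(numeric(n), obj_idx, 1), -replace(numeric(n), obj_idx, 1)))
  b <- c(numeric(nrow(dat$S)), obj_value)
  # v = p - q with p in [max(0, lb), max(0, ub)], q in [max(0, -ub),
  # max(0, -lb)] so the original box on v is preserved
  lb <- c(pmax(0, s$lb), pmax(0, -s$ub))
  ub <- c(pmax(s$ub, 0), pmax(-s$lb, 0))
  obj <- rep(1, 2 * n)
  res <- solve_lp(obj, A, b, lb, ub, maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)], dat$rxn_ids)
}

#' Steady-state residual of a flux distribution
#' @param model a `metabolic_model`.
#' @param fd a `flux_distribution` (status optimal).
#' @return max |S v|.
#' @export
steady_state_residual <- function(model, fd) {
  S <- build_stoichiometric_matrix(model)
  max(abs(as.numeric(S %*% fd$flux[colnames(S)])))
}
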