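# Minimization of metabolic adjustment (MOMA): a knockout's flux state is
# predicted as the feasible flux vector of the perturbed network with minimal
# Euclidean distance to the wild-type FBA solution, reflecting that mutants
# have not been evolutionarily re-optimized. This is a convex QP with the
# identity Hessian, solved with quadprog's dual active-set method.

#' Solve a MOMA problem
#'
#' Finds argmin ||v - v_wt||_2 subject to S v = 0, the model bounds, and any
#' knockout constraints (fluxes forced to zero).
#'
#' @param model a `metabolic_model`.
#' @param wildtype a `flux_distribution` for the unperturbed model (status
#'   optimal); its flux vector is the MOMA reference. The reference is one
#'   optimum among possibly many; use a parsimonious FBA solution for a
#'   reproducible choice.
#' @param knockout_constraints character vector of reaction ids forced to
#'   zero, or a named list `id -> c(lb, ub)` of bound overrides.
#' @param constraints additional scenario bound overrides (same form as in
#'   [solve_fba]), applied before the knockouts.
#' @return a `flux_distribution` whose `objective_value` is the achieved flux
#'   through the wild-type objective reaction, with extra fields
#'   `distance` (Euclidean) and `status`.
#' @export
solve_moma <- function(model, wildtype, knockout_constraints = character(0),
                       constraints = NULL) {
  if (is.null(wildtype$flux)) stop("wild-type distribution has no flux vector")
  dat <- lp_data_for(model, constraints)
  n <- length(dat$rxn_ids)
  s <- substitute_sentinels(dat$lb, dat$ub)
  lb <- s$lb; ub <- s$ub
  if (is.character(knockout_constraints)) {
    for (id in knockout_constraints) {
      j <- match(id, dat$rxn_ids)
      if (is.na(j)) stop("knockout of unknown reaction: ", id)
      lb[j] <- 0; ub[j] <- 0
    }
  } else {
    for (id in names(knockout_constraints)) {
      j <- match(id, dat$rxn_ids)
      if (is.na(j)) stop("knockout of unknown reaction: ", id)
      lb[j] <- knockout_constraints[[id]][1]
      ub[j] <- knockout_constraints[[id]][2]
    }
  }
  wt <- unname(wildtype$flux[dat$rxn_ids])
  if (anyNA(wt)) stop("wild-type flux vector does not cover all reactions")
  S <- dat$S
  # conserved moieties make S row-rank-deficient; quadprog needs linearly
  # independent equality constraints, so keep an independent row basis
  # (the dropped rows are implied, with right-hand side 0)
  qrS <- qr(t(S))
  if (qrS$rank < nrow(S)) S <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  # quadprog: min 1/2 x'Dx - d'x  s.t. A'x >= b (first meq as equalities)
  Amat <- t(rbind(S, diag(n), -diag(n)))
  bvec <- c(numeric(nrow(S)), lb, -ub)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = wt, Amat = Amat, bvec = bvec,
                       meq = nrow(S)),
    error = function(e) e)
  if (inherits(sol, "error")) {
    return(structure(list(flux = NULL, objective_value = NA_real_,
                          status = "infeasible", distance = NA_real_,
                          objective_id = wildtype$objective_id,
                          solver = SOLVER_META),
                     class = "flux_distribution"))
  }
  v <- stats::setNames(sol$solution, dat$rxn_ids)
  # snap knockout fluxes exactly to their bounds against QP round-off
  v[v < lb + 0] <- pmax(v[v < lb], lb[v < lb])
  v[v > ub] <- pmin(v[v > ub], ub[v > ub])
  structure(list(flux = v,
                 objective_value = unname(v[wildtype$objective_id]),
                 status = "optimal",
                 distance = sqrt(sum((v - wt)^2)),
                 objective_id = wildtype$objective_id,
                 solver = SOLVER_META),
            class = "flux_distribution")
}
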