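# Brute-force FVA oracle: exhaustive vertex enumeration of the bounded flux
# polytope {S v = 0, lb <= v <= ub} (optionally cut by an objective floor).
# Linear objectives attain their optima at vertices, so per-coordinate
# minima/maxima over the vertex set reproduce FVA exactly. Deliberately
# independent of the simplex path used by run_fva; guarded to small models.

enumerate_vertices <- function(S, lb, ub, cuts = NULL, tol = 1e-7) {
  n <- ncol(S)
  S <- as.matrix(S)
  # candidate active constraints: rows (a, rhs) meaning a . v = rhs when active
  cand_a <- list(); cand_rhs <- numeric(0)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, 1)
    cand_a[[length(cand_a) + 1L]] <- ei; cand_rhs <- c(cand_rhs, lb[i])
    if (ub[i] > lb[i]) {
      cand_a[[length(cand_a) + 1L]] <- ei; cand_rhs <- c(cand_rhs, ub[i])
    }
  }
  if (!is.null(cuts)) {
    for (k in seq_len(nrow(cuts$A))) {
      cand_a[[length(cand_a) + 1L]] <- cuts$A[k, ]
      cand_rhs <- c(cand_rhs, cuts$b[k])
    }
  }
  r <- if (nrow(S)) qr(S)$rank else 0L
  d <- n - r
  if (d < 0) d <- 0L
  verts <- list()
  feas <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return(FALSE)
    if (nrow(S) && max(abs(S %*% v)) > tol * max(1, max(abs(ub)))) return(FALSE)
    if (!is.null(cuts) && any(cuts$A %*% v < cuts$b - tol)) return(FALSE)
    TRUE
  }
  idx_sets <- if (d == 0L) list(integer(0))
              else utils::combn(length(cand_a), d, simplify = FALSE)
  for (set in idx_sets) {
    A <- rbind(S, do.call(rbind, cand_a[set]))
    rhs <- c(numeric(nrow(S)), cand_rhs[set])
    qrA <- qr(A)
    if (qrA$rank < n) next
    v <- tryCatch(as.numeric(qr.solve(A, rhs, tol = 1e-10)), error = function(e) NULL)
    if (is.null(v) || anyNA(v)) next
    if (feas(v)) verts[[length(verts) + 1L]] <- v
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  V <- unique(round(do.call(rbind, verts), 9))
  V
}

#' Brute-force FVA by vertex enumeration (test oracle)
#'
#' Computes FVA intervals by enumerating all vertices of the flux polytope
#' with dense linear algebra, entirely independently of the simplex solver.
#' Only for small models (size guard at 12 reactions).
#'
#' @param model a `metabolic_model`.
#' @param constraints bound overrides as in [solve_fba].
#' @param objective_fraction objective floor fraction as in [run_fva].
#' @return data frame id / min_flux / max_flux, plus attribute `optimum`.
#' @export
brute_force_fva_oracle <- function(model, constraints = NULL,
                                   objective_fraction = 1) {
  dat <- lp_data_for(model, constraints)
  n <- length(dat$rxn_ids)
  if (n > 12L) stop("oracle size guard: model has ", n, " reactions (max 12)")
  s <- substitute_sentinels(dat$lb, dat$ub)
  jobj <- match(model$objective_id, dat$rxn_ids)
  if (is.na(jobj)) stop("model has no objective reaction")
  V0 <- enumerate_vertices(dat$S, s$lb, s$ub)
  if (!nrow(V0)) stop("oracle: polytope is empty (infeasible)")
  opt <- max(V0[, jobj])
  cobj <- replace(numeric(n), jobj, 1)
  cuts <- list(A = matrix(cobj, 1), b = objective_fraction * opt - 1e-9)
  V <- enumerate_vertices(dat$S, s$lb, s$ub, cuts = cuts)
  out <- data.frame(id = dat$rxn_ids,
                    min_flux = apply(V, 2, min),
                    max_flux = apply(V, 2, max))
  attr(out, "optimum") <- opt
  out
}
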