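# LP layer: a dense bounded-variable two-phase revised primal simplex.
#
# Problems are posed in flux space: optimize c'v subject to A v = b and
# l <= v <= u (all bounds finite after the +/-100000 sentinel substitution).
# Nonbasic variables sit at one of their bounds; phase 1 drives artificial
# variables out of the basis, phase 2 optimizes. Pricing is Dantzig's rule
# with an automatic switch to Bland's rule (which guarantees termination on
# degenerate problems). The optimal basis can be reused to warm-start later
# solves that share the constraint data, which makes the 2n FVA subproblems
# cheap. The solver is deterministic, so downstream analyses are
# reproducible bit-for-bit.

SOLVER_META <- list(backend = "sulfoflux bounded-variable revised simplex",
                    feasibility_tol = 1e-9, comparison_tol = 1e-6)

substitute_sentinels <- function(lb, ub, sentinel = FLUX_BOUND_SENTINEL) {
  lb[is.infinite(lb)] <- -sentinel
  ub[is.infinite(ub)] <- sentinel
  list(lb = lb, ub = ub)
}

# Core simplex. Minimizes cost'x subject to A x = b, lb <= x <= ub.
# warm: list(basic, at_upper) from a previous solve with identical A/b/lb/ub
# (bounds may differ if the warm basis remains feasible; feasibility is
# re-checked and the warm start discarded if violated).
simplex_core <- function(cost, A, b, lb, ub, warm = NULL, max_iter = 20000L,
                         tol = 1e-7) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # pure bound problem
    x <- ifelse(cost >= 0, lb, ub)
    return(list(status = "optimal", x = x, value = sum(cost * x),
                basis = NULL))
  }
  scale_b <- max(1, max(abs(b)), max(abs(ub)), max(abs(lb)))
  feas_tol <- tol * scale_b
  # extended variables: 1..n structural, n+1..n+m artificial
  ne <- n + m
  lbe <- c(lb, numeric(m))
  ube <- c(ub, rep(Inf, m))
  run_phase <- function(cost_e, basic, at_upper, x, phase1, iter_budget) {
    bland <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > iter_budget) return(list(status = "maxiter"))
      B <- A_e[, basic, drop = FALSE]
      luB <- tryCatch(solve(B, diag(m)), error = function(e) NULL)
      if (is.null(luB)) return(list(status = "singular"))
      nonbasic <- setdiff(seq_len(ne), basic)
      xB <- as.numeric(luB %*% (b - A_e[, nonbasic, drop = FALSE] %*%
                                  x[nonbasic]))
      x[basic] <- xB
      y <- as.numeric(crossprod(luB, cost_e[basic]))
      d <- cost_e[nonbasic] - as.numeric(crossprod(A_e[, nonbasic, drop = FALSE], y))
      at_up_n <- at_upper[nonbasic]
      # eligibility: increase from lower bound if d < -tol; decrease from
      # upper bound if d > tol; artificials never re-enter
      elig <- ((!at_up_n & d < -tol) | (at_up_n & d > tol)) & nonbasic <= n
      if (!any(elig)) {
        return(list(status = "optimal", x = x, basic = basic,
                    at_upper = at_upper))
      }
      cand <- which(elig)
      j_rel <- if (bland) cand[which.min(nonbasic[cand])]
               else cand[which.max(abs(d[cand]))]
      e <- nonbasic[j_rel]
      dir <- if (at_upper[e]) -1 else 1      # sign of t (change in x_e)
      w <- as.numeric(luB %*% A_e[, e])      # xB changes by -w * t * dir
      # ratio test
      span_e <- ube[e] - lbe[e]
      t_max <- span_e
      leave <- 0L; leave_to_upper <- FALSE
      delta <- dir * w
      for (i in seq_len(m)) {
        if (delta[i] > tol) {
          r <- (x[basic[i]] - lbe[basic[i]]) / delta[i]
          if (r < t_max - 1e-12 || (abs(r - t_max) <= 1e-12 && leave > 0L &&
                                    basic[i] < basic[leave])) {
            t_max <- max(r, 0); leave <- i; leave_to_upper <- FALSE
          }
        } else if (delta[i] < -tol) {
          if (is.infinite(ube[basic[i]])) next
          r <- (ube[basic[i]] - x[basic[i]]) / (-delta[i])
          if (r < t_max - 1e-12 || (abs(r - t_max) <= 1e-12 && leave > 0L &&
                                    basic[i] < basic[leave])) {
            t_max <- max(r, 0); leave <- i; leave_to_upper <- TRUE
          }
        }
      }
      if (is.infinite(t_max)) return(list(status = "unbounded"))
      # update values
      x[e] <- x[e] + dir * t_max
      x[basic] <- x[basic] - delta * t_max
      if (leave == 0L) {
        # bound flip of the entering variable
        at_upper[e] <- !at_upper[e]
      } else {
        lv <- basic[leave]
        at_upper[lv] <- leave_to_upper
        x[lv] <- if (leave_to_upper) ube[lv] else lbe[lv]
        basic[leave] <- e
      }
      if (!bland && it > 5000L) bland <- TRUE
    }
  }
  A_e <- cbind(A, diag(m))   # artificial signs fixed below per residual
  warm_ok <- FALSE
  if (!is.null(warm) && length(warm$basic) == m && !is.null(warm$art_sign)) {
    for (i in seq_len(m)) A_e[i, n + i] <- warm$art_sign[i]
    basic <- warm$basic
    at_upper <- warm$at_upper
    x <- ifelse(at_upper, ube, lbe)[seq_len(ne)]
    x[is.infinite(x)] <- 0
    B <- A_e[, basic, drop = FALSE]
    xB <- tryCatch({
      nonbasic <- setdiff(seq_len(ne), basic)
      as.numeric(solve(B, b - A_e[, nonbasic, drop = FALSE] %*% x[nonbasic]))
    }, error = function(e) NULL)
    if (!is.null(xB) &&
        all(xB >= lbe[basic] - feas_tol) && all(xB <= ube[basic] + feas_tol)) {
      x[basic] <- pmin(pmax(xB, lbe[basic]), ube[basic])
      warm_ok <- TRUE
    }
  }
  if (!warm_ok) {
    # cold start: structural vars at the bound nearer zero, artificial basis
    A_e <- cbind(A, diag(m))
    at_lower_val <- ifelse(abs(lb) <= abs(ub), lb, ub)
    at_upper <- c(abs(lb) > abs(ub), rep(FALSE, m))
    x <- c(at_lower_val, numeric(m))
    r <- as.numeric(b - A %*% x[seq_len(n)])
    for (i in seq_len(m)) if (r[i] < 0) A_e[i, n + i] <- -1
    basic <- n + seq_len(m)
    x[basic] <- abs(r)
    cost1 <- c(numeric(n), rep(1, m))
    ph1 <- run_phase(cost1, basic, at_upper, x, phase1 = TRUE,
                     iter_budget = max_iter)
    if (ph1$status != "optimal") return(list(status = ph1$status))
    if (sum(ph1$x[n + seq_len(m)]) > feas_tol * 10)
      return(list(status = "infeasible"))
    basic <- ph1$basic; at_upper <- ph1$at_upper; x <- ph1$x
    # pin any zero-valued artificials still in the basis
    ube[n + seq_len(m)] <- 0
    x[n + seq_len(m)] <- pmin(x[n + seq_len(m)], 0)
  }
  cost2 <- c(cost, numeric(m))
  if (warm_ok) ube[n + seq_len(m)] <- 0
  ph2 <- run_phase(cost2, basic, at_upper, x, phase1 = FALSE,
                   iter_budget = max_iter)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  xs <- pmin(pmax(ph2$x[seq_len(n)], lb), ub)
  list(status = "optimal", x = xs, value = sum(cost * xs),
       basis = list(basic = ph2$basic, at_upper = ph2$at_upper,
                    art_sign = A_e[cbind(seq_len(m), n + seq_len(m))]))
}

#' Solve a bounded linear program
#'
#' @param obj objective coefficients (length n).
#' @param A equality constraint matrix (k x n, dense or sparse); may have 0 rows.
#' @param b equality right-hand side (length k).
#' @param lb,ub variable bounds; infinities are clipped to the sentinel.
#' @param maximize direction.
#' @param warm optional warm-start basis from a previous solve sharing the
#'   same constraint matrix.
#' @return list(status = "optimal"|"infeasible"|"maxiter"|..., x, value,
#'   basis).
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE, warm = NULL) {
  n <- length(obj)
  s <- substitute_sentinels(lb, ub)
  if (any(s$lb > s$ub + 1e-12))
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  A <- as.matrix(A)
  res <- simplex_core(if (maximize) -obj else obj, A, b, s$lb, s$ub,
                      warm = warm)
  if (res$status != "optimal")
    return(list(status = if (res$status %in% c("infeasible", "unbounded"))
                  res$status else "maxiter",
                x = NULL, value = NA_real_, basis = NULL))
  list(status = "optimal", x = res$x, value = sum(obj * res$x),
       basis = res$basis)
}

lp_data_for <- function(model, constraints = NULL) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  bnd <- model_bounds(model)
  lb <- bnd$lb; ub <- bnd$ub
  if (!is.null(constraints) && length(constraints)) {
    for (id in names(constraints)) {
      j <- match(id, names(lb))
      if (is.na(j)) stop("constraint on unknown reaction: ", id)
      lb[j] <- constraints[[id]][1]
      ub[j] <- constraints[[id]][2]
      if (lb[j] > ub[j]) stop("constraint on ", id, ": lb > ub")
    }
  }
  list(S = S, lb = lb, ub = ub, rxn_ids = names(model$reactions))
}
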