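# Shared fixtures and independent oracles. Everything is built in code.

# cache the curated model: building parses the shipped files every time
ccm_cache <- new.env(parent = emptyenv())
ccm <- function() {
  if (is.null(ccm_cache$model)) ccm_cache$model <- build_ccm_model()
  ccm_cache$model
}
ccm_glc_constraints <- function() scenario_constraints(ccm(), ccm_scenario("glucose"))
ccm_glc_wt <- function() {
  if (is.null(ccm_cache$wt))
    ccm_cache$wt <- solve_fba(ccm(), ccm_glc_constraints(), parsimonious = TRUE)
  ccm_cache$wt
}

# a tiny 3-metabolite chain: EX_A (uptake <= 1) -> A -> B -> sink
chain_model <- function(uptake = 1) {
  metabolic_model(
    do.call(rbind, lapply(c("a_e", "a", "b"), metabolite)),
    list(reaction("EX_a", c(a_e = -1), lower_bound = -uptake),
         reaction("T_a", c(a_e = -1, a = 1)),
         reaction("R1", c(a = -1, b = 1)),
         reaction("BM", c(b = -1), is_exchange = TRUE)),
    objective_id = "BM")
}

# split every reversible reaction into two antiparallel irreversible ones
split_reversibles <- function(model) {
  rxns <- list()
  for (r in model$reactions) {
    if (is_reversible(r) && !r$is_exchange) {
      fwd <- r; fwd$lower_bound <- 0
      rev <- reaction(paste0(r$id, "_rev"), -r$stoichiometry,
                      lower_bound = 0, upper_bound = -r$lower_bound,
                      gpr = r$gpr, subsystem = r$subsystem,
                      confidence = r$confidence, is_exchange = r$is_exchange)
      rxns[[fwd$id]] <- fwd
      rxns[[rev$id]] <- rev
    } else {
      rxns[[r$id]] <- r
    }
  }
  metabolic_model(model$metabolites, rxns, model$objective_id)
}

# independent MOMA oracle: quadratic grid search over an explicit
# parameterization of the feasible set (model-specific, tiny toys only)
grid_moma_parallel <- function(wt_flux, knocked = "B1", n_grid = 2001) {
  # parallel toy feasible set after knocking one branch: flux f in [0, 1],
  # v = (EX=-f, T=f, B1=0, B2=f, BM=f) (or B1/B2 swapped)
  best <- Inf; best_f <- NA
  for (f in seq(0, 1, length.out = n_grid)) {
    v <- c(EX_a = -f, T_a = f, B1 = 0, B2 = f, BM = f)
    if (knocked == "B2") v <- c(EX_a = -f, T_a = f, B1 = f, B2 = 0, BM = f)
    d2 <- sum((v - wt_flux[names(v)])^2)
    if (d2 < best) { best <- d2; best_f <- f }
  }
  list(distance = sqrt(best), f = best_f)
}

expect_flux_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)), tol)
}
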