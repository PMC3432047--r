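test_that("FBA solves hand-checkable problems and reports statuses", {
  fd <- solve_fba(chain_model())
  expect_equal(fd$status, "optimal")
  expect_equal(fd$objective_value, 1)
  expect_flux_equal(fd$flux[c("T_a", "R1", "BM")], c(1, 1, 1))
  expect_equal(unname(fd$flux["EX_a"]), -1)
  expect_lt(steady_state_residual(chain_model(), fd), 1e-6)

  # all uptakes closed + positive maintenance demand -> infeasible
  toy <- canonical_toys()$maintenance
  fd <- solve_fba(toy, list(EX_a = c(0, 0), R_ngam = c(0.5, 0.5)))
  expect_equal(fd$status, "infeasible")
  expect_null(fd$flux)

  # unlimited uptake straight into the objective -> unbounded (sentinel hit)
  ub <- metabolic_model(rbind(metabolite("a_e"), metabolite("a")),
                        list(reaction("EX_a", c(a_e = -1), lower_bound = -Inf),
                             reaction("T_a", c(a_e = -1, a = 1)),
                             reaction("BM", c(a = -1), is_exchange = TRUE)),
                        "BM")
  expect_equal(solve_fba(ub)$status, "unbounded")
})

test_that("FBA objective is invariant to reaction reordering and reversible splitting", {
  model <- ccm()
  cons <- ccm_glc_constraints()
  ref <- solve_fba(model, cons)$objective_value
  set.seed(7)
  perm <- sample(length(model$reactions))
  shuffled <- metabolic_model(model$metabolites, model$reactions[perm],
                              model$objective_id)
  expect_equal(solve_fba(shuffled, cons)$objective_value, ref, tolerance = 1e-8)
  split <- split_reversibles(model)
  expect_equal(solve_fba(split, cons)$objective_value, ref, tolerance = 1e-8)
})

test_that("tightening a bound never increases the FBA optimum", {
  model <- ccm()
  base <- solve_fba(model, ccm_glc_constraints())$objective_value
  for (up in c(0.5, 0.4, 0.2)) {
    cfg <- scenario_config("t", uptake_bounds = c(EX_glc_e = up), ngam_flux = 1.9)
    v <- solve_fba(model, scenario_constraints(model, cfg))$objective_value
    expect_lte(v, base + 1e-9)
    base <- v
  }
})

test_that("FVA: chains are fully determined, parallel branches share [0, f]", {
  toys <- canonical_toys()
  f <- run_fva(toys$chain)
  expect_lt(max(f$max_flux - f$min_flux), 1e-6)
  f <- run_fva(toys$parallel)
  for (id in c("B1", "B2")) {
    expect_equal(f$min_flux[f$id == id], 0, tolerance = 1e-6)
    expect_equal(f$max_flux[f$id == id], 1, tolerance = 1e-6)
  }
  # intervals at fraction 1 nest inside fraction 0.95
  model <- ccm()
  cons <- ccm_glc_constraints()
  sel <- c("R_kdgk", "R_kdga", "R_icl", "R_pc", "R_pepc", "R_gdh", "R_t_s7p")
  f1 <- run_fva(model, cons, 1, reactions = sel)
  f95 <- run_fva(model, cons, 0.95, reactions = sel)
  expect_true(all(f95$min_flux <= f1$min_flux + 1e-6))
  expect_true(all(f95$max_flux >= f1$max_flux - 1e-6))
})

test_that("balanced cycles show sentinel-wide variability", {
  f <- run_fva(canonical_toys()$cycle3)
  loops <- f[f$id %in% c("L12", "L23", "L31"), ]
  expect_true(all(abs(loops$min_flux + FLUX_BOUND_SENTINEL) < 1))
  expect_true(all(abs(loops$max_flux - FLUX_BOUND_SENTINEL) < 1))
})

test_that("variability classification follows the reporting bins", {
  iv <- data.frame(id = c("fixed", "wide", "zeroflex", "narrow"),
                   min_flux = c(0, 0, 0, 1),
                   max_flux = c(0, 2.5, 0.3, 1.4),
                   reference_flux = c(0, 1, 0, 1))
  out <- classify_variability(iv)
  expect_equal(out$category, c("fixed", "gt100", "zero_flexible", "30to100"))
})

test_that("differing-ATP-yield branches route all flux through the higher yield", {
  fd <- solve_fba(canonical_toys()$atp_branch)
  expect_equal(unname(fd$flux["B_hi"]), 1, tolerance = 1e-6)
  expect_equal(unname(fd$flux["B_lo"]), 0, tolerance = 1e-6)
})

test_that("maintenance toy follows the closed-form linear decline to infeasibility", {
  toy <- canonical_toys()$maintenance
  for (m in c(0, 0.25, 0.5, 0.75, 1)) {
    fd <- solve_fba(toy, list(R_ngam = c(m, m)))
    expect_equal(fd$objective_value, (1 - m) / 1.5, tolerance = 1e-6)
  }
  expect_equal(solve_fba(toy, list(R_ngam = c(1.2, 1.2)))$status, "infeasible")
})

test_that("MOMA returns the wild type for knockouts of zero-flux reactions", {
  model <- ccm()
  wt <- ccm_glc_wt()
  sol <- solve_moma(model, wt, "R_pmo", constraints = ccm_glc_constraints())
  expect_equal(sol$distance, 0, tolerance = 1e-5)
  expect_equal(sol$objective_value, wt$objective_value, tolerance = 1e-6)
})

test_that("MOMA matches an independent quadratic grid search on the 2-branch toy", {
  toy <- canonical_toys()$parallel
  # wild type forced through B1
  wt <- solve_fba(toy, list(B2 = c(0, 0)))
  wt$flux["B2"] <- 0
  sol <- solve_moma(toy, wt, "B1")
  oracle <- grid_moma_parallel(wt$flux, knocked = "B1")
  expect_equal(sol$distance, oracle$distance, tolerance = 1e-4)
  expect_equal(unname(sol$flux["BM"]), oracle$f, tolerance = 1e-3)
  # MOMA biomass never exceeds the FBA optimum of the perturbed model
  fba_ko <- solve_fba(toy, list(B1 = c(0, 0)))
  expect_lte(sol$objective_value, fba_ko$objective_value + 1e-8)
})

test_that("every optimal solution satisfies steady state within tolerance", {
  model <- ccm()
  for (sc in c("glucose", "phenol", "hco3")) {
    fd <- solve_fba(model, scenario_constraints(model, ccm_scenario(sc)))
    expect_equal(fd$status, "optimal")
    expect_lt(steady_state_residual(model, fd), 1e-6)
  }
})
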