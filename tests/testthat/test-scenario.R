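test_that("uptake normalization follows 1 mmol carbon per gDW per hour", {
  model <- ccm()
  expect_equal(round_half_up(normalized_uptake(model, "glc"), 3), 0.167)
  expect_equal(normalized_uptake(model, "etoh"), 0.5)
  c1 <- metabolic_model(rbind(metabolite("m", formula = "CH4")),
                        list(reaction("r", c(m = -1))))
  expect_equal(normalized_uptake(c1, "m"), 1)
  z <- metabolic_model(rbind(metabolite("w", formula = "H2O")),
                       list(reaction("r", c(w = -1))))
  expect_error(normalized_uptake(z, "w"), "zero-carbon")
})

test_that("ATP equivalence arithmetic matches the P/O = 0.5 conversion rules", {
  expect_equal(atp_equivalents(0, 3, 0, 0.5), 1.5)
  expect_equal(atp_equivalents(0, 0, 2, 0.5), 0.5)
  expect_equal(atp_equivalents(1, 0, 0, 0.7), 1)
  expect_error(atp_equivalents(1, 1, 0, 0), "p_o")
})

test_that("EPS flux balances the routed carbon fraction", {
  eu <- ccm_eps_unit()
  f <- compute_eps_flux(0.55, 0.225, eu$stoichiometry, eu$carbons)
  expect_equal(round_half_up(f, 3), 0.049)
  expect_equal(compute_eps_flux(0.55, 0, eu$stoichiometry, eu$carbons), 0)
  expect_equal(compute_eps_flux(0.55, 1, c(glc = 1), c(glc = 6)), 0.55)
  expect_error(compute_eps_flux(0.55, 0.2, c(x = 1), c(y = 6)), "missing carbon")
})

test_that("pathway energy accounts recover curated stoichiometric yields", {
  model <- ccm()
  rt <- ccm_routes()
  # substrate = product: the all-zero account
  a0 <- pathway_energy_account(model, "pyr", "pyr", character(0))
  expect_equal(a0$atp_equivalents, 0)
  # glycerol -> pyruvate, scaled to 2 glycerol (6 carbon atoms): the kinase
  # cost is repaid by pyruvate kinase, and 2 NAD(P)H + 2 FADH2 remain
  g <- pathway_energy_account(model, "glyc", "pyr", rt$glycerol,
                              substrate_amount = 2, product_amount = 2)
  expect_equal(g$net_atp, 0, tolerance = 1e-9)
  expect_equal(g$net_nadph, 2, tolerance = 1e-9)
  expect_equal(g$net_fadh2, 2, tolerance = 1e-9)
  expect_equal(g$atp_equivalents, 2, tolerance = 1e-9)
  # both ED branches yield exactly the same energy per glucose
  s <- pathway_energy_account(model, "glc", "pyr", rt$glycolysis_semi, 1, 2)
  n <- pathway_energy_account(model, "glc", "pyr", rt$glycolysis_nonp, 1, 2)
  expect_equal(s$net_atp, n$net_atp)
  expect_equal(s$atp_equivalents, n$atp_equivalents)
  # an impossible conversion names the gap
  expect_error(pathway_energy_account(model, "glc", "akg", rt$glycerol),
               "no feasible conversion")
})

test_that("scenario reports carry growth, carbon bookkeeping and run metadata", {
  model <- ccm()
  rep <- run_scenario(model, ccm_scenario("glucose"), fva = FALSE)
  expect_equal(rep$status, "optimal")
  expect_gt(rep$biomass_flux, 0)
  expect_gt(rep$carbon_usage_ratio, 0)
  expect_lt(rep$carbon_usage_ratio, 1)
  expect_gt(rep$co2_flux, 0)
  expect_match(rep$solver$backend, "simplex")
  # carbon conservation: imported = biomass + respired + secreted
  fd <- rep$fba
  carb <- stats::setNames(model$metabolites$carbon, model$metabolites$id)
  imported <- secreted <- 0
  for (r in model$reactions[vapply(model$reactions, `[[`, TRUE, "is_exchange")]) {
    cc <- carb[[names(r$stoichiometry)]]
    if (is.na(cc) || cc == 0) next
    f <- fd$flux[[r$id]]
    if (f < 0) imported <- imported - f * cc else secreted <- secreted + f * cc
  }
  expect_equal(imported, rep$biomass_carbon + secreted, tolerance = 1e-6)
  # infeasible configs surface as such
  bad <- scenario_config("starve", ngam_flux = 5)
  expect_equal(run_scenario(model, bad, fva = FALSE)$status, "infeasible")
})

test_that("carbon-source scan emits one row per catalogue source, glucose = 100", {
  model <- ccm()
  cat <- read_carbon_source_catalogue()
  scan <- run_carbon_source_scan(model, cat, ngam = 0.67)
  expect_equal(nrow(scan), nrow(cat))
  expect_equal(scan$relative_to_glucose[scan$source == "glucose"], 100)
  expect_true(all(scan$status %in% c("ok", "unsupported", "infeasible")))
  expect_true(all(is.na(scan$biomass_flux[scan$status == "unsupported"])))
  expect_equal(scan$uptake[scan$source == "acetoin"], NA_real_)
})

test_that("interval overlap decides scenario significance", {
  a <- data.frame(id = c("r1", "r2", "r3"), min_flux = c(0, 0, 0),
                  max_flux = c(1, 1, 1), reference_flux = 0)
  b <- data.frame(id = c("r1", "r2", "r4"), min_flux = c(0.5, 2, 0),
                  max_flux = c(2, 3, 1), reference_flux = 0)
  expect_warning(cmp <- compare_scenarios_fva(a, b), "intersection")
  expect_equal(cmp$id, c("r1", "r2"))
  expect_equal(cmp$significant, c(FALSE, TRUE))
})
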