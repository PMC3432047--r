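test_that("the manifest covers every numbered pathway enzyme exactly once", {
  man <- fixture_manifest()
  ccm_idx <- man$index[man$figure %in% c(2, 6)]
  expect_setequal(ccm_idx, 1:55)
  expect_equal(anyDuplicated(ccm_idx), 0L)
  hb_idx <- man$index[man$figure == 3]
  expect_setequal(hb_idx, 1:16)
  model <- ccm()
  for (ids in strsplit(man$reaction_ids, ","))
    expect_true(all(ids %in% reaction_ids(model)))
})

test_that("promiscuous enzymes share one gene across their reactions", {
  model <- ccm()
  g <- function(id) gpr_genes_of(model$reactions[[id]]$gpr)
  expect_equal(g("R_kdpga"), g("R_kdga"))   # the two ED aldolases
  expect_equal(g("R_tkt1"), g("R_tkt2"))    # the two transketolase steps
  expect_equal(g("R_gdh"), g("R_galdh"))    # glucose/galactose dehydrogenase
})

test_that("glucose growth uses both ED branches with the RuMP leak under 3% carbon", {
  model <- ccm()
  rep <- run_scenario(model, ccm_scenario("glucose"), fva = FALSE)
  expect_gt(rep$biomass_flux, 0)
  fva <- run_fva(model, ccm_glc_constraints(),
                 reactions = c("R_kdgk", "R_kdga", "R_gdh", "R_t_s7p"))
  ed_total <- fva$max_flux[fva$id == "R_gdh"]
  # each branch can carry the bulk of the glycolytic flux
  for (id in c("R_kdgk", "R_kdga"))
    expect_gt(fva$max_flux[fva$id == id] - fva$min_flux[fva$id == id],
              0.5 * ed_total)
  # sedoheptulose-7-phosphate leak below 3% of imported carbon
  leak_c <- 7 * rep$fba$flux[["R_t_s7p"]]
  expect_lt(leak_c / rep$carbon_imported, 0.03)
  # and the leak is forced (no flexibility in the reverse RuMP pathway)
  s7p <- fva[fva$id == "R_t_s7p", ]
  expect_lt(s7p$max_flux - s7p$min_flux, 1e-6)
})

test_that("autotrophic scenario fixes bicarbonate through the HP/HB cycle on sulfide", {
  model <- ccm()
  rep <- run_scenario(model, ccm_scenario("hco3"), fva = FALSE)
  expect_gt(rep$biomass_flux, 0)
  fd <- rep$fba
  # ED inactive, cycle active, PEP carboxykinase gluconeogenic
  expect_lt(abs(fd$flux[["R_gdh"]]), 1e-6)
  expect_gt(fd$flux[["R_acc"]], 1e-3)
  expect_gt(fd$flux[["R_pepck"]], 1e-6)
  # halving the FBA-chosen sulfide flux reduces biomass
  v <- -fd$flux[["EX_h2s_e"]]
  cfg <- ccm_scenario("hco3")
  cfg$uptake_bounds[["EX_h2s_e"]] <- v / 2
  half <- solve_fba(model, scenario_constraints(model, cfg))
  expect_lt(half$objective_value, rep$biomass_flux - 1e-6)
})

test_that("optional subsystems can be toggled off", {
  no_hb <- build_ccm_model(include_hphb = FALSE)
  cfg <- ccm_scenario("hco3")
  fd <- solve_fba(no_hb, scenario_constraints(no_hb, cfg))
  expect_true(fd$status == "infeasible" || fd$objective_value < 1e-9)
  no_ph <- build_ccm_model(include_phenol = FALSE)
  fd <- solve_fba(no_ph, scenario_constraints(no_ph, ccm_scenario("phenol")))
  expect_true(fd$status == "infeasible" || fd$objective_value < 1e-9)
  # the malate pentose route gives lower yield than the 2-oxoglutarate route
  alt <- build_ccm_model(pentose_route = "malate")
  cfg <- scenario_config("xyl", uptake_bounds = c(EX_xyl_e = 0.2),
                         ngam_flux = 0.67)
  mu_mal <- solve_fba(alt, scenario_constraints(alt, cfg))$objective_value
  mu_akg <- solve_fba(ccm(), scenario_constraints(ccm(), cfg))$objective_value
  expect_lt(mu_mal, mu_akg)
})

test_that("glucose vs phenol: ED shut down, enolase reversed, TCA oxidative in both", {
  model <- ccm()
  sel <- c("R_gdh", "R_gad", "R_eno", "R_cs", "R_aco", "R_pmo")
  glc <- run_fva(model, ccm_glc_constraints(), reactions = sel)
  phe <- run_fva(model, scenario_constraints(model, ccm_scenario("phenol")),
                 reactions = sel)
  cmp <- compare_scenarios_fva(glc, phe)
  sig <- stats::setNames(cmp$significant, cmp$id)
  expect_true(sig[["R_gdh"]])   # glucose oxidation off under phenol
  expect_true(sig[["R_gad"]])
  expect_true(sig[["R_pmo"]])   # phenol route on
  # enolase significant because its direction reverses (gluconeogenic)
  expect_true(sig[["R_eno"]])
  expect_gt(min(cmp$min_a[cmp$id == "R_eno"]), 0)
  expect_lt(max(cmp$max_b[cmp$id == "R_eno"]), 0)
  # the TCA core stays oxidative (positive flux) under both substrates
  for (id in c("R_cs", "R_aco"))
    expect_true(cmp$min_a[cmp$id == id] > 0 && cmp$min_b[cmp$id == id] > 0)
})
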