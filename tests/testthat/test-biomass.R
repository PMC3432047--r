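test_that("class weight is the molar-fraction-weighted mean monomer weight", {
  one <- list(list(id = "m", percent = 100, mw = 0.1))
  expect_equal(compute_class_weight(one), 0.1)
  two <- list(list(id = "a", percent = 50, mw = 0.1),
              list(id = "b", percent = 50, mw = 0.3))
  expect_equal(compute_class_weight(two), 0.2)
  # a 4-nucleotide class at 25% each, hand-summed
  nts <- list(list(id = "amp", percent = 25, mw = 0.347),
              list(id = "gmp", percent = 25, mw = 0.363),
              list(id = "cmp", percent = 25, mw = 0.323),
              list(id = "ump", percent = 25, mw = 0.324))
  expect_equal(compute_class_weight(nts), (0.347 + 0.363 + 0.323 + 0.324) / 4)
  expect_error(compute_class_weight(list()), "empty")
})

test_that("biomass construction carries GAM and normalizes percentages internally", {
  comp <- structure(list(
    gam = 24.86,
    classes = list(protein = list(mass_fraction = 1, monomers = list(
      list(id = "ala", percent = 100, mw = 0.0711, byproducts = list())))),
    soluble = list()), class = "biomass_composition")
  bm <- build_biomass_reaction(comp)
  expect_equal(unname(bm$stoichiometry["atp"]), -24.86)
  expect_equal(unname(bm$stoichiometry["adp"]), 24.86)
  expect_equal(unname(bm$stoichiometry["ala"]), -1 / 0.0711)

  comp0 <- comp; comp0$gam <- 0
  bm0 <- build_biomass_reaction(comp0)
  expect_false("atp" %in% names(bm0$stoichiometry))

  # scaling all molar percentages by a constant leaves the reaction unchanged
  comp2 <- comp
  comp2$classes$protein$monomers[[1]]$percent <- 400
  expect_equal(build_biomass_reaction(comp2)$stoichiometry, bm$stoichiometry)
})

test_that("mass normalization residual behaves as a diagnostic", {
  comp <- read_biomass_composition(system.file("extdata", "sso_biomass.yml",
                                               package = "sulfoflux"))
  bm <- build_biomass_reaction(comp)
  expect_lt(mass_normalization_check(bm, comp), 0.01)
  doubled <- bm
  doubled$stoichiometry["ala"] <- 2 * doubled$stoichiometry["ala"]
  extra <- -bm$stoichiometry[["ala"]] * 0.0711
  expect_equal(mass_normalization_check(doubled, comp), extra, tolerance = 2e-3)
  empty <- reaction("R_biomass", c(atp = -1, adp = 1, h2o = -1, pi = 1))
  expect_equal(mass_normalization_check(empty, comp), 1)
})

test_that("byproduct cofactor moieties return to their pools", {
  comp <- read_biomass_composition(system.file("extdata", "sso_biomass.yml",
                                               package = "sulfoflux"))
  bm <- build_biomass_reaction(comp)
  expect_equal(unname(bm$stoichiometry["nadp"]), 0.04)
  expect_equal(unname(bm$stoichiometry["nadph"]), -0.04)
})
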