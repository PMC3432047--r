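test_that("stoichiometric matrix reproduces reaction columns with the sign convention", {
  m <- metabolic_model(rbind(metabolite("A"), metabolite("B")),
                       list(reaction("r", c(A = -1, B = 1))))
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 1L))
  expect_equal(as.numeric(S[, "r"]), c(-1, 1))

  empty <- metabolic_model(metabolite("x")[0, ], list())
  expect_equal(dim(build_stoichiometric_matrix(empty)), c(0L, 0L))

  chain <- metabolic_model(
    do.call(rbind, lapply(c("A", "B", "C"), metabolite)),
    list(reaction("EX_A", c(A = 1), lower_bound = 0, is_exchange = TRUE),
         reaction("R1", c(A = -1, B = 1)),
         reaction("R2", c(B = -1, C = 1))))
  S <- as.matrix(build_stoichiometric_matrix(chain))
  expect_equal(unname(S), rbind(c(1, -1, 0), c(0, 1, -1), c(0, 0, 1)))
})

test_that("matrix assembly is linear under model concatenation", {
  m1 <- chain_model()
  m2 <- metabolic_model(rbind(metabolite("p"), metabolite("q")),
                        list(reaction("rz", c(p = -2, q = 3))))
  S1 <- as.matrix(build_stoichiometric_matrix(m1))
  S2 <- as.matrix(build_stoichiometric_matrix(m2))
  comb <- metabolic_model(rbind(m1$metabolites, m2$metabolites),
                          c(m1$reactions, m2$reactions), "BM")
  Sc <- as.matrix(build_stoichiometric_matrix(comb))
  expect_equal(Sc[rownames(S1), colnames(S1), drop = FALSE], S1)
  expect_equal(Sc[rownames(S2), colnames(S2), drop = FALSE], S2)
  expect_true(all(Sc[rownames(S1), colnames(S2)] == 0))
})

test_that("constructor invariants reject malformed input", {
  expect_error(metabolic_model(rbind(metabolite("A"), metabolite("A")), list()),
               "duplicate metabolite")
  expect_error(metabolic_model(metabolite("A"),
                               list(reaction("r", c(Zz = -1)))),
               "unknown metabolite")
  expect_error(reaction("r", c(A = -1, B = 1), lower_bound = 2, upper_bound = 1),
               "lower_bound")
  expect_error(reaction("r", c(A = -1, B = 1), is_exchange = TRUE),
               "exactly one metabolite")
  expect_error(reaction("r", c(A = -1), confidence = 7), "confidence")
  r <- reaction("r", c(A = -1, B = 1), lower_bound = -Inf)
  expect_true(is_reversible(r))
  expect_false(is_reversible(reaction("r", c(A = -1, B = 1))))
})

test_that("carbon counts come from formulas, with two-letter elements intact", {
  expect_equal(formula_carbon_count("C6H12O6"), 6L)   # glucose
  expect_equal(formula_carbon_count("C4H8O2"), 4L)    # acetoin
  expect_equal(formula_carbon_count("C2H6O"), 2L)     # ethanol
  expect_equal(formula_carbon_count("CaCl2"), 0L)
  expect_equal(formula_carbon_count("CH2O"), 1L)
  m <- metabolic_model(rbind(metabolite("glc", formula = "C6H12O6"),
                             metabolite("mys")),
                       list(reaction("r", c(glc = -1, mys = 6))))
  expect_equal(carbon_count(m, "glc"), 6L)
  expect_error(carbon_count(m, "mys"), "unknown-carbon")
  expect_error(metabolite("x", formula = "C6H12O6", carbon = 5), "disagrees")
})

test_that("integrity report flags dangling metabolites and carbon imbalance", {
  m <- metabolic_model(
    rbind(metabolite("A", formula = "C6H12O6"),
          metabolite("B", formula = "C5H10O5"),
          metabolite("D")),
    list(reaction("r1", c(A = -1, B = 1)),     # C6 -> C5, no C1 product
         reaction("r2", c(D = -1, A = 1))))    # D consumed, produced nowhere
  rep <- check_model_integrity(m)
  expect_true("r1" %in% rep$carbon_imbalance$id)
  expect_equal(rep$carbon_imbalance$imbalance[rep$carbon_imbalance$id == "r1"], -1)
  expect_true("D" %in% rep$dangling)
  expect_false(rep$ok)
})

test_that("the curated fixture passes every integrity check", {
  rep <- check_model_integrity(ccm())
  expect_equal(nrow(rep$carbon_imbalance), 0L)
  expect_length(rep$dangling, 0L)
  # the only deliberately clamped reaction is the optional pentose route
  expect_equal(rep$blocked, "R_pentmal")
})
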