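test_that("generation is seed-deterministic, byte for byte", {
  a <- generate_random_model(synthetic_spec(6, 9, 0.5, seed = 42))
  b <- generate_random_model(synthetic_spec(6, 9, 0.5, seed = 42))
  expect_identical(write_model_text(a$model), write_model_text(b$model))
  expect_identical(a$planted$flux, b$planted$flux)
  c2 <- generate_random_model(synthetic_spec(6, 9, 0.5, seed = 43))
  expect_false(identical(write_model_text(a$model), write_model_text(c2$model)))
})

test_that("impossible specs are rejected", {
  expect_error(synthetic_spec(2, 10, seed = 1), "impossible spec")
  expect_error(synthetic_spec(5, 4, seed = 1), "impossible spec")
  expect_error(synthetic_spec(5, 8), "seed is mandatory")
})

test_that("planted vectors are feasible and generated models are sound", {
  for (s in 1:12) {
    g <- generate_random_model(synthetic_spec(4 + s %% 3, 7 + s %% 3,
                                              0.4, seed = s))
    S <- build_stoichiometric_matrix(g$model)
    v <- g$planted$flux[colnames(S)]
    expect_lt(max(abs(as.numeric(S %*% v))), 1e-12)
    bnd <- model_bounds(g$model)
    expect_true(all(v >= bnd$lb[names(v)] - 1e-12 &
                      v <= bnd$ub[names(v)] + 1e-12))
    rep <- check_model_integrity(g$model)
    expect_length(rep$dangling, 0)
    # bottlenecked uptake: FBA optimum equals the planted throughput
    fd <- solve_fba(g$model)
    expect_gte(fd$objective_value, g$planted$objective_value - 1e-8)
    expect_equal(fd$objective_value, g$planted$objective_value,
                 tolerance = 1e-8)
  }
})

test_that("MOMA on the unperturbed generated model returns the wild type", {
  g <- generate_random_model(synthetic_spec(5, 8, 0.3, seed = 11))
  wt <- solve_fba(g$model, parsimonious = TRUE)
  sol <- solve_moma(g$model, wt)
  expect_lt(sol$distance, 1e-6)
})
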