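test_that("noiseless synthetic tables reproduce the generating maps exactly", {
  spec <- synthetic_spec(noise_sd = 0, seed = 7)
  tab <- generate_bde_table(spec)
  expect_equal(nrow(tab), 300)
  br <- fit_cross_halogen(tab, "Br")
  cl <- fit_cross_halogen(tab, "Cl")
  expect_equal(br$slope, spec$slope_br, tolerance = 1e-10)
  expect_equal(br$intercept, spec$intercept_br, tolerance = 1e-8)
  expect_equal(br$r_squared, 1, tolerance = 1e-12)
  expect_equal(cl$slope, spec$slope_cl, tolerance = 1e-10)
})

test_that("generation is deterministic and feeds the standard loader pathway", {
  spec <- synthetic_spec(noise_sd = 2, missing_fraction = 0.2, seed = 31)
  a <- generate_bde_table(spec)
  b <- generate_bde_table(spec)
  attr(a, "spec") <- attr(b, "spec") <- NULL
  expect_identical(a, b)
  # same schema as the packaged fixtures
  expect_true(all(names(bde_table("homolytic")) %in% names(a)))
  sp <- split_dataset(a[!a$missing, ], 0.1, seed = 1)
  expect_equal(length(sp$test), round(0.1 * sum(!a$missing)))
})

test_that("missingness is binomial at the requested rate", {
  spec <- synthetic_spec(n_skeletons = 10, n_groups = 10,
                         missing_fraction = 0.3, seed = 5)
  tab <- generate_bde_table(spec)
  n <- nrow(tab)
  observed <- sum(!tab$missing)
  ci <- qbinom(c(0.0005, 0.9995), n, 0.7)
  expect_gte(observed, ci[1])
  expect_lte(observed, ci[2])
})

test_that("slope recovery is unbiased to within 0.02 over 20 seeds at noise 3", {
  spec0 <- synthetic_spec(n_skeletons = 10, n_groups = 10, slope_br = 0.9,
                          intercept_br = -14, noise_sd = 3)
  slopes <- vapply(1:20, function(s) {
    spec <- spec0; spec$seed <- s
    fit_cross_halogen(generate_bde_table(spec), "Br")$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.9), 0.02)
})

test_that("slope-recovery error shrinks monotonically as noise vanishes", {
  rmse_at <- function(noise) {
    errs <- vapply(1:20, function(s) {
      spec <- synthetic_spec(n_skeletons = 10, n_groups = 10, slope_br = 0.9,
                             intercept_br = -14, noise_sd = noise, seed = s)
      fit_cross_halogen(generate_bde_table(spec), "Br")$slope - 0.9
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  r <- vapply(c(0, 3, 10), rmse_at, numeric(1))
  expect_equal(r[1], 0, tolerance = 1e-10)
  expect_true(all(diff(r) > 0))
})

test_that("toy libraries parse and targets satisfy the generating rule exactly", {
  toy <- generate_toy_library(40, seed = 3)
  expect_identical(toy, generate_toy_library(40, seed = 3))
  graphs <- mol_graphs(toy$smiles)
  expect_true(all(vapply(graphs, graph_is_connected, TRUE)))
  recomputed <- vapply(seq_len(nrow(toy)), function(i) {
    toy_composition_rule(as.list(toy[i, c("C", "N", "O", "F", "Cl", "Br", "I")]))
  }, numeric(1))
  expect_equal(toy$target, recomputed)
  # heavy-atom counts in the parsed molecule match the bookkeeping
  parsed_n <- vapply(graphs, `[[`, 1L, "n")
  expect_equal(parsed_n, rowSums(toy[, c("C", "N", "O", "F", "Cl", "Br", "I")]))
  # the rule is exactly linear in composition
  fit <- lm(target ~ C + N + O + F + Cl + Br + I, data = toy)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})
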