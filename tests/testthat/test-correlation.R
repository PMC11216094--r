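test_that("cross-halogen fits reproduce the published equations at 2 d.p.", {
  hom <- homolytic_records()
  het <- heterolytic_records()
  maps <- list(
    list(fit_cross_halogen(hom, "Br"), 0.89, -13.85, 100),
    list(fit_cross_halogen(hom, "Cl"), 0.76, -26.02, 100),
    list(fit_cross_halogen(het, "Br"), 0.96, -20.50, 69),
    list(fit_cross_halogen(het, "Cl"), 0.92, -29.39, 69)
  )
  for (m in maps) {
    expect_equal(round(m[[1]]$slope, 2), m[[2]])
    # printed intercepts carry a +/-0.01 rounding ambiguity at 2 d.p.
    expect_lt(abs(m[[1]]$intercept - m[[3]]), 0.015)
    expect_equal(m[[1]]$n_pairs, m[[4]])
    expect_gte(m[[1]]$r_squared, 0)
    expect_lte(m[[1]]$r_squared, 1)
  }
  # heterolytic correlations are much tighter than homolytic ones
  expect_gt(fit_cross_halogen(het, "Br")$r_squared, 0.99)
  expect_lt(fit_cross_halogen(hom, "Cl")$r_squared, 0.7)
})

test_that("an exact line is recovered exactly and matches the normal equations", {
  x <- c(1, 2, 4, 7, 9)
  recs <- data.frame(skeleton_id = 1, group_id = letters[1:5],
                     halogen = rep(c("I", "Br"), each = 5),
                     bde_kcal_mol = c(x, 2 * x + 1),
                     bde_type = "synthetic")
  fit <- fit_cross_halogen(recs, "Br")
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  set.seed(99)
  for (i in 1:5) {
    xs <- rnorm(40, 50, 12)
    ys <- 0.8 * xs - 10 + rnorm(40, 0, 4)
    recs <- data.frame(skeleton_id = rep(1:4, 10), group_id = rep(letters[1:10], each = 4),
                       halogen = "I", bde_kcal_mol = xs, bde_type = "synthetic")
    recs <- rbind(recs, transform(recs, halogen = "Br", bde_kcal_mol = ys))
    fit <- fit_cross_halogen(recs, "Br")
    ref <- ols_normal_equations(xs, ys)
    expect_lt(abs(fit$slope - ref["slope"]), 1e-8)
    expect_lt(abs(fit$intercept - ref["intercept"]), 1e-8)
  }
})

test_that("too few matched pairs is an error", {
  recs <- data.frame(skeleton_id = 1, group_id = c("a", "b"),
                     halogen = rep(c("I", "Br"), each = 2),
                     bde_kcal_mol = c(1, 2, 3, NA), bde_type = "x")
  expect_error(fit_cross_halogen(recs, "Br"), "3 matched")
})

test_that("iodine-based prediction is affine, monotone, and matches worked examples", {
  m_hom <- linear_map(slope = 0.89, intercept = -13.85)
  m_het <- linear_map(slope = 0.96, intercept = -20.50)
  expect_equal(round(predict_from_iodine(m_hom, 32.6), 1), 15.2)
  expect_equal(round(predict_from_iodine(m_het, 79.9), 1), 56.2)
  expect_equal(predict_from_iodine(m_hom, 0), m_hom$intercept)
  x <- sort(runif(20, -10, 90))
  expect_true(all(diff(predict_from_iodine(m_hom, x)) > 0))
})

test_that("metrics match definitions, a brute-force oracle, and the printed RMSEs", {
  # printed machine-learning row vs DFT reference for the external reagents
  ml <- c(72.7, 45.2, 27.2, 38.1, 13.3, -4.5)
  dft <- c(68.3, 44.1, 26.2, 32.6, 10, -6.2)
  expect_equal(round(compute_metrics(ml, dft)$rmse, 1), 3.3)

  ident <- compute_metrics(dft, dft)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$mae, 0)
  expect_equal(ident$rmse, 0)

  set.seed(7)
  p <- rnorm(100); r <- rnorm(100)
  met <- compute_metrics(p, r)
  rmse_loop <- 0; mae_loop <- 0
  for (i in seq_along(p)) {
    rmse_loop <- rmse_loop + (p[i] - r[i])^2
    mae_loop <- mae_loop + abs(p[i] - r[i])
  }
  expect_lt(abs(met$rmse - sqrt(rmse_loop / 100)), 1e-10)
  expect_lt(abs(met$mae - mae_loop / 100), 1e-10)
  expect_lte(met$mae, met$rmse)

  expect_error(compute_metrics(1:3, 1:4), "equal length")
  expect_error(compute_metrics(c(1, 2), c(5, 5)), "constant")
})

test_that("R-squared of the fit is invariant under a shared affine rescaling", {
  tab <- generate_bde_table(synthetic_spec(noise_sd = 4, seed = 21))
  f1 <- fit_cross_halogen(tab, "Br")
  tab2 <- tab
  tab2$bde_kcal_mol <- 3.7 * tab2$bde_kcal_mol - 11
  f2 <- fit_cross_halogen(tab2, "Br")
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("external validation reproduces the published LE row and RMSE comparison", {
  ev <- external_validation("homolytic")
  expect_equal(ev$maps$Br$slope, 0.89)
  expect_equal(ev$maps$Cl$intercept, -26.02)
  row <- ev$table[ev$table$group_label == "CF2SO2Ph" & ev$table$halogen == "Br", ]
  expect_equal(row$le_pred_kcal_mol, 15.2)
  expect_equal(round(ev$rmse_le, 1), 3.9)
  expect_equal(round(ev$rmse_ml, 1), 3.3)
  expect_lt(ev$rmse_ml, ev$rmse_le)

  ev_het <- external_validation("heterolytic")
  row <- ev_het$table[ev_het$table$group_label == "CF2SO2Ph" & ev_het$table$halogen == "Br", ]
  expect_equal(row$le_pred_kcal_mol, 56.2)
  expect_lt(ev_het$rmse_ml, ev_het$rmse_le)
})
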