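quick_cfg <- function(max_epochs = 80, ...) {
  gat_config(hidden_dim = 16, heads = 2, max_epochs = max_epochs, patience = 0,
             val_fraction = 0, seed = 3, ...)
}

test_that("analytic gradients match finite differences", {
  toy <- toy_set(8, seed = 13)
  batch <- halogat:::batch_graphs(toy$graphs)
  cfg <- gat_config(n_layers = 2, heads = 2, hidden_dim = 8)
  set.seed(5)
  params <- halogat:::init_params(ncol(batch$X), cfg)
  y <- as.numeric(scale(toy$data$target))
  loss_fn <- function(p) mean((halogat:::gat_forward(p, batch, cfg)$yhat - y)^2)
  fwd <- halogat:::gat_forward(params, batch, cfg)
  dy <- 2 * (fwd$yhat - y) / batch$n_graphs
  gr <- halogat:::gat_backward(params, batch, fwd, dy, cfg)

  eps <- 1e-6
  check_block <- function(analytic, get, set, probe) {
    p0 <- get(params)
    for (i in probe) {
      pp <- params; v <- p0; v[i] <- v[i] + eps; pp <- set(pp, v)
      pm <- params; v <- p0; v[i] <- v[i] - eps; pm <- set(pm, v)
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_lt(abs(analytic[i] - num), 1e-5 * max(1, abs(num)))
    }
  }
  check_block(as.numeric(gr$layers[[1]]$W),
              function(p) as.numeric(p$layers[[1]]$W),
              function(p, v) { p$layers[[1]]$W <- matrix(v, nrow(p$layers[[1]]$W)); p },
              c(1, 19, 57, 100))
  check_block(as.numeric(gr$layers[[1]]$a_src),
              function(p) as.numeric(p$layers[[1]]$a_src),
              function(p, v) { p$layers[[1]]$a_src <- matrix(v, 4); p },
              1:8)
  check_block(as.numeric(gr$layers[[2]]$a_dst),
              function(p) as.numeric(p$layers[[2]]$a_dst),
              function(p, v) { p$layers[[2]]$a_dst <- matrix(v, 4); p },
              1:8)
  check_block(gr$w_out, function(p) p$w_out,
              function(p, v) { p$w_out <- v; p }, c(1, 5, 8))
})

test_that("training reduces the loss substantially on a small library", {
  toy <- toy_set(20, seed = 17)
  model <- train_gat(toy$graphs, toy$data$target,
                     gat_config(max_epochs = 200, patience = 0,
                                val_fraction = 0, seed = 1))
  h <- model$history
  expect_true(all(is.finite(h$train_mse)))
  expect_lt(h$train_mse[nrow(h)], 0.5 * h$train_mse[1])
})

test_that("training is reproducible for a fixed seed", {
  toy <- toy_set(20, seed = 17)
  cfg <- quick_cfg(max_epochs = 40)
  m1 <- train_gat(toy$graphs, toy$data$target, cfg)
  m2 <- train_gat(toy$graphs, toy$data$target, cfg)
  diffs <- c(
    max(abs(m1$params$layers[[1]]$W - m2$params$layers[[1]]$W)),
    max(abs(m1$params$layers[[2]]$a_src - m2$params$layers[[2]]$a_src)),
    max(abs(m1$params$w_out - m2$params$w_out))
  )
  expect_lt(max(diffs), 1e-6)
  expect_identical(m1$history, m2$history)
})

test_that("predictions are invariant to atom relabeling", {
  toy <- toy_set(30, seed = 11)
  model <- train_gat(toy$graphs, toy$data$target, quick_cfg())
  pairs <- list(c("CCOC(F)C", "CC(F)OCC"),
                c("NC(Cl)CC", "CCC(Cl)N"),
                c("CC(Br)C(I)CO", "OCC(I)C(Br)C"))
  for (p in pairs) {
    pred <- predict_bde(model, mol_graphs(p))
    expect_lt(abs(pred[1] - pred[2]), 1e-5)
  }
})

test_that("a heavily overfitted model memorizes five molecules to 1 kcal/mol", {
  toy <- toy_set(5, seed = 23)
  model <- train_gat(toy$graphs, toy$data$target,
                     gat_config(max_epochs = 1500, patience = 0,
                                val_fraction = 0, learning_rate = 1e-2, seed = 2))
  pred <- predict_bde(model, toy$graphs)
  expect_lt(max(abs(pred - toy$data$target)), 1)
})

test_that("early stopping returns the best-epoch model", {
  toy <- toy_set(30, seed = 11)
  model <- train_gat(toy$graphs, toy$data$target,
                     gat_config(max_epochs = 150, patience = 20, seed = 4),
                     split = split_dataset(toy$data, 0.2, seed = 4))
  h <- model$history
  expect_equal(h$val_mse[model$best_epoch], min(h$val_mse))
  # held-out indices never enter the training or validation sets
  expect_length(intersect(model$split$test, c(model$train_idx, model$val_idx)), 0)
})

test_that("interface errors are caught", {
  toy <- toy_set(20, seed = 17)
  model <- train_gat(toy$graphs, toy$data$target, quick_cfg(max_epochs = 5))
  species_only <- mol_to_graph("CCO", descriptor_config(use_charge = FALSE,
                                                        use_neighbor_info = FALSE))
  expect_error(predict_bde(model, species_only), "feature length")
  expect_error(evaluate_gat(model, list(), numeric(0)), "empty")
  expect_error(train_gat(toy$graphs, toy$data$target[-1], quick_cfg()))
})

test_that("evaluate_gat agrees with compute_metrics on the same predictions", {
  toy <- toy_set(30, seed = 11)
  sp <- split_dataset(toy$data, 0.2, seed = 9)
  model <- train_gat(toy$graphs, toy$data$target, quick_cfg(), sp)
  met <- evaluate_gat(model, toy$graphs[sp$test], toy$data$target[sp$test])
  ref <- compute_metrics(predict_bde(model, toy$graphs[sp$test]),
                         toy$data$target[sp$test])
  expect_equal(met, ref)
})

test_that("ablation tables aggregate per-config seed runs", {
  toy <- toy_set(40, seed = 29)
  configs <- list(species = descriptor_config(use_charge = FALSE,
                                              use_neighbor_info = FALSE),
                  all = descriptor_config())
  tab <- run_ablation(toy$data$smiles, toy$data$target, configs, seeds = 1:2,
                      model_config = quick_cfg(max_epochs = 40))
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$config, c("species", "all"))
  expect_equal(nrow(attr(tab, "runs")), 4)
  expect_equal(tab$mean_test_r2, sort(tab$mean_test_r2, decreasing = TRUE))
  single <- run_ablation(toy$data$smiles, toy$data$target, configs["all"],
                         seeds = 1, model_config = quick_cfg(max_epochs = 20))
  expect_equal(nrow(single), 1)
})
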