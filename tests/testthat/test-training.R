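test_that("cross-validated training yields one member per fold with histories", {
  ens <- small_trained_ensemble()
  expect_s3_class(ens, "apr_ensemble")
  expect_length(ens$members, 5)
  for (m in ens$members) {
    expect_s3_class(m, "apr_network")
    expect_false(is.na(m$stopping_epoch))
    expect_lte(m$stopping_epoch, nrow(m$history))
    expect_identical(names(m$history), c("epoch", "train_auc", "val_auc"))
  }
  expect_gte(ens$threshold, 0)
  expect_lte(ens$threshold, 1)
  expect_gte(ens$youden_j, 0)
})

test_that("training separates the synthetic classes and is deterministic", {
  dat <- gen_hexapeptides(150, 0.4, noise = 0, seed = 42)
  ens1 <- small_trained_ensemble()
  expect_gte(mean(ens1$fold_val_auc), 0.95)

  ens2 <- train_crossval(dat, tiny_config(), k = 5, seed = 42,
                         max_epochs = 20)
  expect_identical(vapply(ens1$members, `[[`, integer(1), "stopping_epoch"),
                   vapply(ens2$members, `[[`, integer(1), "stopping_epoch"))
  probe <- encode_dataset(dat[1:10, ], tiny_feature_table(),
                          require_labels = FALSE)
  expect_identical(predict_ensemble(ens1, probe$x),
                   predict_ensemble(ens2, probe$x))
})

test_that("training tolerates label noise at reduced but useful accuracy", {
  # the synthetic world stays learnable with 10% flipped labels
  seeds <- c(101, 202, 303)
  aucs <- vapply(seeds, function(s) {
    dat <- gen_hexapeptides(500, 0.36, noise = 0.1, seed = s)
    sp <- stratified_split(dat$label, 0.9, seed = s)
    ens <- train_crossval(dat[sp$train_indices, ], network_config(), k = 5,
                          seed = s)
    test <- dat[sp$test_indices, ]
    enc <- encode_dataset(test, require_labels = FALSE)
    attr(roc_curve(predict_ensemble(ens, enc$x), test$label), "auc")
  }, numeric(1))
  expect_true(all(aucs >= 0.8))
})

test_that("class weighting and no-scaling paths run and return valid models", {
  dat <- gen_hexapeptides(60, 0.3, noise = 0, seed = 13)
  enc <- encode_dataset(dat, tiny_feature_table())
  net <- fit_network(enc$x[1:40, , ], enc$y[1:40], enc$x[41:60, , ],
                     enc$y[41:60], tiny_config(), seed = 3, max_epochs = 5,
                     class_weight = "balanced", standardize = FALSE)
  expect_s3_class(net, "apr_network")
  expect_null(net$scaler)
  s <- predict_window(net, enc$x[1, , ])
  expect_true(s >= 0 && s <= 1)
})

test_that("hyperparameter search ranks configurations by validation AuROCC", {
  dat <- gen_hexapeptides(80, 0.5, noise = 0, seed = 55)
  good <- tiny_config()
  degenerate <- network_config(1, 1, 0.8, c(8, 8), 16, 1e-1)
  res <- hyperparameter_search(dat, configs = list(degenerate, good, good),
                               k = 4, seed = 55,
                               table = tiny_feature_table(), max_epochs = 8)
  expect_identical(nrow(res), 3L)
  expect_identical(res$rank, 1:3)
  expect_true(all(diff(res$mean_val_auc) <= 1e-12))
  # the sound configuration must outrank the degenerate one
  expect_identical(res$config[[1]]$dropout, good$dropout)

  expect_error(hyperparameter_search(dat, configs = list()), "empty")
  expect_error(hyperparameter_search(dat, budget = 0), "budget")
})

test_that("grid and random search strategies draw valid configurations", {
  grid <- aprscan:::draw_search_space(4, "grid", seed = 1)
  expect_length(grid, 4)
  rnd1 <- aprscan:::draw_search_space(4, "random", seed = 1)
  rnd2 <- aprscan:::draw_search_space(4, "random", seed = 1)
  expect_identical(rnd1, rnd2)
  for (cfg in c(grid, rnd1)) {
    expect_s3_class(cfg, "network_config")
    # search candidates stay on the power-of-two width grid
    expect_true(all(cfg$neurons_per_layer %in% 2^(3:9)))
  }
})
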