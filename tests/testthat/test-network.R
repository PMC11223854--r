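test_that("configuration validation names the violated bound", {
  expect_s3_class(network_config(), "network_config")
  expect_error(network_config(dropout = 0.5), "0.2 grid")
  expect_error(network_config(n_bidirectional_layers = 3), "1 or 2")
  expect_error(network_config(n_dense_layers = 0), "1, 2 or 3")
  expect_error(network_config(neurons_per_layer = c(64, 64, 96, 32, 4)),
               "\\[8, 512\\]")
  expect_error(network_config(neurons_per_layer = c(64, 64, 96, 32)),
               "must have 5 entries")
  expect_error(network_config(neurons_per_layer = c(64, 63, 96, 32, 32)),
               "even")
  expect_error(network_config(batch_size = 8), "16 or 32")
  expect_error(network_config(learning_rate = 5e-3), "1e-4")
})

test_that("the published configuration builds the 8-layer architecture", {
  net <- build_network(network_config(), seed = 1)
  expect_identical(n_layers(net), 8L)
  # widths of the published stack: projection 36->64, biLSTM 64 and 96,
  # dense 96->32->32->1
  expect_identical(dim(net$weights$proj$W), c(36L, 64L))
  expect_identical(dim(net$weights$rnn[[1]]$fwd$Wx), c(64L, 4L * 32L))
  expect_identical(dim(net$weights$rnn[[2]]$fwd$Wx), c(64L, 4L * 48L))
  expect_identical(dim(net$weights$dense[[1]]$W), c(96L, 32L))
  expect_identical(dim(net$weights$dense[[2]]$W), c(32L, 32L))
  expect_identical(dim(net$weights$dense[[3]]$W), c(32L, 1L))

  w <- encode_hexapeptide("NFGAIL", tiny_feature_table())
  s <- predict_window(net, w)
  expect_length(s, 1)
  expect_gte(s, 0)
  expect_lte(s, 1)
})

test_that("initialization and inference are deterministic under seed", {
  cfg <- tiny_config()
  w <- encode_hexapeptide("IVIVIV", tiny_feature_table())
  n1 <- build_network(cfg, seed = 123)
  n2 <- build_network(cfg, seed = 123)
  expect_identical(predict_window(n1, w), predict_window(n2, w))
  expect_identical(predict_window(n1, w), predict_window(n1, w))
  n3 <- build_network(cfg, seed = 124)
  expect_false(identical(predict_window(n1, w), predict_window(n3, w)))
})

test_that("scores stay in [0, 1] and batch prediction matches single windows", {
  ft <- tiny_feature_table()
  net <- build_network(tiny_config(), seed = 5)
  withr::with_seed(5, {
    seqs <- random_hexpeptide(20)
  })
  enc <- encode_dataset(tibble::tibble(sequence = seqs), ft,
                        require_labels = FALSE)
  batch <- predict_window(net, enc$x)
  expect_true(all(batch >= 0 & batch <= 1))
  singles <- vapply(seq_len(20), function(k) {
    predict_window(net, enc$x[k, , ])
  }, numeric(1))
  expect_equal(batch, singles, tolerance = 1e-12)
  expect_error(predict_window(net, matrix(0, 3, 36)), "6 x 36")
})

test_that("ensemble consensus is the arithmetic mean of member scores", {
  ft <- tiny_feature_table()
  members <- lapply(1:5, function(s) build_network(tiny_config(), seed = s))
  ens <- new_ensemble(members, threshold = 0.5)
  withr::with_seed(31, {
    seqs <- random_hexpeptide(8)
  })
  enc <- encode_dataset(tibble::tibble(sequence = seqs), ft,
                        require_labels = FALSE)
  consensus <- predict_ensemble(ens, enc$x)
  member_scores <- sapply(members, function(m) predict_window(m, enc$x))
  # mean oracle, recomputed in sorted order to vary the summation order
  manual <- apply(member_scores, 1, function(v) mean(sort(v)))
  expect_equal(consensus, manual, tolerance = 1e-12)
  expect_true(all(consensus >= 0 & consensus <= 1))

  # permutation invariance in member order
  ens_perm <- new_ensemble(members[c(3, 5, 1, 4, 2)], threshold = 0.5)
  expect_equal(predict_ensemble(ens_perm, enc$x), consensus,
               tolerance = 1e-12)

  # all members identical -> consensus equals any member
  same <- new_ensemble(members[c(1, 1, 1, 1, 1)], threshold = 0.5)
  expect_equal(predict_ensemble(same, enc$x),
               predict_window(members[[1]], enc$x), tolerance = 1e-15)
})

test_that("an ensemble has exactly five members unless explicitly overridden", {
  members <- lapply(1:3, function(s) build_network(tiny_config(), seed = s))
  expect_error(new_ensemble(members), "exactly 5 members")
  expect_message(ens <- new_ensemble(members, allow_any_members = TRUE),
                 "3 members")
  expect_length(ens$members, 3)
})

test_that("models round-trip through save/load bit-identically", {
  ft <- tiny_feature_table()
  ens <- small_trained_ensemble()
  withr::with_seed(33, {
    probes <- random_hexpeptide(10)
  })
  enc <- encode_dataset(tibble::tibble(sequence = probes), ft,
                        require_labels = FALSE)
  dir <- withr::local_tempdir()
  save_model(ens, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  re <- load_model(dir)
  expect_identical(predict_ensemble(re, enc$x), predict_ensemble(ens, enc$x))
  # member order is preserved: probe each member individually
  for (m in 1:5) {
    expect_identical(predict_window(re$members[[m]], enc$x),
                     predict_window(ens$members[[m]], enc$x))
  }
  expect_equal(re$threshold, ens$threshold)

  # single-network round trip
  net <- ens$members[[2]]
  dir2 <- withr::local_tempdir()
  save_model(net, dir2)
  re_net <- load_model(dir2)
  expect_identical(predict_window(re_net, enc$x), predict_window(net, enc$x))
})

test_that("corrupted or incomplete model directories are refused", {
  ens <- small_trained_ensemble()
  dir <- withr::local_tempdir()
  save_model(ens, dir)

  file.remove(file.path(dir, "member_3.rds"))
  expect_error(load_model(dir), "missing member weight file")

  dir2 <- withr::local_tempdir()
  save_model(ens, dir2)
  # truncate a weight file
  writeBin(readBin(file.path(dir2, "member_1.rds"), "raw", 50),
           file.path(dir2, "member_1.rds"))
  expect_error(load_model(dir2), "corrupted member weight file")

  dir3 <- withr::local_tempdir()
  save_model(ens, dir3)
  mf <- jsonlite::read_json(file.path(dir3, "manifest.json"))
  mf$format_version <- "0.0"
  jsonlite::write_json(mf, file.path(dir3, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(load_model(dir3), "version mismatch")
  expect_error(load_model(withr::local_tempdir()), "no manifest")
})
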