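test_that("a sequence fragments into L - 5 overlapping hexapeptide windows", {
  w <- sequence_to_windows("ACDEFGHI")
  expect_identical(w$start, 1:3)
  expect_identical(w$sequence, c("ACDEFG", "CDEFGH", "DEFGHI"))

  w6 <- sequence_to_windows("NFGAIL")
  expect_identical(nrow(w6), 1L)
  expect_identical(w6$sequence, "NFGAIL")

  withr::with_seed(14, {
    for (rep in 1:20) {
      L <- sample(6:200, 1)
      s <- random_protein(L)
      ws <- sequence_to_windows(s)
      expect_identical(nrow(ws), L - 5L)
      for (j in sample(nrow(ws), min(5, nrow(ws)))) {
        expect_identical(ws$sequence[j], substr(s, j, j + 5))
      }
    }
  })
  expect_error(sequence_to_windows("ACDEF"), "at least 6")
  expect_error(sequence_to_windows("ACDEFGXZ"), "'X' at position 7")
})

test_that("per-residue aggregation averages the covering windows", {
  const <- aggregate_per_residue(rep(0.7, 15), length = 20)
  expect_equal(const$scores, rep(0.7, 20))
  expect_identical(const$coverage[1:6], 1:6)
  expect_identical(const$coverage[7:14], rep(6L, 8))

  # the L = 7 worked case: window 1 covers 1-6, window 2 covers 2-7
  agg <- aggregate_per_residue(c(0, 1), length = 7)
  expect_equal(agg$scores, c(0, 0.5, 0.5, 0.5, 0.5, 0.5, 1))
  expect_identical(agg$coverage, c(1L, 2L, 2L, 2L, 2L, 2L, 1L))

  withr::with_seed(15, {
    for (rep in 1:25) {
      L <- sample(6:150, 1)
      ws <- runif(L - 5)
      got <- aggregate_per_residue(ws, L)
      expect_equal(got$scores, oracle_coverage_mean(ws, L),
                   tolerance = 1e-12)
      expect_true(all(got$coverage >= 1 & got$coverage <= 6))
    }
  })
  expect_error(aggregate_per_residue(c(0.1, 0.2), length = 10),
               "expected 5 window scores")
})

test_that("profile_sequence composes windowing, consensus scoring and aggregation", {
  ft <- tiny_feature_table()
  ens <- small_trained_ensemble()
  withr::with_seed(16, {
    s <- random_protein(40)
  })
  prof <- profile_sequence(ens, s, table = ft, sequence_id = "p1")
  expect_s3_class(prof, "residue_profile")
  expect_identical(nrow(prof), 40L)
  expect_identical(prof$residue, strsplit(s, "")[[1]])
  expect_true(all(prof$score >= 0 & prof$score <= 1))

  # pipeline oracle: manual composition of the three component operations
  ws <- sequence_to_windows(s)
  enc <- encode_dataset(ws, ft, require_labels = FALSE)
  wscores <- predict_ensemble(ens, enc$x)
  manual <- aggregate_per_residue(wscores, 40)
  expect_equal(prof$score, manual$scores, tolerance = 1e-15)
  expect_identical(prof$coverage, manual$coverage)

  # single-window sequence: every residue equals the ensemble score
  hex <- "IVIVIV"
  p6 <- profile_sequence(ens, hex, table = ft)
  e6 <- predict_ensemble(ens, encode_hexapeptide(hex, ft))
  expect_equal(p6$score, rep(e6, 6), tolerance = 1e-15)

  # aux channels are carried through, never computed
  aux <- profile_sequence(ens, s, table = ft,
                          aux_channels = list(tm_propensity = runif(40)))
  expect_true("tm_propensity" %in% names(aux))
  expect_error(profile_sequence(ens, s, table = ft,
                                aux_channels = list(bad = 1:3)),
               "length 3")
})

test_that("APR calls require at least six consecutive above-threshold residues", {
  mk_prof <- function(scores) {
    structure(tibble::tibble(sequence_id = "x",
                             position = seq_along(scores),
                             score = scores),
              class = c("residue_profile", class(tibble::tibble())))
  }
  # 5-residue peak above threshold: rejected
  p5 <- mk_prof(c(rep(0.1, 10), rep(0.9, 5), rep(0.1, 10)))
  expect_identical(nrow(call_aprs(p5, 0.5)), 0L)
  # 6-residue peak: accepted with exact bounds
  p6 <- mk_prof(c(rep(0.1, 10), rep(0.9, 6), rep(0.1, 10)))
  calls <- call_aprs(p6, 0.5)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$start, 11L)
  expect_identical(calls$end, 16L)
  expect_identical(calls$length, 6L)
  expect_equal(calls$mean_score, 0.9)
  # residues exactly at the threshold count as above
  peq <- mk_prof(c(rep(0.5, 6), rep(0.4, 6)))
  expect_identical(nrow(call_aprs(peq, 0.5)), 1L)
  # all below: empty
  expect_identical(nrow(call_aprs(mk_prof(rep(0.2, 30)), 0.5)), 0L)

  withr::with_seed(17, {
    for (rep in 1:20) {
      prof <- mk_prof(runif(sample(30:120, 1)))
      th <- runif(1, 0.2, 0.8)
      calls <- call_aprs(prof, th)
      if (nrow(calls) > 0) {
        expect_true(all(calls$length >= 6))
        expect_true(all(calls$end >= calls$start))
        if (nrow(calls) > 1) {
          expect_true(all(calls$start[-1] > calls$end[-nrow(calls)]))
        }
        for (r in seq_len(nrow(calls))) {
          expect_true(all(prof$score[calls$start[r]:calls$end[r]] >= th))
        }
      }
      # monotonicity: raising the threshold never adds APR residues
      n_res <- function(th) sum(call_aprs(prof, th)$length)
      expect_gte(n_res(th), n_res(min(th + 0.1, 1)))
    }
  })
  expect_error(call_aprs(mk_prof(runif(10)), 1.5), "\\[0, 1\\]")
})
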