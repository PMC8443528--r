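test_that("load_dataset parses well-formed rows and flags bad ones", {
  # header-only file
  p <- write_fixture_tsv(fixture_entries()[0, ])
  ds <- load_dataset(p)
  expect_equal(nrow(ds), 0)
  expect_equal(nrow(validation_report(ds)), 0)

  # 3-row hand-written fixture round-trips field by field
  rows <- fixture_entries()[1:3, ]
  ds <- load_dataset(write_fixture_tsv(rows))
  expect_equal(nrow(ds), 3)
  expect_equal(ds$wt_aa, c("V", "V", "V"))
  expect_equal(ds$d_tm, c(-1, -3, -5))
  expect_equal(ds$tm_wt, rep(65.1, 3))
  expect_equal(ds$residue_number, 1:3)

  # self-substitution is quarantined, not silently dropped
  rows$mut_aa[2] <- "V"
  ds <- load_dataset(write_fixture_tsv(rows))
  expect_equal(nrow(ds), 2)
  rep_ <- validation_report(ds)
  expect_equal(rep_$reason, "self-substitution")
  expect_equal(rep_$row, 2L)

  # unparseable numeric flags the row
  rows <- fixture_entries()[1:3, ]
  rows$d_tm <- as.character(rows$d_tm)
  rows$d_tm[3] <- "not-a-number"
  ds <- load_dataset(write_fixture_tsv(rows))
  expect_equal(nrow(ds), 2)
  expect_true("unparseable-or-missing-numeric" %in% validation_report(ds)$reason)

  # missing required column is fatal and names the column
  bad <- fixture_entries()[, setdiff(names(fixture_entries()), "tm_wt")]
  expect_error(load_dataset(write_fixture_tsv(bad)), "tm_wt")
})

test_that("dTm records violating invariants are quarantined with reasons", {
  rows <- fixture_entries()[1:4, ]
  rows$d_tm[1] <- 25       # beyond the truncation limit
  rows$ph[2] <- 15         # impossible pH
  rows$rsa[3] <- -0.2      # negative RSA
  ds <- mutation_dataset(rows)
  expect_equal(nrow(ds), 1)
  expect_setequal(validation_report(ds)$reason,
                  c("dtm-out-of-range", "ph-out-of-range", "negative-rsa"))
})

test_that("stability classification uses a closed neutral band", {
  expect_equal(classify_stability(-2.5), "destabilizing")
  expect_equal(classify_stability(0), "neutral")
  expect_equal(classify_stability(2.0), "neutral")   # boundary is neutral
  expect_equal(classify_stability(-2.0), "neutral")
  expect_equal(classify_stability(3.1), "stabilizing")
  expect_error(classify_stability(NaN), "non-finite")
  expect_error(classify_stability(1, threshold = 0))

  # perturbing the threshold moves both boundaries consistently
  eps <- 1e-9
  expect_equal(classify_stability(2.0, 2 - eps), "stabilizing")
  expect_equal(classify_stability(-2.0, 2 - eps), "destabilizing")
})

test_that("summarize_dataset reports consistent composition statistics", {
  ds <- fixture_dataset()
  s <- summarize_dataset(ds)
  expect_equal(unname(s$ph_fractions["6-8"]), 0.5)  # 5 of 10 at pH 7
  # partition fractions sum to 1 (overlay bands excluded)
  expect_equal(sum(s$ph_fractions[c("<6", "6-8", ">8")]), 1, tolerance = 1e-9)
  expect_equal(sum(s$dtm_category_fractions[c("destabilizing", "neutral",
                                              "stabilizing")]), 1,
               tolerance = 1e-9)
  expect_equal(sum(s$technique_fractions), 1, tolerance = 1e-9)
  # category fractions agree with a direct per-entry tally
  tally <- table(classify_stability(ds$d_tm)) / nrow(ds)
  expect_equal(unname(s$dtm_category_fractions["destabilizing"]),
               unname(tally[["destabilizing"]]))
  expect_equal(unname(s$dtm_category_fractions["stabilizing"]),
               unname(tally[["stabilizing"]]))
  expect_equal(sum(s$per_protein_counts$n), nrow(ds))

  # degenerate composition
  rows <- fixture_entries()
  rows$d_tm <- 0
  expect_equal(unname(
    summarize_dataset(mutation_dataset(rows))$dtm_category_fractions["neutral"]),
    1.0)

  # perfect RSA/B-factor correlation
  rows <- fixture_entries()
  rows$avg_b <- rows$rsa
  expect_equal(summarize_dataset(mutation_dataset(rows))$rsa_b_correlation, 1.0)

  expect_error(summarize_dataset(mutation_dataset(fixture_entries()[0, ])),
               "empty")
})

test_that("substitution matrix counts and statistics are exact", {
  # empty dataset
  sm0 <- substitution_matrix(mutation_dataset(fixture_entries()[0, ]))
  expect_true(all(sm0$counts == 0))
  expect_equal(sm0$coverage, 0)

  # 4 V->A entries with hand-computed mean and sample SD
  ds <- fixture_dataset()
  sm <- substitution_matrix(ds)
  expect_equal(sm$counts["V", "A"], 4L)
  expect_equal(sm$mean_dtm["V", "A"], mean(c(-1, -3, -5, -7)))
  expect_equal(sm$sd_dtm["V", "A"], sqrt(sum((c(-1, -3, -5, -7) + 4)^2) / 3))
  # cells below the reporting threshold have no mean
  expect_equal(sm$counts["I", "A"], 1L)
  expect_true(is.na(sm$mean_dtm["I", "A"]))
  # total counts equal dataset size; diagonal empty
  expect_equal(sum(sm$counts), nrow(ds))
  expect_true(all(diag(sm$counts) == 0))

  # one entry per each of the 380 ordered pairs: full coverage, no means
  subs <- all_substitutions()
  rows <- tibble::tibble(protein_id = "1ABC", chain = "A",
                         residue_number = seq_len(380),
                         wt_aa = subs$wt_aa, mut_aa = subs$mut_aa,
                         tm_wt = 60, d_tm = 1)
  sm1 <- substitution_matrix(mutation_dataset(rows), report_threshold = 3)
  expect_equal(sm1$coverage, 1.0)
  expect_true(all(is.na(sm1$mean_dtm)))

  # permutation invariance
  perm <- fixture_entries()[sample.int(10), ]
  sm_p <- substitution_matrix(mutation_dataset(perm))
  expect_equal(sm_p$counts, sm$counts)
  expect_equal(sm_p$mean_dtm, sm$mean_dtm)
})

test_that("binned profiles partition entries and track generators", {
  # equal-count bins hold equal numbers
  set.seed(42)
  rows <- tibble::tibble(protein_id = "1ABC", chain = "A",
                         residue_number = 1:100, wt_aa = "V", mut_aa = "A",
                         tm_wt = 60, d_tm = stats::rnorm(100),
                         rsa = stats::runif(100))
  prof <- binned_profile(mutation_dataset(rows), "rsa", n_bins = 10)
  expect_equal(prof$n, rep(10L, 10))
  expect_equal(sum(prof$n), 100)

  # noise-free linear generator: per-bin mean increases with rsa
  rows$d_tm <- -10 * (1 - rows$rsa)
  prof <- binned_profile(mutation_dataset(rows), "rsa", n_bins = 5)
  expect_true(all(diff(prof$mean_dtm) > 0))

  # single bin equals the dataset mean
  prof1 <- binned_profile(mutation_dataset(rows), "rsa", n_bins = 1)
  expect_equal(prof1$mean_dtm, mean(rows$d_tm))

  expect_error(binned_profile(fixture_dataset(), "rsa", n_bins = 50),
               "annotated")
})
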