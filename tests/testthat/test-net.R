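test_that("mock wild-type augmentation adds 15 zero-dTm rows per protein", {
  ds <- fixture_dataset()  # 2 proteins, fully annotated
  aug <- augment_with_wt(ds, n_per_protein = 15, seed = 1)
  expect_equal(nrow(aug), nrow(ds) + 30)
  mocks <- aug[aug$wt_aa == aug$mut_aa, ]
  expect_equal(nrow(mocks), 30)
  expect_true(all(mocks$d_tm == 0))
  expect_equal(as.vector(table(mocks$protein_id)), c(15, 15))
  # original entries untouched
  expect_equal(tibble::as_tibble(aug)[seq_len(nrow(ds)), ],
               tibble::as_tibble(ds))

  # n = 0 leaves the dataset unchanged
  expect_identical(augment_with_wt(ds, 0), ds)

  # seeded reproducibility
  expect_identical(tibble::as_tibble(augment_with_wt(ds, 15, seed = 9)),
                   tibble::as_tibble(augment_with_wt(ds, 15, seed = 9)))

  # protein with no annotated residues is skipped with a warning
  rows <- fixture_entries()
  rows$rsa[rows$protein_id == "2XYZ"] <- NA
  expect_warning(aug2 <- augment_with_wt(mutation_dataset(rows), 15, 1),
                 "2XYZ")
  expect_equal(nrow(aug2), nrow(rows) + 15)
})

test_that("reverse augmentation is exactly antisymmetric with copied features", {
  ds <- fixture_dataset()
  rev <- augment_with_reversed(ds)
  n <- nrow(ds)
  expect_equal(nrow(rev), 2 * n)
  expect_equal(rev$d_tm[seq_len(n)] + rev$d_tm[n + seq_len(n)], rep(0, n))
  expect_equal(rev$wt_aa[n + seq_len(n)], ds$mut_aa)
  expect_equal(rev$mut_aa[n + seq_len(n)], ds$wt_aa)
  expect_equal(rev$rsa[n + seq_len(n)], ds$rsa)
  expect_equal(rev$avg_b[n + seq_len(n)], ds$avg_b)
  expect_equal(rev$ss_code[n + seq_len(n)], ds$ss_code)

  # single entry worked example
  one <- mutation_dataset(fixture_entries()[2, ])  # V->A, dTm -3
  r1 <- augment_with_reversed(one)
  expect_equal(r1$wt_aa[2], "A")
  expect_equal(r1$mut_aa[2], "V")
  expect_equal(r1$d_tm[2], 3)

  # reversed-only half: transpose counts, negated means
  rev_only <- mutation_dataset(tibble::as_tibble(rev)[n + seq_len(n), ],
                               validate = FALSE)
  sm_f <- substitution_matrix(ds, report_threshold = 3)
  sm_r <- substitution_matrix(rev_only, report_threshold = 3)
  expect_equal(sm_r$counts, t(sm_f$counts))
  expect_equal(sm_r$mean_dtm, -t(sm_f$mean_dtm))
})

test_that("splitting is disjoint, exhaustive and seed-reproducible", {
  sim <- small_synth(100, seed = 2)
  parts <- split_dataset(sim$dataset, seed = 4)
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 60L, validation = 30L, test = 10L))
  # union of parts equals input as multisets
  all_rows <- dplyr::bind_rows(lapply(parts, tibble::as_tibble))
  key <- function(d) sort(paste(d$protein_id, d$residue_number, d$wt_aa,
                                d$mut_aa, d$d_tm))
  expect_equal(key(all_rows), key(tibble::as_tibble(sim$dataset)))
  # same seed, same partition
  parts2 <- split_dataset(sim$dataset, seed = 4)
  expect_identical(tibble::as_tibble(parts$train),
                   tibble::as_tibble(parts2$train))
  expect_error(split_dataset(sim$dataset, fractions = c(0.5, 0.5, 0.2)),
               "fractions")
  expect_error(split_dataset(mutation_dataset(fixture_entries()[1:3, ])),
               "too small")
})

test_that("training honors the smoke contract and is deterministic", {
  sim <- small_synth(120, seed = 5)
  parts <- split_dataset(sim$dataset, seed = 1)
  cfg <- net_config(max_epochs = 1, early_stop_patience = 1, seed = 7)
  m <- train_baseline(parts$train, parts$validation, cfg)
  expect_equal(nrow(m$history), 1)
  expect_s3_class(m, "tm_baseline")

  cfg2 <- net_config(max_epochs = 50, early_stop_patience = 10, seed = 7)
  m1 <- train_baseline(parts$train, parts$validation, cfg2)
  m2 <- train_baseline(parts$train, parts$validation, cfg2)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  # prediction is a pure function of (weights, normalizer, input)
  expect_identical(predict(m1, parts$test), predict(m2, parts$test))
})

test_that("a model trained on all-zero targets predicts near zero", {
  # degenerate-target oracle: a handful of substitutions so the held-out
  # entries share the training support
  set.seed(11)
  n <- 250
  pairs <- data.frame(wt = c("V", "L", "I", "G", "E"),
                      mut = c("A", "A", "T", "W", "K"))
  pick <- sample(5, n, replace = TRUE)
  rows <- tibble::tibble(
    protein_id = "S001", chain = "A",
    residue_number = sample(100, n, TRUE),
    wt_aa = pairs$wt[pick], mut_aa = pairs$mut[pick],
    tm_wt = 60, d_tm = 0,
    rsa = stats::runif(n), avg_b = stats::runif(n, 5, 80),
    ss_code = sample(c(-1, 0, 1), n, TRUE))
  parts <- split_dataset(mutation_dataset(rows), seed = 2)
  m <- train_baseline(parts$train, parts$validation,
                      net_config(max_epochs = 2000,
                                 early_stop_patience = 500, seed = 1))
  preds <- predict(m, parts$test)
  expect_true(all(abs(preds) < 0.1))
  # grid predictions are total: finite everywhere, no NaN
  g <- generate_grid(m, substitutions = tibble::tibble(wt_aa = "V",
                                                       mut_aa = "A"))
  expect_true(all(is.finite(g$pred_dtm)))
})

test_that("evaluation metrics match their closed-form definitions", {
  expect_equal(evaluate(1:5, 1:5)$rmse, 0)
  expect_equal(evaluate(1:5, 1:5)$pearson_r, 1)

  ev <- evaluate(1:5 + 0.5, 1:5)
  expect_equal(ev$rmse, 0.5)
  expect_equal(unname(ev$error_band_fractions["lt1"]), 1)

  # hand-sized oracle from the direct formulas
  p <- c(1.2, -3.4, 0.0, 5.6, 2.1)
  o <- c(0.8, -2.9, 1.1, 4.0, 2.2)
  ev <- evaluate(p, o)
  expect_equal(ev$rmse, sqrt(sum((p - o)^2) / 5), tolerance = 1e-12)
  r_direct <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  expect_equal(as.numeric(ev$pearson_r), r_direct, tolerance = 1e-12)
  expect_true(ev$error_band_fractions["ge10"] <=
                ev$error_band_fractions["gt5"])

  # zero variance: r undefined but flagged, rmse still returned
  ev0 <- evaluate(rep(1, 3), c(1, 2, 3))
  expect_true(is.na(ev0$pearson_r))
  expect_true(attr(ev0$pearson_r, "r_undefined"))
  expect_equal(ev0$rmse, sqrt(mean(c(0, 1, 2)^2)))
  expect_error(evaluate(1:3, 1:4), "equal length")
})

test_that("replicate training selects deterministically by validation RMSE", {
  sim <- small_synth(150, seed = 8, noise_sd = 1)
  aug <- augment_with_wt(sim$dataset, 5, seed = 1)
  cfg <- fast_net(seed = 1)
  reps <- replicate_training(aug, n_replicates = 3, cfg = cfg,
                             split_seeds = c(11L, 12L, 13L))
  expect_length(reps$models, 3)
  expect_equal(nrow(reps$metrics), 3)
  expect_true(reps$selected %in% 1:3)
  expect_named(reps$dispersion, c("min", "median", "max"))
  expect_true(reps$dispersion["min"] <= reps$dispersion["median"])
  # selection is invariant to replicate order
  reps_perm <- replicate_training(aug, 3, cfg, split_seeds = c(13L, 11L, 12L))
  expect_equal(reps_perm$metrics$split_seed[reps_perm$selected],
               reps$metrics$split_seed[reps$selected])
})

test_that("model JSON serialization round-trips predictions", {
  sim <- small_synth(120, seed = 5)
  parts <- split_dataset(sim$dataset, seed = 1)
  m <- train_baseline(parts$train, parts$validation, fast_net(seed = 3))
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(predict(m2, parts$test), predict(m, parts$test),
               tolerance = 1e-12)
})
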