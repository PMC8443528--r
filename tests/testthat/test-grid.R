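test_that("the prediction grid enumerates 462 cells per substitution in order", {
  sim <- small_synth(120, seed = 5)
  parts <- split_dataset(sim$dataset, seed = 1)
  m <- train_baseline(parts$train, parts$validation, fast_net(seed = 3))

  g1 <- generate_grid(m, substitutions = tibble::tibble(wt_aa = "V",
                                                        mut_aa = "A"))
  expect_equal(nrow(g1), 462)
  # documented enumeration order: ss, then rsa, then b (b fastest)
  expect_equal(unlist(g1[1, c("ss", "rsa", "b")]),
               c(ss = -1, rsa = 0, b = 10))
  expect_equal(g1$b[1:14], seq(10, 140, by = 10))
  expect_equal(g1$rsa[15], 0.1)
  expect_equal(sort(unique(g1$ss)), c(-1, 0, 1))
  expect_equal(length(unique(g1$rsa)), 11)
  expect_equal(length(unique(g1$b)), 14)

  # row count is |substitutions| x 462 for any subset
  subs3 <- all_substitutions()[c(1, 50, 200), ]
  expect_equal(nrow(generate_grid(m, substitutions = subs3)), 3 * 462)
})

test_that("per-substitution OLS recovers exact generators and refuses tiny fits", {
  # noise-free entries generated from the transcribed linear coefficients
  set.seed(31)
  n <- 25
  rows <- tibble::tibble(
    protein_id = "1ABC", chain = "A", residue_number = seq_len(n),
    wt_aa = "V", mut_aa = "A", tm_wt = 60,
    rsa = stats::runif(n), avg_b = stats::runif(n, 5, 60),
    ss_code = sample(c(-1, 0, 1), n, replace = TRUE))
  rows$d_tm <- 12.63 * rows$rsa - 0.089 * rows$avg_b +
    1.95 * rows$ss_code - 5.81
  ds <- mutation_dataset(rows)
  fit <- fit_substitution_regression(ds, "V", "A")
  expect_equal(unname(fit$coefficients),
               c(-5.81, 12.63, -0.089, 1.95), tolerance = 1e-8)
  expect_equal(fit$rmse, 0, tolerance = 1e-8)
  expect_equal(fit$n_entries, n)

  # refusal below min_entries names the count
  expect_error(fit_substitution_regression(ds[1:3, ], "V", "A"),
               "3 annotated")
  # rank-deficient design is rejected
  rows2 <- rows; rows2$rsa <- 0.5; rows2$ss_code <- 1
  expect_error(fit_substitution_regression(mutation_dataset(rows2),
                                           "V", "A"),
               "rank-deficient")
})

test_that("OLS equals the normal-equations closed form on random instances", {
  set.seed(99)
  for (trial in seq_len(100)) {
    n <- sample(10:25, 1)
    rows <- tibble::tibble(
      protein_id = "1ABC", chain = "A", residue_number = seq_len(n),
      wt_aa = "L", mut_aa = "G", tm_wt = 60,
      rsa = stats::runif(n), avg_b = stats::runif(n, 5, 80),
      ss_code = sample(c(-1, 0, 1), n, replace = TRUE),
      d_tm = stats::rnorm(n, -3, 4))
    # guard against accidental collinearity in tiny draws
    X <- cbind(1, rows$rsa, rows$avg_b, rows$ss_code)
    if (qr(X)$rank < 4) next
    fit <- fit_substitution_regression(mutation_dataset(rows), "L", "G")
    beta <- solve(crossprod(X), crossprod(X, rows$d_tm))
    expect_equal(unname(fit$coefficients), as.numeric(beta),
                 tolerance = 1e-10)
  }
})

test_that("the transcribed Val-to-Ala reference equations evaluate exactly", {
  expect_equal(eval_reference_equation("val_ala_linear", 0, 0, 0), -5.81)
  expect_equal(eval_reference_equation("val_ala_symbolic", 0, ss = 0), -7.35)
  # direct arithmetic on the printed coefficients
  expect_equal(eval_reference_equation("val_ala_linear", 1, 0, 0),
               12.63 - 5.81)
  expect_equal(eval_reference_equation("val_ala_linear", 0.5, 20, 1),
               12.63 * 0.5 - 0.089 * 20 + 1.95 - 5.81)
  expect_equal(eval_reference_equation("val_ala_symbolic", 0.5, ss = 1),
               1 - 1 / (8.58 * 0.5 - 0.89) + 13.56 * 0.5 - 7.35)

  # the symbolic form is flagged undefined at its pole
  expect_warning(v <- eval_reference_equation("val_ala_symbolic",
                                              0.89 / 8.58, ss = 1),
                 "pole")
  expect_true(is.na(v))
  expect_error(eval_reference_equation("nope", 0))
})

test_that("the linear reference equation is monotone over the grid domain", {
  spec <- grid_spec()
  for (ss in spec$ss_values) {
    for (b in spec$b_values) {
      v <- eval_reference_equation("val_ala_linear", spec$rsa_values, b, ss)
      expect_true(all(diff(v) > 0))  # increasing in RSA
    }
    for (rsa in spec$rsa_values) {
      v <- eval_reference_equation("val_ala_linear", rsa, spec$b_values, ss)
      expect_true(all(diff(v) < 0))  # decreasing in B-factor
    }
  }
})

test_that("web-app export writes one JSON per substitution plus an index", {
  ds <- fixture_dataset()
  two <- mutation_dataset(tibble::as_tibble(ds)[ds$wt_aa %in% c("V", "L"), ])
  sim <- small_synth(120, seed = 5)
  parts <- split_dataset(sim$dataset, seed = 1)
  m <- train_baseline(parts$train, parts$validation, fast_net(seed = 3))
  g <- generate_grid(m, substitutions = tibble::tibble(
    wt_aa = c("V", "L"), mut_aa = c("A", "A")))
  out <- file.path(tempfile(), "webapp")
  files <- export_webapp_json(two, g, out)
  expect_equal(sort(list.files(out)),
               sort(c("V_A.json", "L_A.json", "index.json")))
  # every experimental entry appears in exactly one file
  docs <- lapply(file.path(out, c("V_A.json", "L_A.json")),
                 jsonlite::read_json, simplifyVector = TRUE)
  expect_equal(sum(vapply(docs, function(d) d$n_entries, numeric(1))),
               nrow(two))
  va <- docs[[1]]
  expect_equal(va$wt_aa, "V")
  expect_equal(nrow(va$grid), 462)
  expect_true(all(va$entries$category %in%
                    c("destabilizing", "neutral", "stabilizing")))
  idx <- jsonlite::read_json(file.path(out, "index.json"),
                             simplifyVector = TRUE)
  expect_setequal(idx$substitutions, c("V_A", "L_A"))
})
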