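# Training-protocol plumbing around the baseline network: mock wild-type
# augmentation, forward+reverse augmentation, splitting, replicated
# training, evaluation metrics, and the forward/reverse symmetry
# experiment.

as_mutation_dataset <- function(d, template) {
  structure(tibble::as_tibble(d),
            provenance = attr(template, "provenance"),
            validation = attr(template, "validation"),
            class = class(template))
}

#' Augment a dataset with mock wild-type "mutations"
#'
#' For each protein, adds `n_per_protein` rows sampled (with replacement)
#' from that protein's structurally annotated entries, with the mutant
#' amino acid set equal to the wild type and dTm set to 0. This teaches
#' the network that the identity substitution changes nothing, which
#' improves the baseline. Original entries are untouched; proteins with no
#' annotated entries are skipped with a warning.
#'
#' @param ds An annotated `mutation_dataset`.
#' @param n_per_protein Mock rows per protein (default 15).
#' @param seed Integer seed for the residue sampling.
#' @return The augmented `mutation_dataset` (mock rows are recognizable by
#'   `wt_aa == mut_aa`).
#' @export
augment_with_wt <- function(ds, n_per_protein = 15, seed = 1) {
  stopifnot(n_per_protein >= 0)
  d <- tibble::as_tibble(ds)
  if (n_per_protein == 0) return(ds)
  set.seed(seed)
  annotated <- !is.na(d$rsa) & !is.na(d$avg_b) & !is.na(d$ss_code)
  mocks <- lapply(unique(d$protein_id), function(pid) {
    pool <- which(d$protein_id == pid & annotated)
    if (length(pool) == 0) {
      warning("protein ", pid, " has no annotated residues; skipped",
              call. = FALSE)
      return(NULL)
    }
    take <- sample(pool, n_per_protein, replace = TRUE)
    mock <- d[take, ]
    mock$mut_aa <- mock$wt_aa
    mock$d_tm <- 0
    mock
  })
  as_mutation_dataset(dplyr::bind_rows(list(d), mocks), ds)
}

#' Augment a dataset with all reversed mutations
#'
#' Appends, for every entry, the reverse mutation (mutant to wild type)
#' with negated dTm, wild-type Tm shifted to the mutant's Tm, and the
#' structural features copied unchanged from the forward entry (the
#' wild-type structure stands in for the unknown mutant structure). The
#' output has exactly twice the entries and is antisymmetric by
#' construction: forward/reverse dTm pairs sum to zero.
#'
#' @param ds A `mutation_dataset`.
#' @return The doubled `mutation_dataset` (forward entries first).
#' @export
augment_with_reversed <- function(ds) {
  d <- tibble::as_tibble(ds)
  rev <- d
  rev$wt_aa <- d$mut_aa
  rev$mut_aa <- d$wt_aa
  rev$d_tm <- -d$d_tm
  rev$tm_wt <- d$tm_wt + d$d_tm
  as_mutation_dataset(dplyr::bind_rows(d, rev), ds)
}

#' Split a dataset into train / validation / test parts
#'
#' Seeded random partition into disjoint, exhaustive parts. Train and
#' validation sizes are floored; the remainder goes to test.
#'
#' @param ds A `mutation_dataset` with at least 10 entries.
#' @param fractions Positive fractions `(train, validation, test)` summing
#'   to 1 (default `c(0.6, 0.3, 0.1)`).
#' @param seed Integer shuffle seed.
#' @return Named list of three `mutation_dataset`s: `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(ds, fractions = c(0.6, 0.3, 0.1), seed = 1) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-12) {
    stop("fractions must be three positive numbers summing to 1",
         call. = FALSE)
  }
  n <- nrow(ds)
  if (n < 10) stop("dataset too small to split (", n, " < 10)",
                   call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  d <- tibble::as_tibble(ds)
  list(train = as_mutation_dataset(d[idx[seq_len(n_train)], ], ds),
       validation = as_mutation_dataset(
         d[idx[n_train + seq_len(n_val)], ], ds),
       test = as_mutation_dataset(
         d[idx[(n_train + n_val + 1):n], ], ds))
}

#' Evaluate predictions against observations
#'
#' Computes RMSE, the Pearson correlation, and the shares of absolute
#' prediction errors in the bands `[0, 1)`, `[1, 4]`, `(5, Inf)` and
#' `[10, Inf)` degrees C. The last two bands overlap by construction
#' (the `[10, Inf)` share is contained in the `(5, Inf)` share); they are
#' reported this way because that is how baseline-accuracy breakdowns are
#' conventionally quoted for this problem. If either vector has zero
#' variance the correlation is undefined: `pearson_r` is `NA` with
#' attribute `r_undefined = TRUE` (RMSE is still returned).
#'
#' @param predictions,observations Equal-length numeric vectors
#'   (length at least 2), degrees C.
#' @return Object of class `tm_metrics`: list with `rmse`, `pearson_r`,
#'   `error_band_fractions` (named `lt1`, `b1to4`, `gt5`, `ge10`), `n`.
#' @export
evaluate <- function(predictions, observations) {
  if (length(predictions) != length(observations) ||
      length(predictions) < 2) {
    stop("predictions and observations must have equal length >= 2",
         call. = FALSE)
  }
  err <- predictions - observations
  rmse <- sqrt(mean(err^2))
  r <- if (stats::sd(predictions) == 0 || stats::sd(observations) == 0) {
    structure(NA_real_, r_undefined = TRUE)
  } else {
    stats::cor(predictions, observations)
  }
  ae <- abs(err)
  structure(list(
    rmse = rmse,
    pearson_r = r,
    error_band_fractions = c(lt1 = mean(ae < 1),
                             b1to4 = mean(ae >= 1 & ae <= 4),
                             gt5 = mean(ae > 5),
                             ge10 = mean(ae >= 10)),
    n = length(err)
  ), class = "tm_metrics")
}

#' @export
print.tm_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.2f C, Pearson r %s, n = %d\n", x$rmse,
              ifelse(is.na(x$pearson_r), "undefined",
                     sprintf("%.2f", x$pearson_r)), x$n))
  cat(sprintf("|error| bands: <1 C %.0f%%, 1-4 C %.0f%%, >5 C %.0f%%, >=10 C %.0f%%\n",
              100 * x$error_band_fractions["lt1"],
              100 * x$error_band_fractions["b1to4"],
              100 * x$error_band_fractions["gt5"],
              100 * x$error_band_fractions["ge10"]))
  invisible(x)
}

#' Train replicated baselines over different random splits
#'
#' Trains one network per random split of the (already augmented) dataset
#' and evaluates each on its own held-out test part. The final model is
#' selected by the deterministic rule "best validation RMSE" (ties broken
#' by split seed), replacing any manual pick; selection is invariant to
#' replicate order.
#'
#' @param ds The full (augmented) annotated `mutation_dataset`.
#' @param n_replicates Number of replicate splits (default 20).
#' @param cfg Base [net_config()]; each replicate trains with
#'   `seed = cfg$seed + i`.
#' @param split_seeds Integer vector of split seeds (default
#'   `seq_len(n_replicates)` offset by `cfg$seed`).
#' @param fractions Split fractions (default `c(0.6, 0.3, 0.1)`).
#' @param table Property table.
#' @return Object of class `tm_replicates`: list with `models` (list of
#'   `tm_baseline`), `metrics` (tibble: replicate, split_seed,
#'   train/validation/test RMSE and r), `selected` (index of the chosen
#'   replicate), `dispersion` (min/median/max test RMSE).
#' @export
replicate_training <- function(ds, n_replicates = 20, cfg = net_config(),
                               split_seeds = NULL,
                               fractions = c(0.6, 0.3, 0.1),
                               table = default_property_table()) {
  stopifnot(n_replicates >= 1)
  if (is.null(split_seeds)) split_seeds <- cfg$seed * 1000L + seq_len(n_replicates)
  stopifnot(length(split_seeds) == n_replicates)
  runs <- lapply(seq_len(n_replicates), function(i) {
    parts <- split_dataset(ds, fractions, seed = split_seeds[i])
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    model <- train_baseline(parts$train, parts$validation, cfg_i, table)
    mets <- lapply(parts, function(p) {
      evaluate(predict(model, p), p$d_tm)
    })
    list(model = model,
         row = tibble::tibble(
           replicate = i, split_seed = split_seeds[i],
           train_rmse = mets$train$rmse, train_r = as.numeric(mets$train$pearson_r),
           val_rmse = mets$validation$rmse,
           val_r = as.numeric(mets$validation$pearson_r),
           test_rmse = mets$test$rmse, test_r = as.numeric(mets$test$pearson_r)),
         test_metrics = mets$test)
  })
  metrics <- dplyr::bind_rows(lapply(runs, `[[`, "row"))
  selected <- order(metrics$val_rmse, metrics$split_seed)[1]
  structure(list(models = lapply(runs, `[[`, "model"),
                 metrics = metrics,
                 test_metrics = lapply(runs, `[[`, "test_metrics"),
                 selected = selected,
                 dispersion = c(min = min(metrics$test_rmse),
                                median = stats::median(metrics$test_rmse),
                                max = max(metrics$test_rmse))),
            class = "tm_replicates")
}

#' @export
print.tm_replicates <- function(x, ...) {
  cat(sprintf("%d replicate networks; test RMSE min/median/max = %.2f/%.2f/%.2f C; selected replicate %d\n",
              nrow(x$metrics), x$dispersion["min"], x$dispersion["median"],
              x$dispersion["max"], x$selected))
  invisible(x)
}

#' Forward/reverse symmetry experiment
#'
#' For each seed, splits the forward dataset, trains (a) a model on the
#' forward training entries and (b) a model on the forward training
#' entries plus all their reversals, and evaluates both on the same
#' forward test part. Also reports, for each model, the prediction
#' asymmetry statistic: the RMS of (forward prediction + reverse
#' prediction) over the test entries, which is 0 for a perfectly
#' antisymmetric predictor.
#'
#' @param ds An annotated forward `mutation_dataset`.
#' @param cfg Base [net_config()].
#' @param seeds Integer vector of split seeds (one experiment per seed).
#' @param n_mock_per_protein Mock wild-type rows per protein added to each
#'   training set (default 15; applied to both arms identically).
#' @param fractions Split fractions.
#' @param table Property table.
#' @return Object of class `tm_symmetry`: list with `per_seed` (tibble:
#'   seed, forward-model and reverse-augmented-model test RMSE/r and
#'   asymmetry) and `median` (named vector of medians over seeds).
#' @export
symmetry_experiment <- function(ds, cfg = net_config(), seeds = 1:5,
                                n_mock_per_protein = 15,
                                fractions = c(0.6, 0.3, 0.1),
                                table = default_property_table()) {
  rows <- lapply(seeds, function(s) {
    parts <- split_dataset(ds, fractions, seed = s)
    tr_fwd <- augment_with_wt(parts$train, n_mock_per_protein, seed = s)
    tr_rev <- augment_with_reversed(tr_fwd)
    cfg_f <- cfg; cfg_f$seed <- cfg$seed + s
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + s
    m_fwd <- train_baseline(tr_fwd, parts$validation, cfg_f, table)
    m_rev <- train_baseline(tr_rev, parts$validation, cfg_r, table)
    test_rev <- augment_with_reversed(parts$test)
    test_rev <- test_rev[seq(nrow(parts$test) + 1, nrow(test_rev)), ]
    asym <- function(model) {
      pf <- predict(model, parts$test)
      pr <- predict(model, test_rev)
      sqrt(mean((pf + pr)^2))
    }
    ev_f <- evaluate(predict(m_fwd, parts$test), parts$test$d_tm)
    ev_r <- evaluate(predict(m_rev, parts$test), parts$test$d_tm)
    tibble::tibble(seed = s,
                   forward_rmse = ev_f$rmse,
                   forward_r = as.numeric(ev_f$pearson_r),
                   reversed_rmse = ev_r$rmse,
                   reversed_r = as.numeric(ev_r$pearson_r),
                   forward_asymmetry = asym(m_fwd),
                   reversed_asymmetry = asym(m_rev))
  })
  per_seed <- dplyr::bind_rows(rows)
  structure(list(per_seed = per_seed,
                 median = vapply(per_seed[-1], stats::median, numeric(1))),
            class = "tm_symmetry")
}

#' @export
print.tm_symmetry <- function(x, ...) {
  cat(sprintf("symmetry experiment over %d seeds (medians): forward-only test RMSE %.2f C, forward+reversed test RMSE %.2f C\n",
              nrow(x$per_seed), x$median["forward_rmse"],
              x$median["reversed_rmse"]))
  cat(sprintf("prediction asymmetry (RMS of fwd+rev): forward-only %.2f, forward+reversed %.2f\n",
              x$median["forward_asymmetry"], x$median["reversed_asymmetry"]))
  invisible(x)
}
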