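# Baseline prediction grid, per-substitution linear regression, and the
# transcribed Val-to-Ala reference equations.

#' Structural-feature grid specification
#'
#' The canonical grid over the three structural inputs: secondary
#' structure in \{-1, 0, +1\}, RSA from 0 to 1 every 0.1 (11 values), and
#' mean B-factor from 10 to 140 every 10 (14 values) — 3 x 11 x 14 = 462
#' combinations per substitution.
#'
#' @param ss_values,rsa_values,b_values Override the default axes.
#' @return List of class `grid_spec`.
#' @export
grid_spec <- function(ss_values = c(-1, 0, 1),
                      rsa_values = seq(0, 1, by = 0.1),
                      b_values = seq(10, 140, by = 10)) {
  structure(list(ss_values = ss_values, rsa_values = rsa_values,
                 b_values = b_values),
            class = "grid_spec")
}

#' Tabulate baseline predictions over the structural-feature grid
#'
#' Runs a trained baseline network over every combination of secondary
#' structure, RSA, and mean B-factor in the grid, for each requested
#' ordered substitution. Enumeration order is fixed and documented so
#' exports are diffable: substitutions in the given order, then secondary
#' structure ascending, then RSA ascending, then B-factor ascending
#' (B-factor varies fastest).
#'
#' @param model A `tm_baseline`.
#' @param spec A [grid_spec()].
#' @param substitutions Tibble with columns `wt_aa`, `mut_aa` (default
#'   [all_substitutions()], 380 pairs giving 175,560 rows).
#' @return Tibble of class `grid_table`: `wt_aa`, `mut_aa`, `ss`, `rsa`,
#'   `b`, `pred_dtm`.
#' @export
generate_grid <- function(model, spec = grid_spec(),
                          substitutions = all_substitutions()) {
  cells <- expand.grid(b = spec$b_values, rsa = spec$rsa_values,
                       ss = spec$ss_values, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("ss", "rsa", "b")]
  blocks <- lapply(seq_len(nrow(substitutions)), function(i) {
    tibble::tibble(wt_aa = substitutions$wt_aa[i],
                   mut_aa = substitutions$mut_aa[i],
                   ss = cells$ss, rsa = cells$rsa, b = cells$b)
  })
  out <- dplyr::bind_rows(blocks)
  X <- encode_mutation(out$wt_aa, out$mut_aa, rsa = out$rsa,
                       avg_b = out$b, ss_code = out$ss,
                       table = model$property_table)
  out$pred_dtm <- predict(model, X)
  structure(out, class = c("grid_table", class(out)))
}

#' Per-substitution multiple linear regression of dTm on structure
#'
#' Ordinary least squares of dTm on RSA, mean B-factor, and the ternary
#' secondary-structure code (entered as the numeric -1/0/+1 value), with
#' intercept, over the annotated entries of one ordered substitution.
#' Refuses to fit below `min_entries` observations, the floor under which
#' a 4-parameter fit is judged unstable.
#'
#' @param ds An annotated `mutation_dataset`.
#' @param wt_aa,mut_aa The ordered substitution.
#' @param min_entries Minimum observation count (default 10).
#' @return Object of class `substitution_lm`: list with `wt_aa`, `mut_aa`,
#'   `coefficients` (named: `intercept`, `rsa`, `avg_b`, `ss_code`, all
#'   degrees C scaled), `se` (standard errors, same names), `n_entries`,
#'   `rmse`, `pearson_r`, and the underlying `lm` fit.
#' @export
fit_substitution_regression <- function(ds, wt_aa, mut_aa,
                                        min_entries = 10) {
  assert_canonical(c(wt_aa, mut_aa))
  d <- tibble::as_tibble(ds)
  d <- d[d$wt_aa == wt_aa & d$mut_aa == mut_aa &
           !is.na(d$rsa) & !is.na(d$avg_b) & !is.na(d$ss_code), ]
  if (nrow(d) < min_entries) {
    stop("only ", nrow(d), " annotated ", wt_aa, "->", mut_aa,
         " entries; ", min_entries, " required", call. = FALSE)
  }
  fit <- stats::lm(d_tm ~ rsa + avg_b + ss_code, data = d)
  if (fit$rank < 4) {
    stop("rank-deficient design for ", wt_aa, "->", mut_aa,
         " (rank ", fit$rank, " < 4)", call. = FALSE)
  }
  co <- stats::coef(fit)
  # a perfect (noise-free) fit makes summary.lm warn about reliability;
  # the standard errors are still well-defined (zero)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  nm <- c(intercept = "(Intercept)", rsa = "rsa", avg_b = "avg_b",
          ss_code = "ss_code")
  pred <- stats::fitted(fit)
  structure(list(wt_aa = wt_aa, mut_aa = mut_aa,
                 coefficients = stats::setNames(co[nm], names(nm)),
                 se = stats::setNames(se[nm], names(nm)),
                 n_entries = nrow(d),
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 pearson_r = stats::cor(pred, d$d_tm),
                 fit = fit),
            class = "substitution_lm")
}

#' @export
print.substitution_lm <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("%s->%s (n = %d): dTm = %.2f RSA %+.3f B %+.2f SS %+.2f  [RMSE %.2f C, r %.2f]\n",
              x$wt_aa, x$mut_aa, x$n_entries, co["rsa"], co["avg_b"],
              co["ss_code"], co["intercept"], x$rmse, x$pearson_r))
  invisible(x)
}

# Transcribed reference equations for Val-to-Ala mutations (fixtures, not
# fitted here). Coefficients are immutable.
REFERENCE_EQUATIONS <- list(
  val_ala_linear = list(
    form = "dTm = 12.63 RSA - 0.089 B + 1.95 SS - 5.81",
    coefficients = c(rsa = 12.63, b = -0.089, ss = 1.95,
                     intercept = -5.81)),
  val_ala_symbolic = list(
    form = "dTm = SS - SS / (8.58 RSA - 0.89) + 13.56 RSA - 7.35",
    parameters = c(a = 8.58, b = -0.89, c = 13.56, d = -7.35),
    pole_rsa = 0.89 / 8.58)
)

#' Evaluate a shipped Val-to-Ala reference equation
#'
#' Evaluates one of the two transcribed reference models of Val-to-Ala
#' dTm from structural features: `"val_ala_linear"`, a multiple linear
#' regression `dTm = 12.63 RSA - 0.089 B + 1.95 SS - 5.81`, or
#' `"val_ala_symbolic"`, the closed form
#' `dTm = SS - SS / (8.58 RSA - 0.89) + 13.56 RSA - 7.35`. Both are
#' shipped as immutable fixtures. The symbolic form has a pole at
#' RSA = 0.89 / 8.58; within `1e-9` of it the value is returned as `NA`
#' with a warning (flagged undefined) rather than an infinity.
#'
#' @param name `"val_ala_linear"` or `"val_ala_symbolic"`.
#' @param rsa,b,ss Structural features (vectorized; `b` is ignored by the
#'   symbolic form, which does not use the B-factor).
#' @return Predicted dTm, degrees C.
#' @export
#' @examples
#' eval_reference_equation("val_ala_linear", rsa = 0, b = 0, ss = 0)  # -5.81
#' eval_reference_equation("val_ala_symbolic", rsa = 0, ss = 0)       # -7.35
eval_reference_equation <- function(name = c("val_ala_linear",
                                             "val_ala_symbolic"),
                                    rsa, b = 0, ss = 0) {
  name <- match.arg(name)
  stopifnot(all(is.finite(rsa)), all(is.finite(b)), all(is.finite(ss)))
  eq <- REFERENCE_EQUATIONS[[name]]
  if (name == "val_ala_linear") {
    co <- eq$coefficients
    unname(co["rsa"] * rsa + co["b"] * b + co["ss"] * ss + co["intercept"])
  } else {
    p <- eq$parameters
    denom <- p["a"] * rsa + p["b"]
    out <- ss - ss / denom + p["c"] * rsa + p["d"]
    at_pole <- abs(rsa - eq$pole_rsa) < 1e-9
    if (any(at_pole)) {
      warning("rsa at the pole of the symbolic form (RSA = ",
              format(eq$pole_rsa), "); value undefined", call. = FALSE)
      out[at_pole] <- NA_real_
    }
    unname(out)
  }
}

#' Export per-substitution JSON documents for the data-navigation web app
#'
#' Writes one JSON document per ordered substitution present in the
#' dataset, each holding that substitution's experimental entries (with
#' their stability category from [classify_stability()], the app's color
#' code) and, when a grid table is supplied, the baseline grid
#' predictions for the same substitution; plus an `index.json` listing
#' the files. Schema: `{wt_aa, mut_aa, n_entries, entries: [{protein_id,
#' chain, residue_number, d_tm, category, rsa, avg_b, ss_code}], grid:
#' [{ss, rsa, b, pred_dtm}]}`.
#'
#' @param ds A `mutation_dataset`.
#' @param grid Optional `grid_table` from [generate_grid()].
#' @param out_dir Output directory (created if absent).
#' @param threshold Stability band half-width, degrees C.
#' @return Character vector of written file paths (invisibly).
#' @export
export_webapp_json <- function(ds, grid = NULL, out_dir,
                               threshold = 2) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", out_dir, call. = FALSE)
  }
  d <- tibble::as_tibble(ds)
  d$category <- classify_stability(d$d_tm, threshold)
  subs <- dplyr::distinct(d, .data$wt_aa, .data$mut_aa)
  files <- character(0)
  for (i in seq_len(nrow(subs))) {
    wt <- subs$wt_aa[i]; mut <- subs$mut_aa[i]
    di <- d[d$wt_aa == wt & d$mut_aa == mut, ]
    doc <- list(wt_aa = wt, mut_aa = mut, n_entries = nrow(di),
                entries = di[, c("protein_id", "chain", "residue_number",
                                 "d_tm", "category", "rsa", "avg_b",
                                 "ss_code")])
    if (!is.null(grid)) {
      gi <- grid[grid$wt_aa == wt & grid$mut_aa == mut,
                 c("ss", "rsa", "b", "pred_dtm")]
      doc$grid <- gi
    }
    path <- file.path(out_dir, paste0(wt, "_", mut, ".json"))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
    files <- c(files, path)
  }
  index <- file.path(out_dir, "index.json")
  jsonlite::write_json(
    list(substitutions = paste0(subs$wt_aa, "_", subs$mut_aa),
         files = basename(files)),
    index, auto_unbox = TRUE)
  invisible(c(files, index))
}
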