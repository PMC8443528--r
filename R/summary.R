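#' Summarize a mutation dataset
#'
#' Computes the composition statistics used to characterize a dTm mutation
#' dataset: pH-band fractions, a 1 degree C wild-type Tm histogram,
#' stability-category fractions, technique fractions, per-protein entry
#' counts, and (when RSA and mean B-factor annotations are present on at
#' least 3 entries) the Pearson correlation between RSA and mean B-factor.
#'
#' The pH bands `<6`, `6-8` and `>8` partition the entries with a recorded
#' pH (band edges: `ph < 6`, `6 <= ph <= 8`, `ph > 8`); the `<=3.5` share
#' is an overlay of the `<6` band, not part of the partition. Likewise
#' `within_1` (|dTm| <= 1) overlays the neutral category.
#'
#' @param ds A non-empty `mutation_dataset`.
#' @param threshold Stability band half-width in degrees C passed to
#'   [classify_stability()].
#' @return An object of class `tm_summary`: a list with elements
#'   `n_entries`, `ph_fractions`, `tm_histogram`, `dtm_category_fractions`,
#'   `technique_fractions`, `per_protein_counts`, `rsa_b_correlation`.
#' @export
summarize_dataset <- function(ds, threshold = 2) {
  if (nrow(ds) == 0) stop("empty dataset", call. = FALSE)
  d <- tibble::as_tibble(ds)

  ph <- d$ph[!is.na(d$ph)]
  ph_fractions <- if (length(ph) > 0) {
    c("<6"    = mean(ph < 6),
      "6-8"   = mean(ph >= 6 & ph <= 8),
      ">8"    = mean(ph > 8),
      "<=3.5" = mean(ph <= 3.5))
  } else {
    c("<6" = NA_real_, "6-8" = NA_real_, ">8" = NA_real_, "<=3.5" = NA_real_)
  }

  bin_left <- floor(d$tm_wt)
  tm_histogram <- dplyr::count(tibble::tibble(bin_left = bin_left),
                               .data$bin_left, name = "count")

  cat_ <- classify_stability(d$d_tm, threshold)
  dtm_category_fractions <- c(
    destabilizing = mean(cat_ == "destabilizing"),
    neutral       = mean(cat_ == "neutral"),
    stabilizing   = mean(cat_ == "stabilizing"),
    within_1      = mean(abs(d$d_tm) <= 1)
  )

  tech <- d$technique[!is.na(d$technique)]
  technique_fractions <- if (length(tech) > 0) {
    tab <- table(factor(tech, levels = union(TECHNIQUES, unique(tech))))
    tab <- tab[tab > 0 | names(tab) %in% TECHNIQUES]
    stats::setNames(as.numeric(tab) / length(tech), names(tab))
  } else {
    stats::setNames(numeric(0), character(0))
  }

  per_protein_counts <- dplyr::count(d, .data$protein_id, name = "n",
                                     sort = TRUE)

  annot <- !is.na(d$rsa) & !is.na(d$avg_b)
  rsa_b_correlation <- if (sum(annot) >= 3) {
    stats::cor(d$rsa[annot], d$avg_b[annot], method = "pearson")
  } else {
    NA_real_
  }

  structure(list(
    n_entries = nrow(d),
    ph_fractions = ph_fractions,
    tm_histogram = tm_histogram,
    dtm_category_fractions = dtm_category_fractions,
    technique_fractions = technique_fractions,
    per_protein_counts = per_protein_counts,
    rsa_b_correlation = rsa_b_correlation
  ), class = "tm_summary")
}

#' @export
print.tm_summary <- function(x, ...) {
  cat("dTm dataset summary:", x$n_entries, "entries,",
      nrow(x$per_protein_counts), "proteins\n")
  cat("categories:",
      paste(sprintf("%s %.1f%%", names(x$dtm_category_fractions),
                    100 * x$dtm_category_fractions), collapse = ", "), "\n")
  if (!is.na(x$rsa_b_correlation)) {
    cat(sprintf("RSA vs B-factor Pearson r = %.2f\n", x$rsa_b_correlation))
  }
  invisible(x)
}

#' Write a dataset summary as JSON
#'
#' @param s A `tm_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(s, path) {
  jsonlite::write_json(unclass(s), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Ordered-pair substitution matrix with dTm statistics
#'
#' Counts every ordered (wild type, mutant) substitution in the dataset and
#' reports the mean and sample standard deviation of dTm for pairs observed
#' at least `report_threshold` times (SD additionally requires at least 2
#' observations). The coverage fraction is the share of the 380
#' off-diagonal ordered pairs observed at least once.
#'
#' @param ds A `mutation_dataset`.
#' @param report_threshold Minimum count for reporting a cell mean
#'   (default 3).
#' @return An object of class `substitution_matrix`: list with 20 x 20
#'   matrices `counts`, `mean_dtm`, `sd_dtm` (rows = wild type, columns =
#'   mutant, [AA_ALPHABET] order), plus `report_threshold`, `coverage`,
#'   `n_entries`.
#' @export
substitution_matrix <- function(ds, report_threshold = 3) {
  d <- tibble::as_tibble(ds)
  counts <- matrix(0L, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  mean_dtm <- matrix(NA_real_, 20, 20,
                     dimnames = list(AA_ALPHABET, AA_ALPHABET))
  sd_dtm <- mean_dtm
  if (nrow(d) > 0) {
    stats_tbl <- dplyr::summarise(
      dplyr::group_by(d, .data$wt_aa, .data$mut_aa),
      n = dplyr::n(),
      m = mean(.data$d_tm),
      s = stats::sd(.data$d_tm),
      .groups = "drop")
    idx <- cbind(match(stats_tbl$wt_aa, AA_ALPHABET),
                 match(stats_tbl$mut_aa, AA_ALPHABET))
    counts[idx] <- as.integer(stats_tbl$n)
    report <- stats_tbl$n >= report_threshold
    mean_dtm[idx[report, , drop = FALSE]] <- stats_tbl$m[report]
    report_sd <- stats_tbl$n >= max(2, report_threshold)
    sd_dtm[idx[report_sd, , drop = FALSE]] <- stats_tbl$s[report_sd]
  }
  off_diag <- counts[row(counts) != col(counts)]
  structure(list(counts = counts, mean_dtm = mean_dtm, sd_dtm = sd_dtm,
                 report_threshold = report_threshold,
                 coverage = mean(off_diag >= 1),
                 n_entries = nrow(d)),
            class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("substitution matrix:", x$n_entries, "entries,",
      sprintf("coverage %.1f%% of 380 ordered pairs,", 100 * x$coverage),
      "report threshold", x$report_threshold, "\n")
  invisible(x)
}

#' Write a substitution matrix as delimited text and/or JSON
#'
#' Writes the three 20 x 20 grids (counts, mean, SD) as a tab-separated
#' file with a `stat` column, and optionally the whole object as JSON.
#'
#' @param sm A `substitution_matrix`.
#' @param path Output TSV path.
#' @param json_path Optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(sm, path, json_path = NULL) {
  grid <- function(m, stat) {
    out <- tibble::as_tibble(as.data.frame(m), rownames = "wt_aa")
    out$stat <- stat
    out[, c("stat", "wt_aa", AA_ALPHABET)]
  }
  readr::write_tsv(dplyr::bind_rows(grid(sm$counts, "count"),
                                    grid(sm$mean_dtm, "mean_dtm"),
                                    grid(sm$sd_dtm, "sd_dtm")), path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(counts = sm$counts, mean_dtm = sm$mean_dtm, sd_dtm = sm$sd_dtm,
           report_threshold = sm$report_threshold, coverage = sm$coverage,
           n_entries = sm$n_entries),
      json_path, auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  }
  invisible(path)
}

#' Bin dTm against a structural feature
#'
#' Groups annotated entries into bins of a structural feature (RSA or mean
#' B-factor) and reports per-bin dTm statistics, the device used to show
#' how effect magnitude depends on burial or flexibility. With
#' `equal_count = TRUE` (default) bins hold near-equal numbers of entries
#' (counts differ by at most 1); otherwise bins are equal-width over the
#' observed range.
#'
#' @param ds A `mutation_dataset` with the feature annotated on at least
#'   `n_bins` entries.
#' @param feature `"rsa"` or `"avg_b"`.
#' @param n_bins Number of bins.
#' @param equal_count Equal-count (quantile-like) binning flag.
#' @return Tibble with one row per bin: `bin`, `lo`, `hi` (observed value
#'   range), `mid`, `n`, `mean_dtm`, `sd_dtm`, `mean_abs_dtm`.
#' @export
binned_profile <- function(ds, feature = c("rsa", "avg_b"), n_bins = 10,
                           equal_count = TRUE) {
  feature <- match.arg(feature)
  d <- tibble::as_tibble(ds)
  x <- d[[feature]]
  keep <- !is.na(x)
  if (sum(keep) < n_bins) {
    stop("only ", sum(keep), " entries annotated with ", feature,
         " but ", n_bins, " bins requested", call. = FALSE)
  }
  d <- d[keep, ]
  x <- x[keep]
  if (n_bins == 1) {
    bin <- rep(1L, length(x))
  } else if (equal_count) {
    ord <- order(x)
    bin <- integer(length(x))
    # split sorted indices into n_bins contiguous chunks of near-equal size
    bin[ord] <- as.integer(cut(seq_along(ord), breaks = n_bins, labels = FALSE))
  } else {
    bin <- as.integer(cut(x, breaks = n_bins, include.lowest = TRUE,
                          labels = FALSE))
  }
  d$bin <- bin
  d$x <- x
  dplyr::summarise(dplyr::group_by(d, .data$bin),
                   lo = min(.data$x), hi = max(.data$x),
                   mid = (min(.data$x) + max(.data$x)) / 2,
                   n = dplyr::n(),
                   mean_dtm = mean(.data$d_tm),
                   sd_dtm = stats::sd(.data$d_tm),
                   mean_abs_dtm = mean(abs(.data$d_tm)),
                   .groups = "drop")
}
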