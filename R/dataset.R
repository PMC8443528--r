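#' Construct a mutation dataset
#'
#' A mutation dataset is a tibble with one row per accepted single-point
#' mutation record and a validation report attached as an attribute. Rows
#' violating the record invariants (self-substitution, non-canonical amino
#' acid, \eqn{|\Delta T_m| \ge 20} degrees C, pH outside (0, 14), negative
#' RSA, unparseable numbers) are quarantined: excluded from the entries but
#' listed, with reasons, in the validation report. Nothing is silently
#' dropped.
#'
#' @param entries A data frame with columns `protein_id`, `chain`,
#'   `residue_number`, `wt_aa`, `mut_aa`, `tm_wt`, `d_tm` and optionally
#'   `ph`, `technique`, `rsa`, `avg_b`, `ss_code`.
#' @param provenance Free-text source tag.
#' @param validate If `TRUE` (default) apply the record invariants and
#'   quarantine violating rows.
#' @return A tibble of class `mutation_dataset` with attributes
#'   `provenance` (character) and `validation` (tibble of quarantined or
#'   flagged rows: `row`, `reason`).
#' @export
mutation_dataset <- function(entries, provenance = "unspecified",
                             validate = TRUE) {
  required <- c("protein_id", "chain", "residue_number", "wt_aa", "mut_aa",
                "tm_wt", "d_tm")
  optional <- c("ph", "technique", "rsa", "avg_b", "ss_code")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  entries <- tibble::as_tibble(entries)
  for (col in optional) {
    if (!col %in% names(entries)) {
      entries[[col]] <- if (col == "technique") NA_character_ else NA_real_
    }
  }
  entries <- entries[, c(required, optional)]
  entries$residue_number <- as.integer(entries$residue_number)

  flags <- tibble::tibble(row = integer(), reason = character())
  if (validate && nrow(entries) > 0) {
    flag <- function(idx, reason) {
      tibble::tibble(row = which(idx), reason = reason)
    }
    bad_aa   <- !is_canonical_aa(entries$wt_aa) | !is_canonical_aa(entries$mut_aa)
    self_sub <- !bad_aa & entries$wt_aa == entries$mut_aa
    bad_num  <- !is.finite(entries$tm_wt) | !is.finite(entries$d_tm)
    big_dtm  <- !bad_num & abs(entries$d_tm) >= 20
    bad_ph   <- !is.na(entries$ph) & (entries$ph <= 0 | entries$ph >= 14)
    bad_rsa  <- !is.na(entries$rsa) & entries$rsa < 0
    flags <- dplyr::bind_rows(
      flag(bad_aa,   "unknown-amino-acid"),
      flag(self_sub, "self-substitution"),
      flag(bad_num,  "unparseable-or-missing-numeric"),
      flag(big_dtm,  "dtm-out-of-range"),
      flag(bad_ph,   "ph-out-of-range"),
      flag(bad_rsa,  "negative-rsa")
    )
    drop <- bad_aa | self_sub | bad_num | big_dtm | bad_ph | bad_rsa
    entries <- entries[!drop, , drop = FALSE]
  }

  structure(entries,
            provenance = provenance,
            validation = flags,
            class = c("mutation_dataset", class(tibble::tibble())))
}

#' Validation report of a mutation dataset
#'
#' @param ds A `mutation_dataset`.
#' @return Tibble with columns `row` (row index in the input) and `reason`.
#' @export
validation_report <- function(ds) {
  attr(ds, "validation") %||% tibble::tibble(row = integer(),
                                             reason = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a mutation table from delimited text
#'
#' Reads a UTF-8 delimited text file with one header row and one row per
#' single-point mutation. Required columns: `protein_id`, `chain`,
#' `residue_number`, `wt_aa`, `mut_aa`, `tm_wt`, `d_tm`; optional: `ph`,
#' `technique`, `rsa`, `avg_b`, `ss_code`. Unparseable numeric fields are
#' flagged at row level and the row quarantined; a missing required column
#' is a fatal error naming the column.
#'
#' @param path Path to the file.
#' @param delim Field delimiter (default tab).
#' @param col_map Optional named character vector mapping this package's
#'   canonical column names to the file's column names, for foreign
#'   layouts, e.g. `c(protein_id = "PDB")`.
#' @return A [mutation_dataset()].
#' @export
load_dataset <- function(path, delim = "\t", col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  required <- c("protein_id", "chain", "residue_number", "wt_aa", "mut_aa",
                "tm_wt", "d_tm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- intersect(c("residue_number", "tm_wt", "d_tm", "ph", "rsa",
                          "avg_b", "ss_code"), names(raw))
  for (col in num_cols) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  mutation_dataset(raw, provenance = path)
}

#' Write a mutation dataset as tab-separated text
#'
#' @param ds A `mutation_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  readr::write_tsv(tibble::as_tibble(ds), path)
  invisible(path)
}

#' Classify a melting-temperature change as (de)stabilizing or neutral
#'
#' Categories follow the convention used for coloring dTm data: changes
#' below `-threshold` are destabilizing, above `+threshold` stabilizing,
#' and the closed band `[-threshold, +threshold]` neutral (the boundary is
#' classified neutral).
#'
#' @param d_tm Numeric vector of melting-temperature changes, degrees C.
#' @param threshold Positive band half-width, degrees C (default 2).
#' @return Character vector in `{"destabilizing", "neutral", "stabilizing"}`.
#' @export
#' @examples
#' classify_stability(c(-2.5, 0, 2, 3.1))
classify_stability <- function(d_tm, threshold = 2) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  if (any(!is.finite(d_tm))) stop("non-finite d_tm", call. = FALSE)
  out <- rep("neutral", length(d_tm))
  out[d_tm < -threshold] <- "destabilizing"
  out[d_tm > threshold] <- "stabilizing"
  out
}
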