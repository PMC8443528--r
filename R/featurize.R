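# Featurization: the 19-number network input per mutation.
# Layout (fixed): slots 1-8 wild-type descriptor values, 9-16 descriptor
# deltas (mutant - wild type), 17 RSA, 18 mean C/N/O B-factor, 19 ternary
# secondary-structure code.

#' Names of the 8 physicochemical descriptor scales
#' @keywords internal
PROPERTY_SCALES <- c("hydrophobicity", "volume", "polarity", "charge",
                     "hbond", "flexibility", "helix_prop", "sheet_prop")

#' Names of the 19 feature slots, in order
#' @export
FEATURE_NAMES <- c(paste0("wt_", PROPERTY_SCALES),
                   paste0("d_", PROPERTY_SCALES),
                   "rsa", "avg_b", "ss_code")

#' The default amino-acid physicochemical property table
#'
#' 20 amino acids x 8 descriptor scales: Kyte-Doolittle hydrophobicity
#' (unitless), residue volume (Angstrom^3, Zamyatnin), Grantham polarity
#' (unitless), formal side-chain charge at neutral pH (-1/0/+1; Asp/Glu
#' -1, Lys/Arg +1, His and all others 0), side-chain hydrogen-bond
#' donor-plus-acceptor capacity (count), Vihinen average flexibility
#' (unitless), and Chou-Fasman helix and sheet propensities (unitless).
#' The table is a plain TSV config shipped with the package, so an
#' alternative descriptor set (any 8-scale layout) can be swapped in
#' without code change.
#'
#' @param path Optional path to an alternative table with the same layout
#'   (column `aa` plus 8 numeric scale columns).
#' @return A 20 x 8 numeric matrix, rows named by amino acid in
#'   [AA_ALPHABET] order, columns by scale name.
#' @export
default_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "property_table.tsv", package = "tmshift")
  }
  tbl <- utils::read.delim(path, check.names = FALSE)
  scales <- setdiff(names(tbl), "aa")
  if (nrow(tbl) != 20 || anyNA(tbl[scales]) ||
      !setequal(tbl$aa, AA_ALPHABET)) {
    stop("property table must be complete: 20 amino acids x named scales",
         call. = FALSE)
  }
  m <- as.matrix(tbl[scales])
  rownames(m) <- tbl$aa
  if ("charge" %in% scales && !all(m[, "charge"] %in% c(-1, 0, 1))) {
    stop("charge scale must take values in {-1, 0, +1}", call. = FALSE)
  }
  m[AA_ALPHABET, , drop = FALSE]
}

#' Encode mutations as 19-number feature vectors
#'
#' Builds the network input for each mutation: the wild-type amino acid's
#' 8 descriptor values, the 8 descriptor changes (mutant minus wild type),
#' and the 3 structural features (RSA, mean C/N/O B-factor, ternary
#' secondary-structure code). Vectorized over entries.
#'
#' @param wt_aa,mut_aa 1-letter amino acid codes.
#' @param rsa,avg_b,ss_code Structural features (recycled to the common
#'   length); `ss_code` must be in `{-1, 0, 1}`.
#' @param table Property table from [default_property_table()].
#' @return Numeric matrix, one row per mutation, 19 named columns in
#'   [FEATURE_NAMES] order.
#' @export
#' @examples
#' encode_mutation("G", "W", rsa = 0.2, avg_b = 25, ss_code = 1)
encode_mutation <- function(wt_aa, mut_aa, rsa, avg_b, ss_code,
                            table = default_property_table()) {
  assert_canonical(wt_aa)
  assert_canonical(mut_aa)
  n <- max(length(wt_aa), length(mut_aa), length(rsa), length(avg_b),
           length(ss_code))
  wt_aa <- rep_len(wt_aa, n); mut_aa <- rep_len(mut_aa, n)
  rsa <- rep_len(rsa, n); avg_b <- rep_len(avg_b, n)
  ss_code <- rep_len(ss_code, n)
  if (!all(ss_code %in% c(-1, 0, 1))) {
    stop("ss_code must be -1, 0 or +1", call. = FALSE)
  }
  wt_vals <- table[wt_aa, , drop = FALSE]
  deltas <- table[mut_aa, , drop = FALSE] - wt_vals
  out <- cbind(wt_vals, deltas, rsa, avg_b, ss_code)
  dimnames(out) <- list(NULL, FEATURE_NAMES)
  out
}

#' Featurize an annotated mutation dataset
#'
#' @param ds A `mutation_dataset` with `rsa`, `avg_b`, `ss_code` filled on
#'   every entry.
#' @param table Property table.
#' @return Numeric matrix, `nrow(ds)` x 19.
#' @export
featurize_dataset <- function(ds, table = default_property_table()) {
  d <- tibble::as_tibble(ds)
  un <- which(is.na(d$rsa) | is.na(d$avg_b) | is.na(d$ss_code))
  if (length(un) > 0) {
    stop("unannotated entries (missing rsa/avg_b/ss_code): rows ",
         paste(utils::head(un, 5), collapse = ", "),
         if (length(un) > 5) ", ...", call. = FALSE)
  }
  encode_mutation(d$wt_aa, d$mut_aa, d$rsa, d$avg_b, d$ss_code, table)
}

# Slots never z-scored: the ternary secondary-structure code and the two
# charge-valued slots (wild-type charge and charge delta), which stay on
# their categorical -1/0/+1 (and delta -2..+2) coding.
normalizer_excluded_slots <- function() {
  which(FEATURE_NAMES %in% c("ss_code", "wt_charge", "d_charge"))
}

#' Fit a feature normalizer
#'
#' Estimates per-slot mean and standard deviation on a training collection
#' of feature vectors for z-scoring to mean 0 and SD 1. The
#' secondary-structure slot and the charge-valued slots are excluded
#' (passed through untransformed). Slots that are constant in the training
#' collection are flagged degenerate and given SD 1 so that tiny datasets
#' still normalize.
#'
#' @param vectors Numeric matrix of feature vectors (rows), at least 2.
#' @return Object of class `tm_normalizer`: list with `center`, `scale`
#'   (length-19, 0/1 on excluded slots), `excluded` (slot indices),
#'   `degenerate` (slot indices with zero training SD).
#' @export
fit_normalizer <- function(vectors) {
  if (!is.matrix(vectors) || nrow(vectors) < 2) {
    stop("need at least 2 feature vectors to fit a normalizer",
         call. = FALSE)
  }
  stopifnot(ncol(vectors) == length(FEATURE_NAMES))
  excluded <- normalizer_excluded_slots()
  center <- colMeans(vectors)
  scale <- apply(vectors, 2, stats::sd)
  degenerate <- setdiff(which(scale == 0), excluded)
  scale[degenerate] <- 1
  center[excluded] <- 0
  scale[excluded] <- 1
  structure(list(center = center, scale = scale, excluded = excluded,
                 degenerate = degenerate),
            class = "tm_normalizer")
}

#' Apply (or invert) a fitted normalizer
#'
#' @param norm A `tm_normalizer`.
#' @param v Feature vector matrix (rows) or single vector.
#' @param inverse If `TRUE`, undo the transform.
#' @return Matrix of the same shape as `v`.
#' @export
apply_normalizer <- function(norm, v, inverse = FALSE) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1,
                                   dimnames = list(NULL, names(v)))
  if (ncol(v) != length(norm$center)) {
    stop("feature vector length ", ncol(v), " != normalizer length ",
         length(norm$center), call. = FALSE)
  }
  if (inverse) {
    sweep(sweep(v, 2, norm$scale, "*"), 2, norm$center, "+")
  } else {
    sweep(sweep(v, 2, norm$center, "-"), 2, norm$scale, "/")
  }
}
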