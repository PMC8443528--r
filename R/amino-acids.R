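#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids, one-letter codes, alphabetical order.
#' This ordering fixes the row/column order of every 20 x 20 matrix the
#' package produces.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Three-letter residue names keyed by one-letter code
#' @keywords internal
AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' One-letter codes keyed by three-letter residue name
#' @keywords internal
AA_ONE <- stats::setNames(names(AA_THREE), unname(AA_THREE))

#' Maximum accessible surface area per amino acid
#'
#' Theoretical maximum accessible surface areas (Angstrom^2) used as the
#' denominator when converting absolute accessibility (ACC) to relative
#' solvent accessibility (RSA = ACC / maxACC). Values follow the
#' theoretical scale of Tien et al. (2013), the usual modern choice for
#' RSA normalization; an alternative table can be passed to
#' [compute_rsa()].
#'
#' @format Named numeric vector, one positive value per amino acid.
#' @export
MAX_ACC <- c(A = 129, C = 167, D = 193, E = 223, F = 240,
             G = 104, H = 224, I = 197, K = 236, L = 201,
             M = 224, N = 195, P = 159, Q = 225, R = 274,
             S = 155, T = 172, V = 174, W = 285, Y = 263)

#' All ordered amino-acid substitutions
#'
#' The 380 ordered (wild-type, mutant) pairs with wt != mut, enumerated
#' wild type outer / mutant inner in [AA_ALPHABET] order.
#'
#' @return A tibble with columns `wt_aa` and `mut_aa` (380 rows).
#' @export
#' @examples
#' nrow(all_substitutions())  # 380
all_substitutions <- function() {
  grid <- expand.grid(mut_aa = AA_ALPHABET, wt_aa = AA_ALPHABET,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$wt_aa != grid$mut_aa, c("wt_aa", "mut_aa")]
  grid <- grid[order(match(grid$wt_aa, AA_ALPHABET),
                     match(grid$mut_aa, AA_ALPHABET)), ]
  tibble::as_tibble(grid)
}

is_canonical_aa <- function(x) x %in% AA_ALPHABET

assert_canonical <- function(x, what = "amino acid") {
  bad <- unique(x[!is_canonical_aa(x)])
  if (length(bad) > 0) {
    stop("unknown ", what, ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Measurement technique levels
#' @keywords internal
TECHNIQUES <- c("CD", "DSC", "FL", "Abs", "activity", "other")
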