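#' Parse a PDB coordinate file into per-residue records
#'
#' Reads standard PDB-format coordinates (via `bio3d`) and returns one
#' record per (chain, residue number, insertion code), carrying that
#' residue's ATOM-record atoms. HETATM records are excluded. Alternate
#' locations are resolved per atom name by keeping the highest-occupancy
#' conformer, ties broken by altloc identifier order. Author residue
#' numbering is preserved verbatim.
#'
#' @param pdb Path to a PDB file, or the file's text (detected by the
#'   presence of a newline).
#' @return A tibble of class `residue_table`: columns `chain`,
#'   `residue_number`, `insertion_code`, `aa_type` (1-letter; `X` for
#'   non-standard residues) and a list-column `atoms`, each element a
#'   tibble with `atom_name`, `element`, `x`, `y`, `z`, `b_factor`,
#'   `occupancy`.
#' @export
parse_structure <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1], fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(pdb) > 1) pdb else strsplit(pdb, "\n")[[1]], path)
  }
  parsed <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                     error = function(e) NULL)
  if (is.null(parsed) || is.null(parsed$atom) || nrow(parsed$atom) == 0) {
    stop("no ATOM records found", call. = FALSE)
  }
  at <- parsed$atom[parsed$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found", call. = FALSE)

  atoms <- tibble::tibble(
    chain = at$chain,
    residue_number = as.integer(at$resno),
    insertion_code = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    resid = at$resid,
    atom_name = at$elety,
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
    x = at$x, y = at$y, z = at$z,
    b_factor = at$b,
    occupancy = ifelse(is.na(at$o), 1, at$o)
  )
  # altloc resolution: within (residue, atom name) keep highest occupancy,
  # ties by altloc identifier order ("" sorts first)
  atoms <- atoms[order(atoms$chain, atoms$residue_number,
                       atoms$insertion_code, atoms$atom_name,
                       -atoms$occupancy, atoms$alt), ]
  key <- paste(atoms$chain, atoms$residue_number, atoms$insertion_code,
               atoms$atom_name, sep = "\r")
  atoms <- atoms[!duplicated(key), ]

  key <- paste(atoms$chain, sprintf("%6d", atoms$residue_number),
               atoms$insertion_code, sep = "\r")
  chunks <- split(atoms, key)
  res <- dplyr::bind_rows(lapply(chunks, function(a) {
    tibble::tibble(chain = a$chain[1],
                   residue_number = a$residue_number[1],
                   insertion_code = a$insertion_code[1],
                   resid = a$resid[1],
                   atoms = list(a[, c("atom_name", "element", "x", "y",
                                      "z", "b_factor", "occupancy")]))
  }))
  res$aa_type <- unname(ifelse(res$resid %in% names(AA_ONE),
                               AA_ONE[res$resid], "X"))
  res <- res[order(res$chain, res$residue_number, res$insertion_code),
             c("chain", "residue_number", "insertion_code", "aa_type",
               "atoms")]
  structure(res, class = c("residue_table", class(res)))
}

#' Parse a classic DSSP output file
#'
#' Reads the fixed-column dialect of DSSP output (the `.dssp` text format)
#' and extracts, per residue, the secondary-structure class character and
#' the absolute solvent accessibility (ACC, Angstrom^2). Chain-break
#' records (`!`) are skipped. Only the columns this package consumes are
#' parsed.
#'
#' @param dssp Path to a DSSP file, or its text.
#' @return Tibble with columns `chain`, `residue_number`, `aa` (1-letter),
#'   `ss` (DSSP class character, `""` for blank/coil) and `acc`.
#' @export
parse_dssp <- function(dssp) {
  lines <- dssp
  if (length(dssp) == 1 && grepl("\n", dssp, fixed = TRUE)) {
    lines <- strsplit(dssp, "\n")[[1]]
  } else if (length(dssp) == 1) {
    lines <- readLines(dssp, warn = FALSE)
  }
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file: header row missing",
                             call. = FALSE)
  body <- lines[seq(hdr[1] + 1, length(lines))]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  tibble::tibble(
    chain = trimws(substr(body, 12, 12)),
    residue_number = as.integer(trimws(substr(body, 6, 10))),
    aa = aa[keep],
    ss = trimws(substr(body, 17, 17)),
    acc = as.numeric(trimws(substr(body, 35, 38)))
  )
}

#' Relative solvent accessibility from absolute accessibility
#'
#' RSA = ACC / maxACC for the residue type, clamped to `[0, 1]`. Values
#' above 1 (possible because the theoretical maxima can be exceeded in
#' distorted conformations) are clamped with a counted warning, recorded
#' in the `clamped` attribute.
#'
#' @param acc Absolute accessibility, Angstrom^2 (vectorized, `acc >= 0`).
#' @param aa_type 1-letter amino acid code(s), recycled against `acc`.
#' @param max_acc Named per-amino-acid maximum accessibility table
#'   (default [MAX_ACC]).
#' @return Numeric vector of RSA fractions in `[0, 1]`, with attribute
#'   `clamped` = number of values clamped from above.
#' @export
#' @examples
#' compute_rsa(52, "A")           # 52 / 129
#' compute_rsa(104, "G")          # exactly 1
compute_rsa <- function(acc, aa_type, max_acc = MAX_ACC) {
  assert_canonical(aa_type)
  stopifnot(all(acc >= 0, na.rm = TRUE))
  rsa <- acc / unname(max_acc[aa_type])
  n_clamped <- sum(rsa > 1, na.rm = TRUE)
  if (n_clamped > 0) {
    warning(n_clamped, " RSA value(s) > 1 clamped to 1", call. = FALSE)
    rsa <- pmin(rsa, 1)
  }
  structure(rsa, clamped = n_clamped)
}

#' Mean B-factor over a residue's C, N and O atoms
#'
#' Arithmetic mean of the crystallographic B-factor over exactly the atoms
#' whose element is carbon, nitrogen, or oxygen; sulfur, hydrogen, and all
#' other elements are excluded. Backbone atoms are included by default
#' (`sidechain_only = FALSE`); the sidechain-only variant restricts to
#' atoms beyond the backbone N, CA, C, O.
#'
#' @param residue A one-row `residue_table` slice, or an atoms tibble with
#'   columns `atom_name`, `element`, `b_factor`.
#' @param sidechain_only If `TRUE`, exclude backbone N/CA/C/O atoms.
#' @return Mean B-factor, Angstrom^2.
#' @export
avg_bfactor <- function(residue, sidechain_only = FALSE) {
  atoms <- residue
  if ("atoms" %in% names(residue)) atoms <- residue$atoms[[1]]
  keep <- toupper(atoms$element) %in% c("C", "N", "O")
  if (sidechain_only) {
    keep <- keep & !atoms$atom_name %in% c("N", "CA", "C", "O")
  }
  if (!any(keep)) stop("residue has no qualifying C/N/O atoms",
                       call. = FALSE)
  mean(atoms$b_factor[keep])
}

#' Simplify a DSSP class to the ternary secondary-structure code
#'
#' Maps the 8-class DSSP assignment to the ternary code used throughout
#' this package: `B`, `E`, `S` to -1 (sheet-like), `H`, `G`, `I` to +1
#' (helical), and everything else (`T`, blank, unknown) to 0. Total
#' function; vectorized.
#'
#' @param dssp_class Character vector of single DSSP class characters
#'   (`""` or `NA` for blank).
#' @return Integer vector in `{-1, 0, 1}`.
#' @export
#' @examples
#' simplify_ss(c("H", "S", "T", ""))  # 1 -1 0 0
simplify_ss <- function(dssp_class) {
  dssp_class[is.na(dssp_class)] <- ""
  out <- integer(length(dssp_class))
  out[dssp_class %in% c("B", "E", "S")] <- -1L
  out[dssp_class %in% c("H", "G", "I")] <- 1L
  out
}

#' Annotate a mutation dataset with structure-derived features
#'
#' Fills `rsa`, `avg_b` and `ss_code` on each entry from the residue
#' matched by (chain, residue number) in the corresponding structure.
#' Entries whose residue cannot be found are flagged `residue-not-found`
#' and retained unannotated; entries whose wild-type amino acid differs
#' from the structure's residue type are annotated but flagged
#' `sequence-mismatch`. dTm, Tm and the entry count are never modified.
#'
#' @param ds A `mutation_dataset`.
#' @param structures Named list keyed by `protein_id`; each element a list
#'   with `residues` (a [parse_structure()] result) and `dssp` (a
#'   [parse_dssp()] result).
#' @param max_acc RSA denominator table (default [MAX_ACC]).
#' @param sidechain_only Passed to [avg_bfactor()].
#' @return The annotated `mutation_dataset`; annotation flags are appended
#'   to its validation report (annotated entries are kept, not
#'   quarantined).
#' @export
annotate_dataset <- function(ds, structures, max_acc = MAX_ACC,
                             sidechain_only = FALSE) {
  d <- tibble::as_tibble(ds)
  missing_ids <- setdiff(unique(d$protein_id), names(structures))
  if (length(missing_ids) > 0) {
    stop("no structure supplied for: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  flags <- validation_report(ds)
  for (i in seq_len(nrow(d))) {
    s <- structures[[d$protein_id[i]]]
    res <- s$residues
    hit <- which(res$chain == d$chain[i] &
                 res$residue_number == d$residue_number[i])
    if (length(hit) == 0) {
      flags <- dplyr::bind_rows(flags,
        tibble::tibble(row = i, reason = "residue-not-found"))
      next
    }
    hit <- hit[1]
    if (res$aa_type[hit] != d$wt_aa[i]) {
      flags <- dplyr::bind_rows(flags,
        tibble::tibble(row = i, reason = "sequence-mismatch"))
    }
    d$avg_b[i] <- avg_bfactor(res[hit, ], sidechain_only = sidechain_only)
    dssp_hit <- which(s$dssp$chain == d$chain[i] &
                      s$dssp$residue_number == d$residue_number[i])
    if (length(dssp_hit) > 0) {
      d$rsa[i] <- suppressWarnings(
        as.numeric(compute_rsa(s$dssp$acc[dssp_hit[1]], res$aa_type[hit],
                               max_acc = max_acc)))
      d$ss_code[i] <- simplify_ss(s$dssp$ss[dssp_hit[1]])
    }
  }
  structure(d, provenance = attr(ds, "provenance"), validation = flags,
            class = class(ds))
}

#' Write a per-residue feature table
#'
#' @param structures Named list as in [annotate_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(structures, path) {
  rows <- lapply(names(structures), function(id) {
    s <- structures[[id]]
    res <- s$residues
    tibble::tibble(
      protein_id = id, chain = res$chain,
      residue_number = res$residue_number, aa = res$aa_type,
      rsa = vapply(seq_len(nrow(res)), function(i) {
        hit <- which(s$dssp$chain == res$chain[i] &
                     s$dssp$residue_number == res$residue_number[i])
        if (length(hit) == 0 || res$aa_type[i] == "X") return(NA_real_)
        suppressWarnings(as.numeric(
          compute_rsa(s$dssp$acc[hit[1]], res$aa_type[i])))
      }, numeric(1)),
      avg_b = vapply(seq_len(nrow(res)),
                     function(i) avg_bfactor(res[i, ]), numeric(1)),
      ss_code = vapply(seq_len(nrow(res)), function(i) {
        hit <- which(s$dssp$chain == res$chain[i] &
                     s$dssp$residue_number == res$residue_number[i])
        if (length(hit) == 0) return(0L)
        simplify_ss(s$dssp$ss[hit[1]])
      }, integer(1)))
  })
  readr::write_tsv(dplyr::bind_rows(rows), path)
  invisible(path)
}
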