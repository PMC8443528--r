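# Fixtures are built in code: a small hand-written mutation table, a toy
# structure bundle, and a writer for delimited-text fixtures.

fixture_entries <- function() {
  tibble::tibble(
    protein_id = c("1ABC", "1ABC", "1ABC", "1ABC", "1ABC",
                   "2XYZ", "2XYZ", "2XYZ", "2XYZ", "2XYZ"),
    chain = "A",
    residue_number = 1:10,
    wt_aa  = c("V", "V", "V", "V", "I", "L", "G", "E", "D", "T"),
    mut_aa = c("A", "A", "A", "A", "A", "A", "F", "A", "K", "V"),
    tm_wt = c(rep(65.1, 5), rep(52.3, 5)),
    d_tm = c(-1, -3, -5, -7, -9.5, -2.2, 0.4, 3.1, 6.2, -0.8),
    ph = c(7, 7, 7, 7, 7, 3.0, 5.5, 8.5, 5.0, 9.2),
    technique = c(rep("CD", 6), "DSC", "FL", "DSC", "CD"),
    rsa = seq(0.05, 0.95, length.out = 10),
    avg_b = seq(12, 48, length.out = 10),
    ss_code = rep(c(-1, 0, 1, 0, 1), 2)
  )
}

fixture_dataset <- function() mutation_dataset(fixture_entries())

write_fixture_tsv <- function(entries, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(entries, path)
  path
}

toy_bundle <- function(aa = c("V", "A", "G", "L", "S"),
                       ss = c("H", "E", "S", "T", ""),
                       acc = c(0, 50, 104, 30, 80),
                       b = c(10, 20, 30, 40, 50)) {
  structure_bundle(simulate_structure(length(aa), aa = aa, ss = ss,
                                      acc = acc, b_factors = b))
}

# small synthetic dataset for pipeline tests
small_synth <- function(n = 400, seed = 7, noise_sd = 0,
                        outlier_fraction = 0, n_proteins = 20) {
  cfg <- synthetic_config(n_entries = n, n_proteins = n_proteins,
                          dominance_weights = rep(1, n_proteins),
                          noise_sd = noise_sd,
                          outlier_fraction = outlier_fraction)
  simulate_dataset(cfg, seed = seed)
}

fast_net <- function(...) {
  net_config(max_epochs = 300, early_stop_patience = 50, ...)
}
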