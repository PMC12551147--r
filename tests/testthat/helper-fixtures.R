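# Shared fixtures: loaded once per test run.
test_scales <- load_scales()
test_codon <- load_codon_table()

# A reduced design space (6-letter alphabet incl. the SKIK residues) used by
# loop tests so they stay fast; features use zero energies because the ground
# truths planted in tests never involve the energy column.
small_space <- function() {
  enumerate_tetrapeptides(c("A", "D", "I", "K", "N", "S"), 4L)
}

small_features <- function(space = small_space()) {
  encode_table(space, test_scales, energies = numeric(length(space)))
}

# Deterministic pseudo-random peptide sample.
random_peptides <- function(n, seed = 1) {
  set.seed(seed)
  apply(matrix(sample(aa_alphabet(), 4 * n, replace = TRUE), n), 1, paste,
        collapse = "")
}

random_rna <- function(n_min, n_max, seed) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
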