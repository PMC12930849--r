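# Shared fixture builders: everything is generated in code at test time.

# Peptide with several ionizable residues used across the suite.
test_sequence <- "ADGKEHYRC"

make_test_ensemble <- function(n_frames = 10, sequence = test_sequence,
                               amplitude = 1.5, stride = 1,
                               timestep_ps = 100, seed = 11) {
  pep <- generate_peptide(sequence, seed = seed)
  path <- tempfile(fileext = ".pdb")
  generate_trajectory(pep, path, n_frames = n_frames,
                      amplitude = amplitude, seed = seed + 1)
  load_ensemble(path, stride = stride, timestep_ps = timestep_ps)
}

# A single-residue snapshot whose heavy-atom centroid coincides with its
# backbone centroid (both at the origin), so the mock engine's d is 0.
make_centered_asp <- function() {
  new_snapshot(tibble::tibble(
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    resname = "ASP", chain = "A", resid = 1L,
    x = c(1, -1, 1, -1, 2, -2, 2, -2),
    y = c(1, -1, -1, 1, 2, -2, -2, 2),
    z = c(0, 0, 0, 0, 0, 0, 0, 0)
  ))
}

fixture_engine_entries <- function() {
  tibble::tibble(
    resname = c("ASP", "GLU", "HIS", "N+"),
    resid = c(52L, 35L, 15L, 1L),
    chain = "A",
    pka = c(3.70, 6.20, 5.95, 7.83),
    model_pka = c(3.80, 4.50, 6.50, 8.00),
    buried_pct = c(85, 100, 30, NA)
  )
}

# Adjusted Rand Index between two labelings; mclust's implementation is
# the independent reference used for partition comparison.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
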