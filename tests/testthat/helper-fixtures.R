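# Shared fixtures, built in code at test time.

# single-residue map/config for closed-form OU checks
one_residue_config <- function(n_frames = 1000, sigma = 1, rho = 0.8,
                               seed = 7) {
  rm1 <- region_map("TM1", 0, 1)
  synthetic_config(n_trajectories = 1, n_frames = n_frames,
                   region_map = rm1, sigma_by_region = c(TM1 = sigma),
                   rho = rho, seed = seed)
}

# small three-region map: a helix flanked by two loops
toy_map <- function() {
  region_map(c("TM1", "ICL1", "ECL1"), c(0, 10, 15), c(10, 15, 20))
}

toy_config <- function(n_trajectories = 6, n_frames = 12, seed = 3,
                       sigma = c(TM1 = 0.5, ICL1 = 1.5, ECL1 = 1.5),
                       rho = 0.8) {
  synthetic_config(n_trajectories = n_trajectories, n_frames = n_frames,
                   region_map = toy_map(), sigma_by_region = sigma,
                   rho = rho, seed = seed)
}

# deterministic feature matrix: frame t, feature j = t*100 + j
ramp_features <- function(n_frames, n_features) {
  outer(seq_len(n_frames), seq_len(n_features),
        function(t, j) t * 100 + j)
}

# two-model, three-atom PDB text fixture
toy_pdb_lines <- function() {
  c("MODEL        1",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.500   3.500  1.00  0.00",
    "ATOM      3  C   ALA A   2       3.000   3.000   4.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       1.100   2.100   3.100  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.100   2.600   3.600  1.00  0.00",
    "ATOM      3  C   ALA A   2       3.100   3.100   4.100  1.00  0.00           C",
    "ENDMDL",
    "END")
}
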