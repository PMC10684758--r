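#!/usr/bin/env Rscript

# Generate the synthetic GPCR trajectory datasets used by the analysis:
# a seven-helix reference bundle whose residues fluctuate as
# region-dependent OU processes (stiff TM helices, flexible loops).
# Writes a small sample of trajectories in the columnar format plus the
# generator config, and reports the per-region flexibility so the
# TM-vs-loop contrast is visible before any model is trained.
#
# Sizes here are the analysis' working scale (hundreds of trajectories,
# not the full 2000-per-condition production scale, which the same code
# reaches by raising n_trajectories).

suppressPackageStartupMessages(library(gpcrforecast))

out_dir <- "results/dataset"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

map <- default_region_map()
sigma <- ifelse(grepl("^TM", map$name), 0.5, 1.5)
names(sigma) <- map$name

cfg <- synthetic_config(n_trajectories = 200, n_frames = 28,
                        frame_interval = 500, region_map = map,
                        sigma_by_region = sigma, rho = 0.8, seed = 20)
write_synthetic_config(cfg, file.path(out_dir, "generator_config.yml"))

ds <- generate_dataset(cfg)
cat(sprintf("generated %d trajectories x %d frames x %d residues\n",
            length(ds$trajectories), cfg$n_frames,
            length(ds$reference$residue_ids)))

# sample trajectories to disk in the columnar text format
for (i in 1:3) {
  write_residue_table(ds$trajectories[[i]],
                      file.path(out_dir, sprintf("trajectory_%02d.csv", i)))
}
write_trajectory_pdb(ds$trajectories[[1]],
                     file.path(out_dir, "trajectory_01.pdb"))

# flexibility by region: the generator's TM < loop contrast
md <- flexibility_md_rmsd(ds$trajectories, map, c("TM", "ICL", "ECL"))
closed_form <- sigma[c("TM1", "ICL1", "ECL1")] * sqrt(6 * (1 - cfg$rho))
flex <- data.frame(group = names(md), md_rmsd = unname(md),
                   closed_form = unname(closed_form))
write.table(flex, file.path(out_dir, "flexibility_by_region.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("per-region step displacement (MD-RMSD, Angstrom):\n")
print(flex, row.names = FALSE)
cat("TM helices are markedly stiffer than the loops, as configured.\n")
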