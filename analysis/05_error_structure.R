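#!/usr/bin/env Rscript

# Map per-residue prediction error onto the reference structure: run a
# persistence evaluation on held-out trajectories, compute per-residue
# RMSD and export it in the B-factor column of a pseudo-atom PDB for
# colour-coded display in a structure viewer.

suppressPackageStartupMessages(library(gpcrforecast))

dir.create("results", showWarnings = FALSE)

map <- default_region_map()
sigma <- ifelse(grepl("^TM", map$name), 0.5, 1.5)
names(sigma) <- map$name
cfg <- synthetic_config(n_trajectories = 60, n_frames = 28,
                        region_map = map, sigma_by_region = sigma,
                        rho = 0.8, seed = 20)
ds <- generate_dataset(cfg)
ref <- ds$reference

# persistence predictions on the last 20 trajectories
feats <- lapply(ds$trajectories[41:60], trajectory_to_features)
sp <- assemble_split(feats, train_idx = 1:10, test_idx = 11:20)
pred <- persistence_forecast(sp$test)
ps <- prediction_set(pred, sp$test$y, ref$residue_ids)

errs <- per_residue_rmsd(ps)
export_error_structure(ps, ref, "results/per_residue_error.pdb")

lab <- assign_region(map, as.integer(names(errs)))
by_region <- vapply(split(errs, lab), mean, numeric(1))
cat("mean per-residue RMSD by region (Angstrom):\n")
print(round(by_region[order(by_region)], 3))
cat(sprintf("\nwrote %d residues to results/per_residue_error.pdb\n",
            length(errs)))
cat("(open in a viewer and colour by B-factor: the TM bundle is cool,\n")
cat("the loops hot, reproducing the stiff-core/flexible-loop picture)\n")
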