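test_that("reference structure covers exactly the mapped non-gap residues", {
  cfg <- synthetic_config(n_trajectories = 1, region_map = default_region_map())
  ref <- build_reference_structure(cfg)
  # sum of Table-style interval widths: 344 numbering minus the 38-residue gap
  widths <- with(default_region_map(), sum(end - start))
  expect_equal(length(ref$residue_ids), widths)
  expect_equal(length(ref$residue_ids), 306)
  # the gap ids are absent, not zero-filled
  expect_length(intersect(ref$residue_ids, 230:267), 0)
  expect_false(is.unsorted(ref$residue_ids, strictly = TRUE))
  expect_equal(ref$region_labels, assign_region(default_region_map(),
                                                ref$residue_ids))
})

test_that("a TM-only map yields only TM labels and exact helix rise", {
  m <- region_map(c("TM1", "TM2"), c(0, 20), c(10, 30))
  cfg <- synthetic_config(n_trajectories = 1, region_map = m,
                          sigma_by_region = c(TM1 = 1, TM2 = 1),
                          helix_rise = 1.5)
  ref <- build_reference_structure(cfg)
  expect_true(all(startsWith(ref$region_labels, "TM")))
  for (tm in c("TM1", "TM2")) {
    z <- ref$positions[ref$region_labels == tm, 3]
    expect_true(all(abs(abs(diff(z)) - 1.5) < 1e-6))
  }
})

test_that("reference construction is deterministic", {
  cfg <- toy_config()
  r1 <- build_reference_structure(cfg)
  r2 <- build_reference_structure(cfg)
  expect_identical(r1, r2)
})

test_that("zero sigma reproduces the reference in every frame", {
  cfg <- toy_config(sigma = c(TM1 = 0, ICL1 = 0, ECL1 = 0))
  ref <- build_reference_structure(cfg)
  tr <- simulate_trajectory(ref, cfg, seed = 99)
  for (fr in tr$frames) expect_equal(fr, ref$positions)
})

test_that("stationary spread matches sigma for iid frames (rho = 0)", {
  cfg <- one_residue_config(n_frames = 10000, sigma = 1, rho = 0)
  ref <- build_reference_structure(cfg)
  f <- trajectory_to_features(simulate_trajectory(ref, cfg, seed = 11))
  expect_equal(unname(apply(f, 2, sd)), rep(1, 3), tolerance = 0.05)
})

test_that("step displacement matches the closed form sigma*sqrt(6(1-rho))", {
  cfg <- one_residue_config(n_frames = 10000, sigma = 1, rho = 0.8)
  ref <- build_reference_structure(cfg)
  tr <- simulate_trajectory(ref, cfg, seed = 11)
  md <- flexibility_md_rmsd(list(tr), cfg$region_map, "TM1",
                            n_steps_in = 1)
  expect_equal(unname(md), sqrt(6 * (1 - 0.8)), tolerance = 0.02)
})

test_that("long-run marginal variance converges to sigma^2 for rho > 0", {
  cfg <- one_residue_config(n_frames = 20000, sigma = 2, rho = 0.6)
  ref <- build_reference_structure(cfg)
  f <- trajectory_to_features(simulate_trajectory(ref, cfg, seed = 4))
  expect_equal(unname(apply(f, 2, var)), rep(4, 3), tolerance = 0.1)
})

test_that("datasets are seeded, sized and bitwise reproducible", {
  cfg <- toy_config(n_trajectories = 5, n_frames = 8)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_length(d1$trajectories, 5)
  expect_length(d1$trajectories[[1]]$frames, 8)
  expect_identical(d1$trajectories, d2$trajectories)
  # different master seed changes the draws
  cfg2 <- toy_config(n_trajectories = 5, n_frames = 8, seed = 4)
  d3 <- generate_dataset(cfg2)
  expect_false(identical(d1$trajectories[[1]]$frames[[1]],
                         d3$trajectories[[1]]$frames[[1]]))
  # trajectories within a dataset are distinct draws
  expect_false(identical(d1$trajectories[[1]]$frames[[1]],
                         d1$trajectories[[2]]$frames[[1]]))
})

test_that("region flexibility ordering follows the sigma ordering", {
  cfg <- toy_config(n_trajectories = 10, n_frames = 28,
                    sigma = c(TM1 = 0.5, ICL1 = 1.5, ECL1 = 1.5))
  ds <- generate_dataset(cfg)
  for (tr in ds$trajectories) {
    rmsf <- trajectory_rmsf(tr)
    lab <- assign_region(cfg$region_map, as.integer(names(rmsf)))
    expect_lt(mean(rmsf[lab == "TM1"]), mean(rmsf[lab == "ICL1"]))
    expect_lt(mean(rmsf[lab == "TM1"]), mean(rmsf[lab == "ECL1"]))
  }
})

test_that("missing sigma for a present region is rejected", {
  cfg <- toy_config()
  ref <- build_reference_structure(cfg)
  cfg$sigma_by_region <- cfg$sigma_by_region[c("TM1", "ICL1")]
  expect_error(simulate_trajectory(ref, cfg, 1), "no sigma.*ECL1")
  expect_error(synthetic_config(region_map = toy_map(),
                                sigma_by_region = c(TM1 = 1)),
               "no sigma")
})

test_that("generator config round-trips through YAML", {
  cfg <- toy_config(n_trajectories = 7, n_frames = 9, seed = 42)
  path <- withr::local_tempfile(fileext = ".yml")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back$n_trajectories, cfg$n_trajectories)
  expect_equal(back$rho, cfg$rho)
  expect_equal(back$sigma_by_region[names(cfg$sigma_by_region)],
               cfg$sigma_by_region)
  expect_identical(generate_dataset(back)$trajectories[[1]]$frames,
                   generate_dataset(cfg)$trajectories[[1]]$frames)
})
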