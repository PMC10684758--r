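test_that("rmsd matches hand-computed pooled deviations", {
  ids <- c(1L, 2L)
  true <- matrix(0, 1, 6)
  # residue 1 off by (1,0,0), residue 2 off by (0,2,0)
  pred <- matrix(c(1, 0, 0, 0, 2, 0), 1, 6)
  ps <- prediction_set(pred, true, ids)
  expect_equal(rmsd(ps), sqrt((1 + 4) / 2))
  expect_equal(rmsd(ps, 1L), 1)
  expect_equal(rmsd(ps, 2L), 2)
  # identity and uniform-shift cases
  expect_equal(rmsd(prediction_set(true, true, ids)), 0)
  shift <- matrix(rep(c(1, 0, 0), 2), 1, 6)
  expect_equal(rmsd(prediction_set(true + shift, true, ids)), 1)
  expect_error(rmsd(ps, 99L), "empty residue subset")
})

test_that("rmsd is symmetric and permutation-invariant", {
  set.seed(3)
  ids <- 1:4
  pred <- matrix(rnorm(60), 5, 12)
  true <- matrix(rnorm(60), 5, 12)
  a <- prediction_set(pred, true, ids)
  b <- prediction_set(true, pred, ids)
  expect_equal(rmsd(a), rmsd(b))
  perm <- sample(5)
  expect_equal(rmsd(prediction_set(pred[perm, ], true[perm, ], ids)),
               rmsd(a))
})

test_that("squared region RMSDs aggregate to the squared overall RMSD", {
  set.seed(9)
  map <- toy_map()
  ids <- region_subset(map, "ALL-mapped")
  n <- length(ids)
  pred <- matrix(rnorm(3 * n * 7), 7)
  true <- matrix(rnorm(3 * n * 7), 7)
  ps <- prediction_set(pred, true, ids)
  groups <- c("TM1", "ICL1", "ECL1")
  r <- region_rmsd(ps, map, groups)
  w <- vapply(groups, function(g) length(region_subset(map, g)),
              numeric(1))
  expect_equal(sum(w * r^2) / sum(w), rmsd(ps)^2, tolerance = 1e-9)
})

test_that("per-residue RMSD localises errors and averages to the overall MSE", {
  set.seed(4)
  ids <- c(30L, 31L, 32L)
  true <- matrix(rnorm(27), 3, 9)
  pred <- true
  pred[, 1:3] <- pred[, 1:3] + 0.5  # displace residue 30 only
  ps <- prediction_set(pred, true, ids)
  pr <- per_residue_rmsd(ps)
  expect_equal(unname(pr[c("31", "32")]), c(0, 0))
  expect_gt(pr[["30"]], 0)
  expect_equal(mean(pr^2), rmsd(ps)^2)
  # identity predictions are all-zero
  expect_equal(unname(per_residue_rmsd(prediction_set(true, true, ids))),
               rep(0, 3))
})

test_that("region error tables localise displacements and add a Mean row", {
  map <- toy_map()
  ids <- region_subset(map, "ALL-mapped")
  true <- matrix(0, 2, 3 * length(ids))
  pred <- true + 1 / sqrt(3)  # uniform 1 A displacement
  ps <- prediction_set(pred, true, ids)
  tab <- region_error_table(ps, map, c("TM1", "ICL1", "ECL1"))
  expect_equal(tab$region, c("TM1", "ICL1", "ECL1", "Mean"))
  expect_equal(tab$rmsd, rep(1, 4))
  # displacement restricted to TM1 residues
  pred2 <- true
  cols <- gpcrforecast:::feature_columns(ids, region_subset(map, "TM1"))
  pred2[, cols] <- 1
  r <- region_rmsd(prediction_set(pred2, true, ids), map,
                   c("TM1", "ICL1", "ECL1"))
  expect_gt(r[["TM1"]], 0)
  expect_equal(unname(r[c("ICL1", "ECL1")]), c(0, 0))
})

test_that("flexibility baseline is zero for static and ordered by sigma", {
  cfg <- toy_config(n_trajectories = 4, n_frames = 28,
                    sigma = c(TM1 = 0, ICL1 = 0, ECL1 = 0))
  ds <- generate_dataset(cfg)
  md <- flexibility_md_rmsd(ds$trajectories, cfg$region_map,
                            c("TM1", "ICL1", "ECL1"))
  expect_equal(unname(md), c(0, 0, 0))

  cfg2 <- toy_config(n_trajectories = 25, n_frames = 28,
                     sigma = c(TM1 = 0.5, ICL1 = 1.5, ECL1 = 1.0))
  ds2 <- generate_dataset(cfg2)
  md2 <- flexibility_md_rmsd(ds2$trajectories, cfg2$region_map,
                             c("TM1", "ICL1", "ECL1"))
  expect_lt(md2[["TM1"]], md2[["ECL1"]])
  expect_lt(md2[["ECL1"]], md2[["ICL1"]])
  # closed form per region at rho = 0.8
  expect_equal(unname(md2), c(0.5, 1.5, 1.0) * sqrt(6 * (1 - 0.8)),
               tolerance = 0.05)
})

test_that("single-frame trajectories contribute nothing or reject", {
  cfg <- toy_config(n_trajectories = 1, n_frames = 12)
  tr <- simulate_trajectory(build_reference_structure(cfg), cfg, 3)
  one <- trajectory(tr$residue_ids, tr$frames[1])
  expect_error(flexibility_md_rmsd(list(one), cfg$region_map, "TM1"),
               "no trajectory")
  both <- flexibility_md_rmsd(list(one, tr), cfg$region_map, "TM1")
  alone <- flexibility_md_rmsd(list(tr), cfg$region_map, "TM1")
  expect_equal(both, alone)
})
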