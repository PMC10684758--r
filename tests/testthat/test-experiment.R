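test_that("protocol validates its arithmetic and expands group presets", {
  p <- protocol(n_sampled = 2000, n_folds = 5, groups = "E1")
  expect_equal(p$n_sampled / p$n_folds, 400)
  expect_equal(p$groups, c("TM", "ICL", "ECL"))
  expect_equal(protocol(n_sampled = 10, groups = "E2")$groups,
               paste0("TM", 1:7))
  expect_equal(protocol(n_sampled = 10, groups = "E3")$groups,
               c("ICL1", "ICL2", "ECL1", "ECL2", "ECL3"))
  expect_error(protocol(n_sampled = 2001, n_folds = 5), "n_sampled")
})

test_that("fold assignment partitions the sample and is seed-stable", {
  cfg <- toy_config(n_trajectories = 12, n_frames = 10)
  ds <- generate_dataset(cfg)
  p <- protocol(n_sampled = 10, n_folds = 5, n_repetitions = 1,
                groups = c("TM1", "ICL1", "ECL1"),
                models = "persistence", seed = 7)
  r1 <- run_repetition(p, ds, repetition = 1)
  r2 <- run_repetition(p, ds, repetition = 1)
  expect_identical(r1$sampled, r2$sampled)
  expect_identical(r1$rmsd, r2$rmsd)
  # folds are equal-size and exhaust the sample; test fold of 2 = 10/5
  expect_equal(as.integer(table(r1$fold)), rep(2L, 5))
  expect_length(r1$test_idx, 2)
  expect_length(unique(r1$sampled), 10)
  # a different repetition redraws the sample
  r3 <- run_repetition(p, ds, repetition = 2)
  expect_false(identical(r1$sampled, r3$sampled))
  expect_error(run_repetition(protocol(n_sampled = 15, n_folds = 5,
                                       models = "persistence"), ds),
               "pool")
})

test_that("repetition aggregation uses the n-1 standard deviation", {
  expect_equal(aggregate_repetitions(c(1, 1, 1)),
               list(mean = 1, std = 0))
  a <- aggregate_repetitions(c(0, 2))
  expect_equal(a$mean, 1)
  expect_equal(a$std, sqrt(2))
  expect_equal(aggregate_repetitions(c(2, 0))$std, sqrt(2))
})

test_that("t-tests flag separation, stay symmetric, and degrade gracefully", {
  set.seed(10)
  a <- rnorm(10); b <- rnorm(10, mean = 5)
  tt <- ttest_matrix(a, b)
  expect_true(tt$flag01)
  expect_true(tt$flag05)
  expect_equal(ttest_matrix(b, a)$p, tt$p)
  # flag01 implies flag05 by construction
  expect_true(!tt$flag01 || tt$flag05)
  # identical constant samples: degenerate rule p = 1
  same <- rep(2, 5)
  expect_equal(ttest_matrix(same, same)$p, 1)
  expect_equal(ttest_matrix(same, rep(3, 5))$p, 0)
  # pooled-variance option agrees with stats::t.test
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(ttest_matrix(x, y, var_equal = TRUE)$p,
               t.test(x, y, var.equal = TRUE)$p.value)
})

test_that("type-I rate of the 0.05 flag is calibrated under the null", {
  set.seed(123)
  n_pairs <- 2000
  hits <- 0L
  for (i in seq_len(n_pairs)) {
    if (ttest_matrix(rnorm(10), rnorm(10))$flag05) hits <- hits + 1L
  }
  expect_equal(hits / n_pairs, 0.05, tolerance = 0.4)
  expect_gt(hits / n_pairs, 0.03)
  expect_lt(hits / n_pairs, 0.07)
})

test_that("persistence E1 recovers the region flexibility ordering", {
  cfg <- toy_config(n_trajectories = 40, n_frames = 28,
                    sigma = c(TM1 = 0.5, ICL1 = 1.5, ECL1 = 1.5))
  ds <- generate_dataset(cfg)
  p <- protocol(n_sampled = 40, n_folds = 5, n_repetitions = 2,
                groups = c("TM", "ICL", "ECL"), models = "persistence",
                seed = 2)
  rep_out <- run_experiment(p, ds)
  expect_lt(rep_out$mean["persistence", "TM"],
            rep_out$mean["persistence", "ICL"])
  expect_lt(rep_out$mean["persistence", "TM"],
            rep_out$mean["persistence", "ECL"])
  # MD-RMSD column equals the persistence row (same predictor)
  expect_equal(unname(rep_out$md_rmsd),
               unname(rep_out$mean["persistence", ]), tolerance = 1e-9)
})

test_that("experiments are deterministic end to end for seeded models", {
  cfg <- toy_config(n_trajectories = 15, n_frames = 12)
  ds <- generate_dataset(cfg)
  p <- protocol(n_sampled = 10, n_folds = 5, n_repetitions = 2,
                groups = c("TM1", "ICL1"), models = c("persistence", "rf"),
                seed = 5)
  r1 <- run_experiment(p, ds)
  r2 <- run_experiment(p, ds)
  expect_identical(r1$per_rep, r2$per_rep)
  expect_identical(r1$mean, r2$mean)
  expect_equal(dim(r1$per_rep), c(2, 2, 2))
})

test_that("TM-only training restricts the feature space, not the folds", {
  cfg <- toy_config(n_trajectories = 10, n_frames = 10)
  ds <- generate_dataset(cfg)
  base <- protocol(n_sampled = 10, n_folds = 5, n_repetitions = 1,
                   groups = "TM1", models = "persistence", seed = 9)
  tm <- base; tm$tm_only <- TRUE
  r_full <- run_repetition(base, ds)
  r_tm <- run_repetition(tm, ds)
  expect_identical(r_full$sampled, r_tm$sampled)
  expect_identical(r_full$fold, r_tm$fold)
  # TM RMSD is unchanged by dropping loop features (persistence model)
  expect_equal(r_full$rmsd["persistence", "TM1"],
               r_tm$rmsd["persistence", "TM1"])
  # loop groups are no longer evaluable
  bad <- base; bad$tm_only <- TRUE; bad$groups <- "ICL1"
  expect_error(run_repetition(bad, ds), "no residues present")
})

test_that("no leakage: normalisation ignores the hold-out fold", {
  # trajectories with disjoint ranges: train in [0,1], test shifted far away
  feats <- c(lapply(1:4, function(i) matrix(runif(30), 10, 3)),
             lapply(1:1, function(i) matrix(runif(30) + 100, 10, 3)))
  sp <- assemble_split(feats, 1:4, 5, n_steps_in = 5)
  mm <- fit_minmax(do.call(rbind, feats[1:4]))
  z <- apply_minmax(mm, feats[[5]])
  # held-out rows fall far outside [0,1] -> params came from train only
  expect_gt(min(z), 50)
})
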