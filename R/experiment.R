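#' Experiment protocol
#'
#' Describes one resampled cross-validation experiment: per repetition,
#' `n_sampled` trajectories are drawn without replacement from the pool,
#' split into `n_folds` equal folds, the models are trained on the
#' windows of `n_folds - 1` folds and scored by per-region RMSD on the
#' hold-out fold; `n_repetitions` repetitions yield the mean, standard
#' deviation and pairwise t-tests of the report. Group presets follow
#' the three analyses: E1 compares the TM/ICL/ECL aggregates, E2 the
#' seven TM helices, E3 the individual loops.
#'
#' @param n_sampled trajectories drawn per repetition (default 2000;
#'   must be divisible by `n_folds` and no larger than the pool).
#' @param n_folds folds (default 5; one is the hold-out).
#' @param n_repetitions repetitions (default 10).
#' @param groups character vector of region groups, or one of the
#'   presets `"E1"`, `"E2"`, `"E3"`.
#' @param models character vector among `"persistence"`, `"rf"`,
#'   `"ulstm"`, `"blstm"`, `"cnnlstm"`.
#' @param tm_only if `TRUE`, only TM residues are used for training and
#'   prediction (the feature space shrinks to `3 * |TM residues|`).
#' @param n_steps_in window length (default 5).
#' @param fit a [fit_config] for the neural models.
#' @param seed master seed; per-repetition seeds derive from it.
#' @return An object of class `protocol`.
#' @export
protocol <- function(n_sampled = 2000L, n_folds = 5L,
                     n_repetitions = 10L, groups = "E1",
                     models = c("persistence", "ulstm"),
                     tm_only = FALSE, n_steps_in = 5L,
                     fit = fit_config(), seed = 1L) {
  if (length(groups) == 1L && groups %in% c("E1", "E2", "E3")) {
    groups <- switch(groups,
      E1 = c("TM", "ICL", "ECL"),
      E2 = paste0("TM", 1:7),
      E3 = c("ICL1", "ICL2", "ECL1", "ECL2", "ECL3"))
  }
  stopifnot(n_sampled %% n_folds == 0L, n_repetitions >= 1L,
            all(models %in% c("persistence", "rf", "ulstm", "blstm",
                              "cnnlstm")))
  structure(list(n_sampled = as.integer(n_sampled),
                 n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 groups = groups, models = models, tm_only = tm_only,
                 n_steps_in = as.integer(n_steps_in), fit = fit,
                 seed = as.integer(seed)),
            class = "protocol")
}

build_model_spec <- function(name, input_dim, n_steps_in) {
  switch(name,
    persistence = persistence_spec(),
    rf = build_rf(input_dim %/% 3L),
    ulstm = build_ulstm(input_dim, n_steps_in),
    blstm = build_blstm(input_dim, n_steps_in),
    cnnlstm = build_cnn_lstm(input_dim, n_steps_in),
    stop("unknown model '", name, "'"))
}

#' Run one repetition of the protocol
#'
#' Samples trajectories, assigns folds, fits the min-max normalisation
#' on the training folds only, trains every model on the training
#' windows and returns per-(model, group) RMSD on the hold-out fold in
#' Angstrom, together with the hold-out MD-RMSD flexibility baseline.
#'
#' @param proto a [protocol].
#' @param dataset a `trajectory_dataset` (the pool).
#' @param map a [region_map] (defaults to the dataset's generator map).
#' @param repetition repetition index (seeds the resampling).
#' @return List with `rmsd` (models x groups matrix), `md_rmsd`
#'   (per-group vector), `test_idx` and `fold` assignment.
#' @export
run_repetition <- function(proto, dataset, map = NULL, repetition = 1L) {
  stopifnot(inherits(proto, "protocol"),
            inherits(dataset, "trajectory_dataset"))
  if (is.null(map)) map <- dataset$config$region_map
  pool <- dataset$trajectories
  if (length(pool) < proto$n_sampled) {
    stop("run_repetition: pool has ", length(pool),
         " trajectories, need ", proto$n_sampled)
  }
  rep_seed <- derive_seed(proto$seed, repetition)
  assignment <- with_seed(rep_seed, {
    sampled <- sample.int(length(pool), proto$n_sampled)
    fold <- rep(seq_len(proto$n_folds),
                each = proto$n_sampled %/% proto$n_folds)
    list(sampled = sampled, fold = fold)
  })
  sampled <- assignment$sampled
  fold <- assignment$fold
  holdout <- proto$n_folds
  train_idx <- sampled[fold != holdout]
  test_idx <- sampled[fold == holdout]

  keep_ids <- if (proto$tm_only) {
    intersect(region_subset(map, "TM"), pool[[1L]]$residue_ids)
  } else pool[[1L]]$residue_ids

  featurize <- function(tr) {
    keep <- tr$residue_ids %in% keep_ids
    feats <- trajectory_to_features(tr)
    cols <- as.integer(outer(1:3, (which(keep) - 1L) * 3L, `+`))
    feats[, cols, drop = FALSE]
  }
  feats <- vector("list", length(pool))
  for (i in c(train_idx, test_idx)) feats[[i]] <- featurize(pool[[i]])

  mm <- fit_minmax(do.call(rbind, feats[train_idx]))
  norm_feats <- feats
  for (i in c(train_idx, test_idx)) {
    norm_feats[[i]] <- apply_minmax(mm, feats[[i]])
  }
  split <- assemble_split(norm_feats, train_idx, test_idx,
                          n_steps_in = proto$n_steps_in)
  true_A <- invert_minmax(mm, split$test$y)
  input_dim <- ncol(true_A)

  res <- matrix(NA_real_, length(proto$models), length(proto$groups),
                dimnames = list(proto$models, proto$groups))
  for (m in proto$models) {
    spec <- build_model_spec(m, input_dim, proto$n_steps_in)
    fitcfg <- proto$fit
    fitcfg$seed <- derive_seed(rep_seed, match(m, proto$models))
    fitted <- fit_forecaster(spec, split$train, fitcfg)
    pred <- predict(fitted, split$test)
    ps <- prediction_set(invert_minmax(mm, pred), true_A, keep_ids)
    res[m, ] <- region_rmsd(ps, map, proto$groups)
  }
  md <- flexibility_md_rmsd(pool[test_idx], map, proto$groups,
                            n_steps_in = proto$n_steps_in)
  list(rmsd = res, md_rmsd = md, test_idx = test_idx, fold = fold,
       sampled = sampled)
}

#' Aggregate per-repetition RMSDs
#'
#' @param values numeric vector (or matrix row) of per-repetition RMSDs.
#' @return List with `mean` and `std` (sample standard deviation,
#'   `n - 1` denominator; 0 for a single repetition).
#' @export
aggregate_repetitions <- function(values) {
  list(mean = mean(values),
       std = if (length(values) >= 2L) stats::sd(values) else 0)
}

#' Two-sample t-test with significance flags
#'
#' Two-sided t-test on two vectors of per-repetition RMSDs, flagged at
#' the 0.05 and 0.01 levels. Welch's unequal-variance form is the
#' default; `var_equal = TRUE` gives the pooled-variance Student form.
#' If both samples are constant the test is degenerate: `p = 1` when the
#' means are equal, else `p = 0`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance form (default `FALSE`).
#' @return An object of class `ttest_result`: list with `t`, `p`,
#'   `flag05`, `flag01`.
#' @export
ttest_matrix <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    t <- if (p == 1) 0 else Inf
  } else {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    p <- ht$p.value
    t <- unname(ht$statistic)
  }
  structure(list(t = t, p = p, flag05 = p < 0.05, flag01 = p < 0.01),
            class = "ttest_result")
}

#' Run a full resampled experiment
#'
#' Executes every repetition of the protocol, aggregates the
#' per-(model, group) RMSDs to mean and standard deviation, and runs
#' pairwise two-sided t-tests model-vs-model within each group and
#' group-vs-group within each model (flags at 0.05 and 0.01; no
#' multiple-testing correction, and the number of comparisons is
#' recorded). The MD-RMSD flexibility column is averaged over the
#' repetitions' hold-out folds.
#'
#' @inheritParams run_repetition
#' @param var_equal pooled-variance t-tests instead of Welch.
#' @return An object of class `region_error_report`: list with
#'   `per_rep` (reps x models x groups array), `mean`, `std` (models x
#'   groups), `md_rmsd`, `model_tests`, `region_tests`, `n_comparisons`
#'   and the protocol.
#' @export
run_experiment <- function(proto, dataset, map = NULL,
                           var_equal = FALSE) {
  stopifnot(inherits(proto, "protocol"))
  if (is.null(map)) map <- dataset$config$region_map
  nm <- length(proto$models); ng <- length(proto$groups)
  per_rep <- array(NA_real_,
                   dim = c(proto$n_repetitions, nm, ng),
                   dimnames = list(NULL, proto$models, proto$groups))
  md_reps <- matrix(NA_real_, proto$n_repetitions, ng,
                    dimnames = list(NULL, proto$groups))
  for (r in seq_len(proto$n_repetitions)) {
    rep_out <- run_repetition(proto, dataset, map, repetition = r)
    per_rep[r, , ] <- rep_out$rmsd
    md_reps[r, ] <- rep_out$md_rmsd
  }
  mean_mat <- apply(per_rep, c(2, 3), mean)
  std_mat <- apply(per_rep, c(2, 3), function(v) {
    aggregate_repetitions(v)$std
  })

  pair_tests <- function(labels, extract) {
    out <- list()
    if (length(labels) < 2L || proto$n_repetitions < 2L) return(out)
    for (i in seq_along(labels)) for (j in seq_along(labels)) {
      if (i >= j) next
      tt <- ttest_matrix(extract(labels[i]), extract(labels[j]),
                         var_equal = var_equal)
      tt$pair <- c(labels[i], labels[j])
      out[[paste(labels[i], labels[j], sep = " vs ")]] <- tt
    }
    out
  }
  model_tests <- lapply(stats::setNames(proto$groups, proto$groups),
    function(g) pair_tests(proto$models,
                           function(m) per_rep[, m, g]))
  region_tests <- lapply(stats::setNames(proto$models, proto$models),
    function(m) pair_tests(proto$groups,
                           function(g) per_rep[, m, g]))
  n_comparisons <- sum(lengths(model_tests)) + sum(lengths(region_tests))

  structure(list(per_rep = per_rep, mean = mean_mat, std = std_mat,
                 md_rmsd = colMeans(md_reps), md_rmsd_per_rep = md_reps,
                 model_tests = model_tests, region_tests = region_tests,
                 n_comparisons = n_comparisons, protocol = proto),
            class = "region_error_report")
}

#' @export
print.region_error_report <- function(x, ...) {
  cat("<region_error_report>\n")
  cat("MD-RMSD:", paste(sprintf("%s=%.4f", names(x$md_rmsd), x$md_rmsd),
                        collapse = "  "), "\n")
  for (m in rownames(x$mean)) {
    cat(sprintf("%-12s %s\n", m,
                paste(sprintf("%s=%.4f±%.4f", colnames(x$mean),
                              x$mean[m, ], x$std[m, ]), collapse = "  ")))
  }
  invisible(x)
}
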