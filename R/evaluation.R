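#' Bundle predicted and true next-frame positions
#'
#' @param pred,true samples x 3N matrices in Angstrom, feature order
#'   (residue, axis) lexicographic by residue id.
#' @param residue_ids residue ids matching the feature columns.
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(pred, true, residue_ids) {
  pred <- rbind(pred); true <- rbind(true)
  stopifnot(all(dim(pred) == dim(true)),
            ncol(pred) == 3L * length(residue_ids),
            all(is.finite(pred)), all(is.finite(true)))
  structure(list(pred = pred, true = true,
                 residue_ids = as.integer(residue_ids)),
            class = "prediction_set")
}

# feature-column indices of a residue-id subset
feature_columns <- function(residue_ids, subset_ids) {
  pos <- match(subset_ids, residue_ids)
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0L) return(integer(0))
  as.integer(outer(1:3, (pos - 1L) * 3L, `+`))
}

#' Root-mean-square deviation between predicted and true positions
#'
#' Pooled RMSD: the square root of the mean, over every (sample,
#' residue) pair in the subset, of the squared Euclidean distance
#' between predicted and true 3D positions. `pooling = "per_sample"`
#' instead averages per-sample RMSDs (exposed for sensitivity checks;
#' the pooled form is the default used throughout).
#'
#' @param ps a [prediction_set].
#' @param subset_ids residue ids to include (default all).
#' @param pooling `"pooled"` or `"per_sample"`.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(ps, subset_ids = ps$residue_ids, pooling = "pooled") {
  stopifnot(inherits(ps, "prediction_set"))
  cols <- feature_columns(ps$residue_ids, subset_ids)
  if (length(cols) == 0L) stop("rmsd: empty residue subset")
  d2 <- (ps$pred[, cols, drop = FALSE] - ps$true[, cols, drop = FALSE])^2
  n_res <- length(cols) / 3L
  if (pooling == "pooled") {
    sqrt(sum(d2) / (nrow(d2) * n_res))
  } else if (pooling == "per_sample") {
    mean(sqrt(rowSums(d2) / n_res))
  } else stop("rmsd: unknown pooling '", pooling, "'")
}

#' Per-residue RMSD
#'
#' RMSD pooled over samples, separately for each residue; the vector
#' that [write_bfactor_pdb] colour-codes onto the structure.
#'
#' @param ps a [prediction_set].
#' @return Named numeric vector (names = residue ids), Angstrom.
#' @export
per_residue_rmsd <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"), nrow(ps$pred) >= 1L)
  d2 <- (ps$pred - ps$true)^2
  out <- vapply(seq_along(ps$residue_ids), function(i) {
    cols <- (i - 1L) * 3L + 1:3
    sqrt(mean(rowSums(d2[, cols, drop = FALSE])))
  }, numeric(1))
  names(out) <- ps$residue_ids
  out
}

#' Per-group RMSD rows for a prediction set
#'
#' Computes one pooled RMSD per requested region group (e.g. TM/ICL/ECL,
#' or TM1..TM7). Gap residues, which belong to no group, are simply not
#' selected; a group with no residues present in the prediction set is
#' an error naming the group.
#'
#' @param ps a [prediction_set].
#' @param map a [region_map].
#' @param groups character vector of group names for [region_subset].
#' @param pooling see [rmsd].
#' @return Named numeric vector of RMSDs, Angstrom.
#' @export
region_rmsd <- function(ps, map, groups, pooling = "pooled") {
  out <- vapply(groups, function(g) {
    ids <- intersect(region_subset(map, g), ps$residue_ids)
    if (length(ids) == 0L) {
      stop("region_rmsd: no residues present for group '", g, "'")
    }
    rmsd(ps, ids, pooling = pooling)
  }, numeric(1))
  names(out) <- groups
  out
}

#' Region-wise error table for one prediction set
#'
#' One pooled RMSD row per group plus a final `Mean` row averaging the
#' group RMSDs (the layout of the results tables' region blocks).
#'
#' @inheritParams region_rmsd
#' @return data.frame with columns `region` and `rmsd`.
#' @export
region_error_table <- function(ps, map, groups, pooling = "pooled") {
  r <- region_rmsd(ps, map, groups, pooling = pooling)
  data.frame(region = c(names(r), "Mean"),
             rmsd = c(unname(r), mean(r)),
             stringsAsFactors = FALSE)
}

#' Model-free flexibility baseline (MD-RMSD)
#'
#' The persistence-predictor RMSD per region group: the pooled RMSD
#' between each frame (from index `n_steps_in` onward, matching the
#' frames the forecasters are scored on) and its predecessor. This is
#' the per-step displacement of the molecular dynamics itself and is
#' reported as the MD-RMSD column of the results tables. For a
#' stationary OU process with scale `sigma` and autocorrelation `rho`
#' it equals `sigma * sqrt(6 * (1 - rho))`.
#'
#' @param trajectories list of [trajectory] objects.
#' @param map a [region_map].
#' @param groups group names for [region_subset].
#' @param n_steps_in first scored frame index (default 5).
#' @return Named numeric vector of RMSDs, Angstrom.
#' @export
flexibility_md_rmsd <- function(trajectories, map, groups,
                                n_steps_in = 5L) {
  usable <- Filter(function(tr) length(tr$frames) > n_steps_in,
                   trajectories)
  if (length(usable) == 0L) {
    stop("flexibility_md_rmsd: no trajectory with more than ",
         n_steps_in, " frames")
  }
  sets <- lapply(usable, function(tr) {
    feats <- trajectory_to_features(tr)
    idx <- (n_steps_in + 1L):nrow(feats)
    list(pred = feats[idx - 1L, , drop = FALSE],
         true = feats[idx, , drop = FALSE],
         ids = tr$residue_ids)
  })
  ids <- sets[[1L]]$ids
  ps <- prediction_set(do.call(rbind, lapply(sets, `[[`, "pred")),
                       do.call(rbind, lapply(sets, `[[`, "true")), ids)
  region_rmsd(ps, map, groups)
}
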