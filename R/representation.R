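#' Center of mass of one residue's atoms
#'
#' The per-residue representation used throughout the pipeline: the
#' mass-weighted mean position of the residue's atoms,
#' `sum(m_i * x_i) / sum(m_i)` per axis. All atoms present in the input
#' contribute, hydrogens included.
#'
#' @param positions numeric matrix, atoms x 3, in Angstrom.
#' @param masses numeric vector of atomic masses (Da), all > 0.
#' @return Numeric length-3 vector (x, y, z) in Angstrom.
#' @export
residue_center_of_mass <- function(positions, masses) {
  positions <- rbind(positions)
  if (nrow(positions) == 0L) stop("residue_center_of_mass: no atoms")
  stopifnot(ncol(positions) == 3L, length(masses) == nrow(positions),
            all(masses > 0))
  as.numeric(crossprod(positions, masses) / sum(masses))
}

#' Reduce an atom-level frame sequence to a residue-COM trajectory
#'
#' @param atom_frames list of atom frames as returned by
#'   [read_multimodel_pdb]: each a list with `residue_id`, `position`
#'   (atoms x 3) and `mass`.
#' @param frame_interval frame spacing in picoseconds (metadata).
#' @param state,condition provenance labels.
#' @return A [trajectory].
#' @export
atoms_to_com_trajectory <- function(atom_frames, frame_interval = 500,
                                    state = "synthetic",
                                    condition = "synthetic") {
  stopifnot(length(atom_frames) >= 1L)
  ids <- sort(unique(atom_frames[[1L]]$residue_id))
  frames <- lapply(atom_frames, function(fr) {
    pos <- t(vapply(ids, function(id) {
      sel <- fr$residue_id == id
      if (!any(sel)) stop("atoms_to_com_trajectory: residue ", id,
                          " missing from a frame")
      residue_center_of_mass(fr$position[sel, , drop = FALSE],
                             fr$mass[sel])
    }, numeric(3)))
    dimnames(pos) <- NULL
    pos
  })
  trajectory(residue_ids = ids, frames = frames,
             frame_interval = frame_interval,
             state = state, condition = condition)
}

#' Flatten a trajectory into a feature matrix
#'
#' Row `t` of the result is frame `t` flattened in the canonical feature
#' order: residues sorted by id, each contributing its (x, y, z) triplet,
#' giving `3 * n_residues` columns. This is the layout that the min-max
#' scaler and the forecasters operate on.
#'
#' @param traj a [trajectory].
#' @return Numeric matrix, frames x 3N, in Angstrom.
#' @export
trajectory_to_features <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  t(vapply(traj$frames, function(fr) as.numeric(t(fr)),
           numeric(3L * length(traj$residue_ids))))
}

#' Rebuild per-frame coordinate matrices from a feature matrix
#'
#' Inverse of [trajectory_to_features]: each row becomes an N x 3
#' coordinate matrix.
#'
#' @param features frames x 3N matrix.
#' @return List of N x 3 matrices.
#' @export
features_to_frames <- function(features) {
  features <- rbind(features)
  stopifnot(ncol(features) %% 3L == 0L)
  lapply(seq_len(nrow(features)), function(t) {
    matrix(features[t, ], ncol = 3L, byrow = TRUE)
  })
}

#' Linear min-max normalisation
#'
#' `fit_minmax` learns per-feature minima and maxima from training rows
#' (one feature per residue-axis column); `apply_minmax` maps to
#' `(x - min) / (max - min)`, which lies in `[0, 1]` on the fitting set
#' but may exceed it on held-out rows; `invert_minmax` maps back to
#' Angstrom. Degenerate features with `max == min` normalise to 0 and
#' invert back to their constant value.
#'
#' @param rows numeric matrix, samples x features (Angstrom for `fit`
#'   and `apply`, normalised for `invert`).
#' @return `fit_minmax`: an object of class `minmax_params` with fields
#'   `min`, `max`. `apply_minmax`/`invert_minmax`: a matrix shaped like
#'   `rows`.
#' @export
fit_minmax <- function(rows) {
  rows <- rbind(rows)
  stopifnot(nrow(rows) >= 1L)
  structure(
    list(min = apply(rows, 2L, min), max = apply(rows, 2L, max)),
    class = "minmax_params"
  )
}

#' @rdname fit_minmax
#' @param params a `minmax_params` object.
#' @export
apply_minmax <- function(params, rows) {
  rows <- rbind(rows)
  stopifnot(inherits(params, "minmax_params"),
            ncol(rows) == length(params$min))
  rng <- params$max - params$min
  rng[rng == 0] <- 1  # degenerate features map to 0
  sweep(sweep(rows, 2L, params$min, "-"), 2L, rng, "/")
}

#' @rdname fit_minmax
#' @export
invert_minmax <- function(params, rows) {
  rows <- rbind(rows)
  stopifnot(inherits(params, "minmax_params"),
            ncol(rows) == length(params$min))
  rng <- params$max - params$min
  sweep(sweep(rows, 2L, rng, "*"), 2L, params$min, "+")
}

#' Serialise min-max parameters to JSON
#'
#' @param params a `minmax_params` object.
#' @param path file path.
#' @export
write_minmax <- function(params, path) {
  stopifnot(inherits(params, "minmax_params"))
  jsonlite::write_json(list(min = params$min, max = params$max), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_minmax
#' @export
read_minmax <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = as.numeric(obj$min), max = as.numeric(obj$max)),
            class = "minmax_params")
}
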