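#' Build supervised next-frame windows from a feature matrix
#'
#' Slides a window of `n_steps_in` consecutive frames over the feature
#' matrix at stride 1 (an overlap of `n_steps_in - 1` frames between
#' consecutive windows) and pairs each window with the immediately
#' following frame as the target, so every frame with at least
#' `n_steps_in` predecessors appears exactly once as a target. A
#' trajectory of `F` frames yields `max(0, F - n_steps_in)` samples.
#'
#' @param features frames x P feature matrix (one trajectory).
#' @param n_steps_in window length in frames (default 5).
#' @param trajectory_index provenance index stored per sample.
#' @return An object of class `window_set`: list with `X` (samples x
#'   n_steps_in x P array), `y` (samples x P matrix), `n_steps_in`,
#'   `trajectory` and `target_frame` (0-based) per sample.
#' @export
make_windows <- function(features, n_steps_in = 5L,
                         trajectory_index = 1L) {
  features <- rbind(features)
  stopifnot(n_steps_in >= 1L)
  nf <- nrow(features); p <- ncol(features)
  ns <- max(0L, nf - n_steps_in)
  X <- array(0, dim = c(ns, n_steps_in, p))
  y <- matrix(0, ns, p)
  if (ns > 0L) {
    for (s in seq_len(ns)) {
      X[s, , ] <- features[s:(s + n_steps_in - 1L), , drop = FALSE]
      y[s, ] <- features[s + n_steps_in, ]
    }
  }
  structure(list(X = X, y = y, n_steps_in = as.integer(n_steps_in),
                 trajectory = rep(as.integer(trajectory_index), ns),
                 target_frame = if (ns > 0L)
                   seq.int(n_steps_in, nf - 1L) else integer(0)),
            class = "window_set")
}

#' Concatenate window sets
#'
#' @param sets list of `window_set` objects with equal `n_steps_in` and
#'   feature dimension.
#' @return A single `window_set`.
#' @export
bind_windows <- function(sets) {
  sets <- Filter(function(s) dim(s$X)[1L] > 0L, sets)
  if (length(sets) == 0L) stop("bind_windows: no samples")
  n_in <- unique(vapply(sets, `[[`, integer(1), "n_steps_in"))
  p <- unique(vapply(sets, function(s) dim(s$X)[3L], numeric(1)))
  stopifnot(length(n_in) == 1L, length(p) == 1L)
  ns <- sum(vapply(sets, function(s) dim(s$X)[1L], numeric(1)))
  X <- array(0, dim = c(ns, n_in, p))
  y <- matrix(0, ns, p)
  at <- 0L
  for (s in sets) {
    k <- dim(s$X)[1L]
    X[(at + 1L):(at + k), , ] <- s$X
    y[(at + 1L):(at + k), ] <- s$y
    at <- at + k
  }
  structure(list(X = X, y = y, n_steps_in = n_in,
                 trajectory = unlist(lapply(sets, `[[`, "trajectory")),
                 target_frame = unlist(lapply(sets, `[[`,
                                              "target_frame"))),
            class = "window_set")
}

#' Split trajectories into train and test window sets
#'
#' Windows are built within each trajectory and then concatenated, so no
#' window ever spans two trajectories; test windows come only from the
#' hold-out trajectories.
#'
#' @param feature_list list of per-trajectory feature matrices.
#' @param train_idx,test_idx disjoint integer vectors indexing
#'   `feature_list`; `test_idx` may be empty.
#' @param n_steps_in window length.
#' @return List with `train` and (if `test_idx` non-empty) `test`
#'   `window_set`s.
#' @export
assemble_split <- function(feature_list, train_idx, test_idx = integer(0),
                           n_steps_in = 5L) {
  if (length(intersect(train_idx, test_idx)) > 0L) {
    stop("assemble_split: train and test sets overlap")
  }
  if (length(train_idx) == 0L) stop("assemble_split: empty train partition")
  build <- function(idx) {
    bind_windows(lapply(idx, function(i) {
      make_windows(feature_list[[i]], n_steps_in, trajectory_index = i)
    }))
  }
  out <- list(train = build(train_idx))
  if (length(test_idx) > 0L) out$test <- build(test_idx)
  out
}

# flatten a window set's X to samples x (n_steps_in * P), last frame fastest
flatten_windows <- function(ws) {
  d <- dim(ws$X)
  matrix(ws$X, d[1L], d[2L] * d[3L])
}

# last input frame of every window (samples x P)
last_frame <- function(ws) {
  d <- dim(ws$X)
  matrix(ws$X[, d[2L], ], d[1L], d[3L])
}
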