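#' Configuration for the synthetic GPCR-trajectory generator
#'
#' Defines the study conditions the generator emulates: an idealised
#' seven-helix bundle whose residues fluctuate about their reference
#' positions with region-dependent amplitude. Each coordinate follows a
#' stationary AR(1)/Ornstein-Uhlenbeck process with one-step
#' autocorrelation `rho` and stationary standard deviation `sigma` set
#' per region, so transmembrane helices can be made stiffer than the
#' loops, the flexibility contrast the downstream region analysis
#' exploits. Closed forms for the process (stationary variance
#' `sigma^2`, per-step displacement RMSD `sigma*sqrt(6*(1-rho))`) serve
#' as test oracles.
#'
#' @param n_trajectories trajectories per dataset (default 2000).
#' @param n_frames frames per trajectory (default 28, >= 2).
#' @param frame_interval frame spacing, picoseconds (metadata; 500).
#' @param region_map a [region_map] (default [default_region_map]).
#' @param sigma_by_region named numeric vector: stationary displacement
#'   scale per coordinate in Angstrom for each region name in the map.
#'   Defaults: 0.5 for TM1..TM7, 1.5 for ICLs, 1.25 for ECLs, 1.0 for
#'   the termini.
#' @param rho one-step temporal autocorrelation, in `[0, 1)`.
#' @param bundle_radius radius of the helix ring, Angstrom.
#' @param helix_rise spacing of consecutive helix residues along the
#'   helix axis, Angstrom.
#' @param seed master seed for dataset generation.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_trajectories = 2000, n_frames = 28,
                             frame_interval = 500,
                             region_map = default_region_map(),
                             sigma_by_region = NULL, rho = 0.8,
                             bundle_radius = 12, helix_rise = 1.5,
                             seed = 1L) {
  stopifnot(n_frames >= 2, rho >= 0, rho < 1, n_trajectories >= 1,
            inherits(region_map, "region_map"))
  if (is.null(sigma_by_region)) {
    sigma_by_region <- vapply(region_map$name, function(nm) {
      if (grepl("^TM", nm)) 0.5
      else if (grepl("^ICL", nm)) 1.5
      else if (grepl("^ECL", nm)) 1.25
      else 1.0
    }, numeric(1))
  }
  missing_sigma <- setdiff(region_map$name, names(sigma_by_region))
  if (length(missing_sigma) > 0) {
    stop("synthetic_config: no sigma for region(s): ",
         paste(missing_sigma, collapse = ", "))
  }
  if (any(sigma_by_region < 0)) stop("synthetic_config: sigma must be >= 0")
  structure(list(
    n_trajectories = as.integer(n_trajectories),
    n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    region_map = region_map,
    sigma_by_region = sigma_by_region,
    rho = rho, bundle_radius = bundle_radius, helix_rise = helix_rise,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Idealised seven-helix reference structure
#'
#' Places each TM interval of the region map as a straight helical
#' segment on a ring of radius `bundle_radius`, at equal angles,
#' alternating direction along the membrane normal (z) so consecutive
#' helices run antiparallel as in a real bundle; consecutive helix
#' residues are exactly `helix_rise` apart along z. Loop and terminal
#' residues are interpolated linearly between the flanking helix
#' endpoints with a radial bulge away from the bundle axis. Residue ids
#' in unmapped stretches (the ICL3 gap) are omitted entirely, mirroring
#' the unresolved loop of the crystal structures.
#'
#' @param config a [synthetic_config].
#' @return An object of class `reference_structure`: list with
#'   `residue_ids`, `positions` (N x 3, Angstrom) and `region_labels`.
#' @export
build_reference_structure <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  map <- config$region_map
  tm_rows <- which(grepl("^TM[0-9]+$", map$name))
  n_tm <- length(tm_rows)
  angles <- 2 * pi * (seq_len(max(n_tm, 1)) - 1) / max(n_tm, 1)

  ids <- integer(0); pos <- NULL; labels <- character(0)
  # helix axis endpoints, keyed by TM row index, for loop interpolation
  helix_xy <- list(); helix_z <- list()

  for (k in seq_along(tm_rows)) {
    i <- tm_rows[k]
    rid <- seq.int(map$start[i], map$end[i] - 1L)
    nres <- length(rid)
    xy <- config$bundle_radius * c(cos(angles[k]), sin(angles[k]))
    half <- (nres - 1) * config$helix_rise / 2
    z <- seq(-half, half, length.out = nres)
    if (k %% 2 == 0) z <- rev(z)  # antiparallel packing
    helix_xy[[i]] <- xy
    helix_z[[i]] <- c(z[1L], z[nres])
    ids <- c(ids, rid)
    pos <- rbind(pos, cbind(xy[1], xy[2], z))
    labels <- c(labels, rep(map$name[i], nres))
  }

  # non-TM intervals: interpolate between the nearest helix endpoints
  other_rows <- setdiff(seq_len(nrow(map)), tm_rows)
  for (i in other_rows) {
    rid <- seq.int(map$start[i], map$end[i] - 1L)
    nres <- length(rid)
    prev_tm <- tm_rows[tm_rows < i]
    next_tm <- tm_rows[tm_rows > i]
    if (length(prev_tm) > 0) {
      p <- max(prev_tm)
      a <- c(helix_xy[[p]], helix_z[[p]][2L])
    } else {
      a <- NULL
    }
    if (length(next_tm) > 0) {
      q <- min(next_tm)
      b <- c(helix_xy[[q]], helix_z[[q]][1L])
    } else {
      b <- NULL
    }
    if (is.null(a)) a <- b + c(0, 0, 5)   # N-terminal dangle
    if (is.null(b)) b <- a + c(0, 0, -5)  # C-terminal dangle
    f <- seq(0, 1, length.out = nres + 2L)[2:(nres + 1L)]
    seg <- cbind(a[1] + f * (b[1] - a[1]),
                 a[2] + f * (b[2] - a[2]),
                 a[3] + f * (b[3] - a[3]))
    # radial bulge: loops arc outward from the bundle axis
    bulge <- 4 * sin(pi * f)
    r <- sqrt(seg[, 1]^2 + seg[, 2]^2)
    r[r < 1e-9] <- 1e-9
    seg[, 1] <- seg[, 1] * (1 + bulge / r)
    seg[, 2] <- seg[, 2] * (1 + bulge / r)
    ids <- c(ids, rid)
    pos <- rbind(pos, seg)
    labels <- c(labels, rep(map$name[i], nres))
  }

  ord <- order(ids)
  structure(list(residue_ids = ids[ord],
                 positions = unname(pos[ord, , drop = FALSE]),
                 region_labels = labels[ord]),
            class = "reference_structure")
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# deterministic per-trajectory seed below 2^31
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %%
               2147483587)
}

#' Simulate one Ornstein-Uhlenbeck trajectory about a reference
#'
#' Every coordinate evolves independently as a stationary AR(1) process
#' `x[t+1] = mu + rho * (x[t] - mu) + eta`,
#' `eta ~ N(0, sigma^2 * (1 - rho^2))`, where `mu` is the reference
#' position and `sigma` the region's stationary scale. Frame 0 is drawn
#' from the stationary law `N(mu, sigma^2)`, so no burn-in is needed.
#'
#' @param ref a `reference_structure`.
#' @param config a [synthetic_config] (supplies `sigma_by_region`,
#'   `rho`, `n_frames`).
#' @param seed integer seed for this trajectory.
#' @return A [trajectory] with `state = "synthetic"`.
#' @export
simulate_trajectory <- function(ref, config, seed = config$seed) {
  stopifnot(inherits(ref, "reference_structure"),
            inherits(config, "synthetic_config"))
  missing_sigma <- setdiff(unique(ref$region_labels),
                           names(config$sigma_by_region))
  if (length(missing_sigma) > 0) {
    stop("simulate_trajectory: no sigma for region(s): ",
         paste(missing_sigma, collapse = ", "))
  }
  n <- length(ref$residue_ids)
  sigma <- unname(config$sigma_by_region[ref$region_labels])
  rho <- config$rho
  mu <- ref$positions
  frames <- with_seed(seed, {
    out <- vector("list", config$n_frames)
    dev <- matrix(stats::rnorm(n * 3L), n, 3L) * sigma
    out[[1L]] <- mu + dev
    innov_sd <- sigma * sqrt(1 - rho^2)
    for (t in seq_len(config$n_frames - 1L)) {
      dev <- rho * dev + matrix(stats::rnorm(n * 3L), n, 3L) * innov_sd
      out[[t + 1L]] <- mu + dev
    }
    out
  })
  trajectory(ref$residue_ids, frames,
             frame_interval = config$frame_interval,
             state = "synthetic", condition = "synthetic")
}

#' Generate a full synthetic trajectory dataset
#'
#' Builds the reference structure once and simulates
#' `config$n_trajectories` independent trajectories; per-trajectory
#' seeds are derived deterministically from `config$seed` and the
#' trajectory index, so equal configs give bitwise-equal datasets.
#'
#' @param config a [synthetic_config].
#' @return An object of class `trajectory_dataset`: list with
#'   `trajectories`, `reference`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ref <- build_reference_structure(config)
  trajs <- lapply(seq_len(config$n_trajectories), function(i) {
    simulate_trajectory(ref, config, seed = derive_seed(config$seed, i))
  })
  structure(list(trajectories = trajs, reference = ref, config = config),
            class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf("<trajectory_dataset> %d trajectories x %d frames x %d residues\n",
              length(x$trajectories), x$config$n_frames,
              length(x$reference$residue_ids)))
  invisible(x)
}

#' Read/write a synthetic-generator configuration as YAML
#'
#' The serialized form carries every scalar field plus the region map
#' and the per-region sigmas, so a run is fully described by one file.
#'
#' @param config a [synthetic_config].
#' @param path file path.
#' @return `read_synthetic_config` returns a [synthetic_config].
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  map <- config$region_map
  yaml::write_yaml(list(
    n_trajectories = config$n_trajectories,
    n_frames = config$n_frames,
    frame_interval = config$frame_interval,
    rho = config$rho,
    bundle_radius = config$bundle_radius,
    helix_rise = config$helix_rise,
    seed = config$seed,
    sigma_by_region = as.list(config$sigma_by_region),
    regions = lapply(seq_len(nrow(map)), function(i) {
      list(name = map$name[i], start = map$start[i], end = map$end[i])
    })
  ), path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  obj <- yaml::read_yaml(path)
  map <- region_map(
    name = vapply(obj$regions, `[[`, character(1), "name"),
    start = vapply(obj$regions, `[[`, numeric(1), "start"),
    end = vapply(obj$regions, `[[`, numeric(1), "end"))
  synthetic_config(
    n_trajectories = obj$n_trajectories, n_frames = obj$n_frames,
    frame_interval = obj$frame_interval, region_map = map,
    sigma_by_region = unlist(obj$sigma_by_region), rho = obj$rho,
    bundle_radius = obj$bundle_radius, helix_rise = obj$helix_rise,
    seed = obj$seed)
}

#' Per-residue root-mean-square fluctuation of a trajectory
#'
#' RMSF about the per-residue mean position, pooled over frames: the
#' standard per-residue flexibility measure.
#'
#' @param traj a [trajectory].
#' @return Named numeric vector (names = residue ids), Angstrom.
#' @export
trajectory_rmsf <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  arr <- simplify2array(traj$frames)  # N x 3 x F
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mean_pos)^2
  rmsf <- sqrt(apply(dev2, 1, mean) * 3)  # mean over 3F cells * 3 axes
  names(rmsf) <- traj$residue_ids
  rmsf
}
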