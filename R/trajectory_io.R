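#' Residue-level trajectory container
#'
#' An ordered sequence of frames of per-residue 3D positions in Angstrom.
#' All frames share the same residue ids and ordering.
#'
#' @param residue_ids strictly increasing integer vector.
#' @param frames list of N x 3 numeric matrices, one per frame.
#' @param frame_interval time between frames in picoseconds (metadata).
#' @param state provenance label, e.g. `"2RH1"`, `"3P0G"`, `"synthetic"`.
#' @param condition provenance label, e.g. `"APO"`, `"FA"`, `"PIA"`,
#'   `"synthetic"`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(residue_ids, frames, frame_interval = 500,
                       state = "synthetic", condition = "synthetic") {
  residue_ids <- as.integer(residue_ids)
  stopifnot(length(frames) >= 1L,
            !is.unsorted(residue_ids, strictly = TRUE))
  n <- length(residue_ids)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n &&
                 ncol(f) == 3L, logical(1))
  if (!all(ok)) stop("trajectory: frame ", which(!ok)[1L],
                     " does not match residue_ids (need ", n, " x 3)")
  structure(list(residue_ids = residue_ids, frames = frames,
                 frame_interval = frame_interval, state = state,
                 condition = condition),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames x %d residues, %g ps/frame [%s/%s]\n",
    length(x$frames), length(x$residue_ids), x$frame_interval,
    x$state, x$condition))
  invisible(x)
}

# Standard atomic weights (Da) for elements seen in protein structures.
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, MG = 24.305, ZN = 65.38,
  NA. = 22.990, CL = 35.45, K = 39.098, CA = 40.078, MN = 54.938,
  CU = 63.546, F = 18.998, BR = 79.904, I = 126.904
)

element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."  # sodium; avoid the missing-value name
  m <- .atomic_weights[key]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# Infer the element from a PDB v3.3 atom-name field. One-letter elements
# are right-justified in columns 13-14 (" CA " is an alpha carbon, C);
# two-letter elements occupy both columns ("FE  ", "MG  ").
infer_element <- function(name4) {
  two_letter <- c("FE", "MG", "ZN", "NA", "CL", "BR", "SE", "MN", "CU")
  vapply(name4, function(nm) {
    nm <- toupper(nm)
    padded <- formatC(nm, width = 4, flag = "-")
    lead2 <- gsub(" ", "", substr(padded, 1, 2))
    if (nchar(lead2) == 2 && lead2 %in% two_letter) return(lead2)
    stripped <- gsub("[ 0-9']", "", nm)
    if (nchar(stripped) == 0) stop("cannot infer element from atom name '",
                                   nm, "'")
    substr(stripped, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a multi-model PDB file as a sequence of atom frames
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame (a file with no MODEL
#' records is one frame). Elements come from the PDB element column when
#' present, otherwise they are inferred from the atom-name field; masses
#' come from a built-in standard-atomic-weight table. Models with
#' differing atom counts are rejected with the offending model index.
#'
#' @param path PDB file path.
#' @return List of atom frames, each a list with `atom_name`, `element`,
#'   `mass` (Da), `residue_id` and `position` (atoms x 3, Angstrom).
#' @details Coordinate parsing is delegated to [bio3d::read.pdb]; this
#'   wrapper validates the model blocks first (bio3d assumes equal atom
#'   counts) and layers element inference and masses on top.
#' @export
read_multimodel_pdb <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 0L) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts)) {
      stop("read_multimodel_pdb: unbalanced MODEL/ENDMDL records")
    }
    counts <- mapply(function(s, e) sum(is_atom[s:e]),
                     model_starts, model_ends)
  } else {
    counts <- sum(is_atom)
  }
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1L])[1L]
    stop(sprintf(
      "read_multimodel_pdb: model %d has %d atoms, expected %d",
      bad, counts[bad], counts[1L]))
  }
  if (counts[1L] == 0L) stop("read_multimodel_pdb: no ATOM records")

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  elem <- trimws(pdb$atom$elesy)
  elem[is.na(elem)] <- ""
  blank <- elem == ""
  if (any(blank)) elem[blank] <- infer_element(pdb$atom$elety[blank])
  mass <- element_mass(elem)
  resid <- as.integer(pdb$atom$resno)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  lapply(seq_len(nrow(xyz)), function(m) {
    list(
      atom_name = trimws(pdb$atom$elety),
      element = elem,
      mass = mass,
      residue_id = resid,
      position = matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    )
  })
}

pdb_atom_line <- function(serial, name, resname, resid, xyz, b = 0,
                          element = "C") {
  name4 <- if (nchar(name) < 4 && nchar(element) == 1) {
    formatC(paste0(" ", name), width = 4, flag = "-")
  } else {
    formatC(name, width = 4, flag = "-")
  }
  sprintf("ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resname, resid, xyz[1], xyz[2], xyz[3], 1.00, b,
          formatC(element, width = 2))
}

#' Write a trajectory as a multi-model pseudo-atom PDB
#'
#' One CA pseudo-atom per residue center of mass, one `MODEL` block per
#' frame (PDB v3.3 fixed width).
#'
#' @param traj a [trajectory].
#' @param path output file path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", t), con)
    fr <- traj$frames[[t]]
    for (i in seq_along(traj$residue_ids)) {
      writeLines(pdb_atom_line(i, "CA", "GLY", traj$residue_ids[i],
                               fr[i, ]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write per-residue values into the B-factor column of a PDB file
#'
#' Produces a single-model PDB with one CA pseudo-atom per residue at the
#' reference position and the residue's value in the temperature-factor
#' column (`%6.2f`, PDB v3.3), the standard vehicle for colour-coding a
#' per-residue score onto a structure in molecular viewers.
#'
#' @param ref a `reference_structure` (see [build_reference_structure])
#'   or any list with `residue_ids` and `positions`.
#' @param values named or unnamed numeric vector, one finite value per
#'   residue in `ref` (names, if given, are residue ids).
#' @param path output file path.
#' @export
write_bfactor_pdb <- function(ref, values, path) {
  ids <- ref$residue_ids
  if (!is.null(names(values))) {
    unknown <- setdiff(names(values), as.character(ids))
    if (length(unknown) > 0) {
      stop("write_bfactor_pdb: value(s) for unknown residue id(s): ",
           paste(unknown, collapse = ", "))
    }
    values <- values[as.character(ids)]
  }
  if (length(values) != length(ids)) {
    stop("write_bfactor_pdb: need one value per residue (",
         length(ids), "), got ", length(values))
  }
  if (!all(is.finite(values))) stop("write_bfactor_pdb: non-finite values")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(pdb_atom_line(i, "CA", "GLY", ids[i],
                             ref$positions[i, ], b = values[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read/write the columnar residue-trajectory table
#'
#' The bulk text format: CSV with header `frame,residue_id,x,y,z`
#' (coordinates in Angstrom). Frames are sorted ascending and residues by
#' id on read; every (frame, residue) cell must be present.
#'
#' @param traj a [trajectory].
#' @param path file path.
#' @param frame_interval,state,condition metadata attached on read.
#' @return `read_residue_table` returns a [trajectory].
#' @export
write_residue_table <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$residue_ids)
  df <- data.frame(
    frame = rep(seq_along(traj$frames) - 1L, each = n),
    residue_id = rep(traj$residue_ids, times = length(traj$frames)),
    do.call(rbind, traj$frames)
  )
  names(df)[3:5] <- c("x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_residue_table
#' @export
read_residue_table <- function(path, frame_interval = 500,
                               state = "synthetic",
                               condition = "synthetic") {
  df <- utils::read.csv(path)
  need <- c("frame", "residue_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("read_residue_table: header must contain ",
         paste(need, collapse = ","))
  }
  frames_idx <- sort(unique(df$frame))
  ids <- sort(unique(df$residue_id))
  key <- paste(df$frame, df$residue_id)
  want <- expand.grid(residue_id = ids, frame = frames_idx)
  missing <- !(paste(want$frame, want$residue_id) %in% key)
  if (any(missing)) {
    gap <- want[which(missing)[1L], ]
    stop(sprintf("read_residue_table: missing cell frame %d residue %d",
                 gap$frame, gap$residue_id))
  }
  ord <- order(df$frame, df$residue_id)
  df <- df[ord, ]
  n <- length(ids)
  frames <- lapply(seq_along(frames_idx), function(t) {
    block <- df[((t - 1L) * n + 1L):(t * n), ]
    unname(cbind(block$x, block$y, block$z))
  })
  trajectory(ids, frames, frame_interval = frame_interval,
             state = state, condition = condition)
}
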