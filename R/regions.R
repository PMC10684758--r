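#' Residue-interval region maps for seven-transmembrane receptors
#'
#' A region map is an ordered set of half-open residue-id intervals
#' `[start, end)` naming the structural regions of a GPCR: the N-terminus,
#' the seven transmembrane helices TM1..TM7, the intracellular loops
#' ICL1..ICL2, the extracellular loops ECL1..ECL3, and the C-terminus.
#' Residue ids not covered by any interval are "gap" residues; for the
#' beta2-adrenergic receptor the third intracellular loop is unresolved in
#' the source crystal structures and its ids are deliberately unmapped.
#'
#' @param name character vector of region names.
#' @param start,end integer vectors; each region covers ids in
#'   `[start, end)` (0-based, half-open).
#' @return An object of class `region_map`: a data.frame with columns
#'   `name`, `start`, `end`.
#' @examples
#' rm <- region_map(c("TM1", "ICL1"), c(30, 61), c(61, 68))
#' assign_region(rm, 61)
#' @export
region_map <- function(name, start, end) {
  stopifnot(length(name) == length(start), length(start) == length(end))
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(end <= start)) {
    stop("region_map: empty interval(s): ",
         paste(name[end <= start], collapse = ", "))
  }
  ord <- order(start)
  name <- name[ord]; start <- start[ord]; end <- end[ord]
  if (anyDuplicated(name)) {
    stop("region_map: duplicated region name(s)")
  }
  if (length(start) > 1L && any(start[-1L] < end[-length(end)])) {
    bad <- which(start[-1L] < end[-length(end)])[1L]
    stop(sprintf("region_map: overlapping intervals '%s' and '%s'",
                 name[bad], name[bad + 1L]))
  }
  structure(
    data.frame(name = name, start = start, end = end,
               stringsAsFactors = FALSE),
    class = c("region_map", "data.frame")
  )
}

#' Default beta2AR region map
#'
#' The canonical residue-interval assignment for the beta2-adrenergic
#' receptor: N-terminus `[0,30)`, TM1 `[30,61)`, ICL1 `[61,68)`, TM2
#' `[68,97)`, ECL1 `[97,104)`, TM3 `[104,137)`, ICL2 `[137,148)`, TM4
#' `[148,172)`, ECL2 `[172,198)`, TM5 `[198,230)`, TM6 `[268,299)`, ECL3
#' `[299,306)`, TM7 `[306,329)`, C-terminus `[329,344)`. Ids in
#' `[230,268)` are unmapped: the third intracellular loop is replaced by
#' T4-lysozyme (inactive state) or a nanobody (active state) in the
#' crystal structures and is absent from the data.
#'
#' @return A [region_map].
#' @export
default_region_map <- function() {
  region_map(
    name = c("N-term", "TM1", "ICL1", "TM2", "ECL1", "TM3", "ICL2",
             "TM4", "ECL2", "TM5", "TM6", "ECL3", "TM7", "C-term"),
    start = c(0, 30, 61, 68, 97, 104, 137, 148, 172, 198, 268, 299, 306, 329),
    end   = c(30, 61, 68, 97, 104, 137, 148, 172, 198, 230, 299, 306, 329, 344)
  )
}

#' Assign a residue id to its region
#'
#' @param map a [region_map].
#' @param residue_id integer vector of residue ids (>= 0).
#' @return Character vector: region name, or `"gap"` for unmapped ids.
#' @export
assign_region <- function(map, residue_id) {
  stopifnot(inherits(map, "region_map"), all(residue_id >= 0))
  vapply(as.integer(residue_id), function(id) {
    hit <- which(map$start <= id & id < map$end)
    if (length(hit) == 1L) map$name[hit] else "gap"
  }, character(1))
}

#' Residue ids belonging to a region group
#'
#' Groups aggregate the map's intervals: `"TM"` is the union of TM1..TM7,
#' `"ICL"` of ICL1 and ICL2, `"ECL"` of ECL1..ECL3, `"ALL-mapped"` every
#' mapped id; any single region name selects that interval alone.
#'
#' @param map a [region_map].
#' @param group one of `"TM"`, `"ICL"`, `"ECL"`, `"ALL-mapped"`, or a
#'   region name present in `map`.
#' @return Sorted integer vector of residue ids.
#' @export
region_subset <- function(map, group) {
  stopifnot(inherits(map, "region_map"), is.character(group),
            length(group) == 1L)
  pick <- switch(group,
    "TM"  = grepl("^TM[0-9]+$", map$name),
    "ICL" = grepl("^ICL[0-9]+$", map$name),
    "ECL" = grepl("^ECL[0-9]+$", map$name),
    "ALL-mapped" = rep(TRUE, nrow(map)),
    map$name == group
  )
  if (!any(pick)) {
    stop(sprintf("region_subset: unknown group '%s'", group))
  }
  ids <- unlist(lapply(which(pick), function(i) {
    seq.int(map$start[i], map$end[i] - 1L)
  }), use.names = FALSE)
  sort(unique(ids))
}

#' Read/write a region map as YAML
#'
#' Serialized form is a list of `{name, start, end}` records, half-open
#' 0-based intervals (BED-like), so maps for other receptors or the
#' active-state numbering can be supplied as plain config files.
#'
#' @param map a [region_map].
#' @param path file path.
#' @return `read_region_map` returns a [region_map];
#'   `write_region_map` returns `path` invisibly.
#' @export
write_region_map <- function(map, path) {
  stopifnot(inherits(map, "region_map"))
  recs <- lapply(seq_len(nrow(map)), function(i) {
    list(name = map$name[i], start = map$start[i], end = map$end[i])
  })
  yaml::write_yaml(list(regions = recs), path)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  obj <- yaml::read_yaml(path)
  recs <- obj$regions
  if (is.null(recs)) stop("read_region_map: no 'regions' key in ", path)
  region_map(
    name = vapply(recs, `[[`, character(1), "name"),
    start = vapply(recs, `[[`, numeric(1), "start"),
    end = vapply(recs, `[[`, numeric(1), "end")
  )
}
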