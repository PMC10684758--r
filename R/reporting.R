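#' Render a region-error report as TSV and Markdown tables
#'
#' Region rows by model columns, cells `mean ± std` with significance
#' markers: `*` for p < 0.05 and `**` for p < 0.01 against any other
#' model in the same region (the tables' model-column convention), plus
#' the MD-RMSD flexibility column and a final `Mean` row across
#' regions.
#'
#' @param report a `region_error_report` (see [run_experiment]).
#' @param path_tsv,path_md optional output file paths.
#' @param digits decimals for means and stds (default 4).
#' @return data.frame of the rendered cells (invisibly if written).
#' @export
render_results_table <- function(report, path_tsv = NULL,
                                 path_md = NULL, digits = 4) {
  stopifnot(inherits(report, "region_error_report"))
  groups <- colnames(report$mean)
  models <- rownames(report$mean)
  marker <- function(m, g) {
    tests <- report$model_tests[[g]]
    worst <- ""
    for (tt in tests) {
      if (!(m %in% tt$pair)) next
      other <- setdiff(tt$pair, m)
      if (report$mean[m, g] > report$mean[other, g]) {
        if (tt$flag01) worst <- "**"
        else if (tt$flag05 && worst == "") worst <- "*"
      }
    }
    worst
  }
  fmt <- function(mu, sd) sprintf(paste0("%.", digits, "f ± %.", digits,
                                         "f"), mu, sd)
  rows <- lapply(groups, function(g) {
    cells <- vapply(models, function(m) {
      paste0(fmt(report$mean[m, g], report$std[m, g]), marker(m, g))
    }, character(1))
    c(region = g,
      `MD-RMSD` = sprintf(paste0("%.", digits, "f"),
                          report$md_rmsd[[g]]),
      cells)
  })
  mean_row <- c(region = "Mean",
                `MD-RMSD` = sprintf(paste0("%.", digits, "f"),
                                    mean(report$md_rmsd)),
                vapply(models, function(m) {
                  fmt(mean(report$mean[m, ]), mean(report$std[m, ]))
                }, character(1)))
  df <- as.data.frame(do.call(rbind, c(rows, list(mean_row))),
                      stringsAsFactors = FALSE)
  if (!is.null(path_tsv)) {
    utils::write.table(df, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(path_md)) {
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    writeLines(c(header, sep, body), path_md)
  }
  if (is.null(path_tsv) && is.null(path_md)) df else invisible(df)
}

#' Export per-residue prediction errors onto the structure
#'
#' Writes the per-residue RMSD of a prediction set into the B-factor
#' column of a pseudo-atom PDB at the reference positions, for
#' colour-coded display in any structure viewer. Residues of the
#' reference that carry no error value (e.g. when only a residue subset
#' was predicted) are omitted from the file.
#'
#' @param ps a [prediction_set].
#' @param ref a `reference_structure`.
#' @param path output PDB path.
#' @export
export_error_structure <- function(ps, ref, path) {
  errs <- per_residue_rmsd(ps)
  keep <- ref$residue_ids %in% as.integer(names(errs))
  sub_ref <- list(residue_ids = ref$residue_ids[keep],
                  positions = ref$positions[keep, , drop = FALSE])
  write_bfactor_pdb(sub_ref, errs[as.character(sub_ref$residue_ids)],
                    path)
}

#' Write a run manifest
#'
#' Records the protocol, seeds and package version of a run as JSON so
#' deterministic runs can be reproduced bit-compatibly.
#'
#' @param proto a [protocol].
#' @param path output JSON path.
#' @param extra named list of additional fields.
#' @export
write_manifest <- function(proto, path, extra = list()) {
  obj <- c(list(
    package = "gpcrforecast",
    version = as.character(utils::packageVersion("gpcrforecast")),
    n_sampled = proto$n_sampled, n_folds = proto$n_folds,
    n_repetitions = proto$n_repetitions, groups = proto$groups,
    models = proto$models, tm_only = proto$tm_only,
    n_steps_in = proto$n_steps_in, seed = proto$seed,
    epochs = proto$fit$epochs, batch_size = proto$fit$batch_size
  ), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
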