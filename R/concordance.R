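#' TE/PBMC concordance analysis
#'
#' The headline question: does any blood cell of an infant carry the CNA
#' reported in the embryo's TE biopsy? Each (cell event, TE event) pair is
#' classified by reciprocal position and direction; a cell "corresponds to
#' the TE biopsy" iff at least one of its events is concordant with a TE
#' event. Correspondence is operationalized as >= 50% overlap of the
#' smaller event with matching direction (configurable): an overlapping
#' event with the opposite direction — e.g. a short blood-cell deletion
#' inside a region the biopsy reported as gained — is direction-discordant,
#' not concordant.
#'
#' @name concordance
NULL

#' Classify one (cell event, TE event) pair
#'
#' Overlap fraction `o` = overlap bp / length of the smaller event.
#' `no_overlap` if `o = 0`; `concordant` if `o >= min_overlap` and the
#' directions match; `direction_discordant` if `o > 0` and the directions
#' differ; otherwise `partial_overlap`.
#'
#' @param cell_event one row of [call_cna_events()] output.
#' @param te_event one row of TE events (from [te_pipeline()]).
#' @param min_overlap minimum reciprocal overlap for concordance.
#' @return one of `"concordant"`, `"direction_discordant"`,
#'   `"partial_overlap"`, `"no_overlap"`.
#' @export
classify_pair <- function(cell_event, te_event, min_overlap = 0.5) {
  if (cell_event$chrom != te_event$chrom) return("no_overlap")
  ov <- min(cell_event$end_bp, te_event$end_bp) -
    max(cell_event$start_bp, te_event$start_bp)
  if (ov <= 0) return("no_overlap")
  o <- ov / min(cell_event$end_bp - cell_event$start_bp,
                te_event$end_bp - te_event$start_bp)
  if (cell_event$direction != te_event$direction)
    return("direction_discordant")
  if (o >= min_overlap) return("concordant")
  "partial_overlap"
}

MATCH_CLASSES <- c("concordant", "direction_discordant", "partial_overlap",
                   "no_overlap")

#' Summarize one infant
#'
#' Cross-tabulates every QC-passing cell's CNA events against the infant's
#' TE biopsy events. A cell is counted concordant iff any of its pairs is
#' concordant. The detection floor `1 / n_cells_pass_qc` is reported: with
#' zero concordant cells among n, mosaicism in blood is absent or below
#' that fraction.
#'
#' @param infant_id label.
#' @param cell_events data.frame of CNA events for this infant's cells
#'   (rows may be empty for cells without CNAs).
#' @param te_events data.frame of the infant's TE biopsy events.
#' @param qc data.frame with `cell_id` and `pass_all` for this infant.
#' @param min_overlap passed to [classify_pair()].
#' @return an `infant_summary` list: counts, `fraction_with_cna`,
#'   `n_cells_concordant`, per-class pair counts, `detection_floor`,
#'   `pairs` (the full pair classification table), `flagged` when no cell
#'   passed QC.
#' @export
summarize_infant <- function(infant_id, cell_events, te_events, qc,
                             min_overlap = 0.5) {
  passing <- qc$cell_id[qc$pass_all]
  n_pass <- length(passing)
  cell_events <- cell_events[cell_events$cell_id %in% passing, , drop = FALSE]
  cna_cells <- unique(cell_events$cell_id)
  pair_rows <- list()
  concordant_cells <- character(0)
  if (nrow(cell_events) > 0 && nrow(te_events) > 0) {
    for (a in seq_len(nrow(cell_events))) {
      for (b in seq_len(nrow(te_events))) {
        cls <- classify_pair(cell_events[a, ], te_events[b, ], min_overlap)
        pair_rows[[length(pair_rows) + 1]] <- data.frame(
          infant_id = infant_id, cell_id = cell_events$cell_id[a],
          cell_chrom = cell_events$chrom[a],
          cell_start = cell_events$start_bp[a],
          cell_end = cell_events$end_bp[a],
          cell_direction = cell_events$direction[a],
          te_chrom = te_events$chrom[b], te_start = te_events$start_bp[b],
          te_end = te_events$end_bp[b],
          te_direction = te_events$direction[b],
          class = cls, stringsAsFactors = FALSE)
        if (cls == "concordant")
          concordant_cells <- union(concordant_cells,
                                    cell_events$cell_id[a])
      }
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(infant_id = character(), cell_id = character(),
               cell_chrom = character(), cell_start = numeric(),
               cell_end = numeric(), cell_direction = character(),
               te_chrom = character(), te_start = numeric(),
               te_end = numeric(), te_direction = character(),
               class = character(), stringsAsFactors = FALSE)
  class_counts <- setNames(vapply(MATCH_CLASSES, function(cl)
    sum(pairs$class == cl), numeric(1)), MATCH_CLASSES)
  structure(list(
    infant_id = infant_id,
    n_cells_pass_qc = n_pass,
    n_cells_with_cna = length(cna_cells),
    fraction_with_cna = if (n_pass > 0) length(cna_cells) / n_pass
                        else NA_real_,
    n_cells_concordant = length(concordant_cells),
    concordant_cells = concordant_cells,
    class_counts = class_counts,
    detection_floor = if (n_pass > 0) 1 / n_pass else NA_real_,
    pairs = pairs,
    flagged = n_pass == 0), class = "infant_summary")
}

#' @export
print.infant_summary <- function(x, ...) {
  cat(sprintf(
    "infant %s: %d cells pass QC, %d with CNAs (%.2f%%), %d concordant with TE\n",
    x$infant_id, x$n_cells_pass_qc, x$n_cells_with_cna,
    100 * (x$fraction_with_cna %||% NA), x$n_cells_concordant))
  invisible(x)
}

#' Cohort report across infants
#'
#' One row per infant plus the unweighted mean CNA-cell fraction across
#' infants. Optionally writes a TSV of the table and a JSON of the whole
#' report.
#'
#' @param summaries list of `infant_summary` objects.
#' @param tsv_path,json_path optional output paths.
#' @return list with `table` (data.frame) and `mean_cna_fraction`.
#' @export
cohort_report <- function(summaries, tsv_path = NULL, json_path = NULL) {
  stopifnot(length(summaries) >= 1)
  tab <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(infant_id = s$infant_id,
               n_cells_pass_qc = s$n_cells_pass_qc,
               n_cells_with_cna = s$n_cells_with_cna,
               fraction_with_cna = s$fraction_with_cna,
               n_cells_concordant = s$n_cells_concordant,
               detection_floor = s$detection_floor,
               n_pairs_concordant = s$class_counts[["concordant"]],
               n_pairs_direction_discordant =
                 s$class_counts[["direction_discordant"]],
               n_pairs_partial = s$class_counts[["partial_overlap"]],
               n_pairs_no_overlap = s$class_counts[["no_overlap"]],
               stringsAsFactors = FALSE)
  }))
  mean_frac <- mean(tab$fraction_with_cna, na.rm = TRUE)
  if (!is.null(tsv_path))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(infants = tab,
                              mean_cna_fraction = mean_frac),
                         json_path, auto_unbox = TRUE, digits = NA)
  list(table = tab, mean_cna_fraction = mean_frac)
}
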