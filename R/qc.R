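#' Cell-level quality control
#'
#' Cells are excluded when the coefficient of variation (CV) of their
#' depth-normalized bin counts is >= 1 or when their total usable unique
#' read count is <= 300,000. (The read threshold is printed elsewhere in
#' scientific notation with a negative exponent, which is physically
#' meaningless for a read count; this package reads it as 3e5 reads, the
#' order required to populate ~2800 bins, and documents the interpretation
#' as a corrected typo.) A further "manual check" of CNA profiles is
#' replaced here by pinned automated criteria ([auto_profile_check()]) —
#' a stand-in, not a reproduction, so published pass rates that depended
#' on manual review are not expected to be reproduced. The scRNA-seq
#' filter ([rna_qc()]) excludes cells with fewer than 300 detected genes
#' or more than 30% mitochondrial reads.
#'
#' @name qc
NULL

#' Coefficient of variation of bin counts
#'
#' Sample standard deviation over mean of per-bin depth-normalized counts,
#' computed on unmasked autosomal bins. A zero mean yields `Inf` (the cell
#' then fails QC).
#'
#' @param profile a `cell_profile` or `ratio_profile`.
#' @param scaffold the matching `bin_scaffold`.
#' @return non-negative scalar (possibly `Inf`).
#' @export
compute_cv <- function(profile, scaffold) {
  sel <- usable_autosomal(scaffold)
  v <- if (inherits(profile, "cell_profile")) profile$counts[sel]
       else profile$ratios[sel]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 unmasked bins for CV")
  m <- mean(v)
  if (m <= 0) return(Inf)
  sd(v) / m
}

#' Apply the DNA-library quality filter
#'
#' Exclusion rule: `cv >= cv_max` OR `total_usable_reads <= min_reads`.
#' Both boundaries exclude a cell sitting exactly at the threshold.
#'
#' @param records data.frame with at least `cell_id`, `cv`,
#'   `total_usable_reads`; optionally `auto_pass` from
#'   [auto_profile_check()] (assumed `TRUE` when absent).
#' @param cv_max CV threshold (default 1.0).
#' @param min_reads usable-read threshold (default 3e5).
#' @return the table with `pass_cv`, `pass_reads`, `pass_auto`, `pass_all`
#'   columns added.
#' @export
apply_dna_qc <- function(records, cv_max = 1.0, min_reads = 3e5) {
  stopifnot(all(c("cell_id", "cv", "total_usable_reads") %in% names(records)))
  records$pass_cv <- records$cv < cv_max
  records$pass_reads <- records$total_usable_reads > min_reads
  if (is.null(records$auto_pass)) records$auto_pass <- TRUE
  records$pass_auto <- records$auto_pass
  records$pass_all <- records$pass_cv & records$pass_reads & records$pass_auto
  records
}

#' Automated profile-quality check
#'
#' Automated stand-in for a manual review of copy-number profiles. A cell
#' fails when any of: (a) MAPD — the median absolute difference of
#' consecutive (within-chromosome, unmasked autosomal) normalized bins —
#' exceeds `mapd_max`; (b) more than `max_segments` segments genome-wide
#' (over-segmentation); (c) more than `max_nonmodal_frac` of the autosomal
#' genome sits at non-modal copy number while no single event reaches
#' `min_event_bp` (a fragmentation signature: lots of scattered deviation
#' with no coherent event).
#'
#' @param cn_profile a `cn_profile`.
#' @param ratio a `ratio_profile` for the same cell (for MAPD).
#' @param scaffold the matching `bin_scaffold`.
#' @param mapd_max MAPD threshold (default 0.45).
#' @param max_segments genome-wide segment count limit (default 40).
#' @param max_nonmodal_frac fragmentation threshold (default 0.30).
#' @param min_event_bp coherent-event length rescuing a fragmented call.
#' @return list with `score` (the MAPD), `pass`, `reasons`.
#' @export
auto_profile_check <- function(cn_profile, ratio, scaffold, mapd_max = 0.45,
                               max_segments = 40, max_nonmodal_frac = 0.30,
                               min_event_bp = 10e6) {
  stopifnot(inherits(cn_profile, "cn_profile"),
            inherits(ratio, "ratio_profile"))
  mapd <- profile_mapd(ratio, scaffold)
  reasons <- character(0)
  if (mapd > mapd_max)
    reasons <- c(reasons, sprintf("MAPD %.3f > %.2f", mapd, mapd_max))
  segs <- cn_profile$segments
  if (nrow(segs) > max_segments)
    reasons <- c(reasons, sprintf("%d segments > %d", nrow(segs),
                                  max_segments))
  auto <- segs[is_autosome(segs$chrom), , drop = FALSE]
  if (nrow(auto)) {
    span <- auto$end_bp - auto$start_bp
    modal <- as.integer(names(which.max(tapply(span, auto$cn, sum))))
    nonmodal <- auto$cn != modal
    frac <- sum(span[nonmodal]) / sum(span)
    if (frac > max_nonmodal_frac && !any(span[nonmodal] >= min_event_bp))
      reasons <- c(reasons,
                   sprintf("%.0f%% of genome at non-modal CN, fragmented",
                           100 * frac))
  }
  list(score = mapd, pass = length(reasons) == 0, reasons = reasons)
}

profile_mapd <- function(ratio, scaffold) {
  diffs <- c()
  idx_by_chrom <- scaffold_chrom_index(scaffold)
  for (ch in names(idx_by_chrom)) {
    if (!is_autosome(ch)) next
    bins_idx <- idx_by_chrom[[ch]]
    v <- ratio$ratios[bins_idx]
    v <- v[!scaffold$bad[bins_idx] & !is.na(v)]
    if (length(v) >= 2) diffs <- c(diffs, abs(diff(v)))
  }
  if (!length(diffs)) return(NA_real_)
  median(diffs)
}

#' scRNA-seq cell filter
#'
#' Pass iff `genes_detected >= min_genes` and `mito_fraction <= max_mito`:
#' the published criteria are strict inequalities ("less than 300 detected
#' genes", "more than 30 percent mitochondrial reads" excluded), so a cell
#' exactly at either boundary is retained.
#'
#' @param genes_detected integer vector, detected genes per cell.
#' @param mito_fraction numeric vector in [0, 1].
#' @param min_genes,max_mito thresholds.
#' @return logical vector.
#' @export
rna_qc <- function(genes_detected, mito_fraction, min_genes = 300,
                   max_mito = 0.30) {
  stopifnot(length(genes_detected) == length(mito_fraction),
            all(mito_fraction >= 0 & mito_fraction <= 1, na.rm = TRUE))
  genes_detected >= min_genes & mito_fraction <= max_mito
}

#' Build a QC table for a set of cells
#'
#' @param profiles list of `cell_profile` objects.
#' @param ratios named list of `ratio_profile` objects (for MAPD); may be
#'   `NULL`.
#' @param cn_profiles named list of `cn_profile` objects for the automated
#'   profile check; may be `NULL` (then `auto_pass = TRUE`).
#' @param scaffold the matching `bin_scaffold`.
#' @inheritParams apply_dna_qc
#' @return data.frame with one row per cell and all metrics and pass flags.
#' @export
qc_table <- function(profiles, scaffold, ratios = NULL, cn_profiles = NULL,
                     cv_max = 1.0, min_reads = 3e5) {
  rows <- lapply(profiles, function(p) {
    auto_pass <- TRUE
    score <- NA_real_
    if (!is.null(cn_profiles) && !is.null(ratios) &&
        p$cell_id %in% names(cn_profiles)) {
      chk <- auto_profile_check(cn_profiles[[p$cell_id]],
                                ratios[[p$cell_id]], scaffold)
      auto_pass <- chk$pass
      score <- chk$score
    }
    data.frame(cell_id = p$cell_id, plate_id = as.character(p$plate_id),
               sex = p$sex, cv = compute_cv(p, scaffold),
               total_usable_reads = p$total_usable_reads,
               auto_check_score = score, auto_pass = auto_pass,
               stringsAsFactors = FALSE)
  })
  apply_dna_qc(do.call(rbind, rows), cv_max = cv_max, min_reads = min_reads)
}
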