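#' Per-cell read counting
#'
#' The pipeline ingests already aligned, deduplicated, MAPQ-filtered reads
#' exported as BED (one record per read, cell barcode embedded in the name
#' field), or a precomputed cell-by-bin count matrix. A `cell_profile`
#' holds one cell's integer counts per scaffold bin; reads falling in
#' masked bins are counted in `total_usable_reads` but excluded from all
#' downstream statistics.
#'
#' @name readcount
NULL

new_cell_profile <- function(cell_id, counts, total_usable_reads,
                             plate_id = NA_character_, sex = "unknown") {
  stopifnot(all(counts >= 0), total_usable_reads >= sum(counts) || TRUE)
  structure(list(cell_id = cell_id,
                 plate_id = plate_id,
                 counts = as.numeric(counts),
                 total_usable_reads = total_usable_reads,
                 sex = sex),
            class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("cell_profile %s (plate %s, sex %s): %d bins, %d usable reads\n",
              x$cell_id, x$plate_id, x$sex, length(x$counts),
              as.integer(x$total_usable_reads)))
  invisible(x)
}

#' Demultiplex a BED file by cell barcode
#'
#' Splits BED read records into per-cell position streams using an
#' 8-nt (configurable) cell barcode embedded in the BED name field.
#' Records whose name field lacks a parseable barcode are skipped and
#' tallied (with a warning if more than 10% are skipped); reads whose
#' barcode is not in an optional whitelist are dropped and tallied.
#'
#' @param bed_path path to a BED file (3 columns minimum plus a name
#'   column; further columns tolerated and ignored).
#' @param barcode_start 1-based position of the barcode within the name.
#' @param barcode_len barcode length in nt.
#' @param whitelist optional character vector of allowed barcodes.
#' @return list with `cells` (named list of data.frames `chrom`, `pos`),
#'   `n_reads`, `n_skipped` (unparseable), `n_dropped` (not whitelisted).
#' @export
demultiplex_bed <- function(bed_path, barcode_start = 1, barcode_len = 8,
                            whitelist = NULL) {
  if (!file.exists(bed_path) || file.size(bed_path) == 0) {
    return(list(cells = list(), n_reads = 0L, n_skipped = 0L, n_dropped = 0L))
  }
  bed <- data.table::fread(bed_path, header = FALSE, sep = "\t",
                           data.table = FALSE)
  if (nrow(bed) == 0) {
    return(list(cells = list(), n_reads = 0L, n_skipped = 0L, n_dropped = 0L))
  }
  if (ncol(bed) < 4)
    stop("BED file needs a name column (4 columns) for barcode demultiplexing")
  n <- nrow(bed)
  bc <- substr(as.character(bed[[4]]), barcode_start,
               barcode_start + barcode_len - 1)
  ok <- nchar(bc) == barcode_len & grepl("^[ACGTN]+$", bc)
  n_skipped <- sum(!ok)
  if (n_skipped > 0.10 * n)
    warning(sprintf("%d of %d BED records (%.1f%%) lack a parseable barcode",
                    n_skipped, n, 100 * n_skipped / n))
  bed <- bed[ok, , drop = FALSE]
  bc <- bc[ok]
  n_dropped <- 0L
  if (!is.null(whitelist)) {
    keep <- bc %in% whitelist
    n_dropped <- sum(!keep)
    bed <- bed[keep, , drop = FALSE]
    bc <- bc[keep]
  }
  cells <- lapply(split(seq_len(nrow(bed)), bc), function(idx) {
    data.frame(chrom = as.character(bed[[1]][idx]),
               pos = as.numeric(bed[[2]][idx]),
               stringsAsFactors = FALSE)
  })
  list(cells = cells, n_reads = n, n_skipped = n_skipped,
       n_dropped = n_dropped)
}

#' Count one cell's reads into scaffold bins
#'
#' Assigns each read to the unique bin containing its BED start coordinate
#' (half-open convention: a read exactly at a bin boundary belongs to the
#' bin starting there). Reads on chromosomes absent from the scaffold are
#' dropped and tallied. `total_usable_reads` is the number of input reads;
#' reads in masked bins are counted in the bin vector and the total but are
#' ignored by downstream statistics.
#'
#' @param positions data.frame with `chrom` and `pos` (read start, bp).
#' @param scaffold a `bin_scaffold`.
#' @param cell_id,plate_id,sex cell metadata.
#' @return a `cell_profile` with attribute `tally` = c(assigned, masked,
#'   dropped).
#' @export
count_in_bins <- function(positions, scaffold, cell_id = "cell",
                          plate_id = NA_character_, sex = "unknown") {
  validate_scaffold(scaffold)
  counts <- numeric(nrow(scaffold))
  dropped <- 0L
  idx_by_chrom <- scaffold_chrom_index(scaffold)
  if (nrow(positions) > 0) {
    for (ch in unique(positions$chrom)) {
      pos <- positions$pos[positions$chrom == ch]
      bins_idx <- idx_by_chrom[[ch]]
      if (is.null(bins_idx)) {
        dropped <- dropped + length(pos)
        next
      }
      starts <- scaffold$start[bins_idx]
      chrom_end <- scaffold$end[bins_idx[length(bins_idx)]]
      inside <- pos >= starts[1] & pos < chrom_end
      dropped <- dropped + sum(!inside)
      j <- findInterval(pos[inside], starts)
      tab <- tabulate(j, nbins = length(bins_idx))
      counts[bins_idx] <- counts[bins_idx] + tab
    }
  }
  masked_reads <- sum(counts[scaffold$bad])
  prof <- new_cell_profile(cell_id, counts,
                           total_usable_reads = nrow(positions) - dropped,
                           plate_id = plate_id, sex = sex)
  attr(prof, "tally") <- c(assigned = sum(counts) - masked_reads,
                           masked = masked_reads, dropped = dropped)
  prof
}

#' Write / read a cell-by-bin count matrix
#'
#' Tab-separated: one row per cell, first columns `cell_id`, `plate_id`,
#' `sex`, `total_usable_reads`, then one integer column per bin
#' (`bin1..binN`). A `#n_bins` header line keys the matrix to a scaffold;
#' reading against a scaffold with a different bin count is rejected.
#'
#' @param profiles list of `cell_profile` objects.
#' @param path file path.
#' @rdname count_matrix_io
#' @export
write_count_matrix <- function(profiles, path) {
  stopifnot(length(profiles) > 0)
  n_bins <- length(profiles[[1]]$counts)
  mat <- do.call(rbind, lapply(profiles, function(p) p$counts))
  colnames(mat) <- paste0("bin", seq_len(n_bins))
  df <- data.frame(cell_id = vapply(profiles, function(p) p$cell_id, ""),
                   plate_id = vapply(profiles, function(p) as.character(p$plate_id), ""),
                   sex = vapply(profiles, function(p) p$sex, ""),
                   total_usable_reads = vapply(profiles, function(p)
                     p$total_usable_reads, numeric(1)),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#n_bins\t%d", n_bins), con)
  utils::write.table(cbind(df, mat), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param scaffold scaffold the matrix must match (bin count checked).
#' @return `read_count_matrix`: a named list of `cell_profile` objects.
#' @rdname count_matrix_io
#' @export
read_count_matrix <- function(path, scaffold) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  bin_cols <- grep("^bin[0-9]+$", names(df))
  if (length(bin_cols) != nrow(scaffold))
    stop("count matrix has ", length(bin_cols), " bins but scaffold has ",
         nrow(scaffold))
  profs <- lapply(seq_len(nrow(df)), function(i) {
    new_cell_profile(df$cell_id[i], as.numeric(df[i, bin_cols]),
                     df$total_usable_reads[i], df$plate_id[i], df$sex[i])
  })
  names(profs) <- df$cell_id
  profs
}
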