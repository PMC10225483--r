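#' Genomic bin scaffolds
#'
#' A `bin_scaffold` is the coordinate frame for the whole pipeline: an
#' ordered set of non-overlapping, contiguous genomic bins, each carrying a
#' GC fraction, a bad-bin exclusion flag, and a positive weight (the bin's
#' expected relative read share). Coordinates are 0-based half-open
#' (BED convention). Bins flagged `bad` keep their coordinates — they are
#' never re-indexed — but are excluded from every downstream statistic.
#'
#' @name bin_scaffold
#' @rdname bin_scaffold
NULL

new_scaffold <- function(bins, genome_id, mode, chrom_lengths) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "gc", "bad", "weight") %in% names(bins)))
  bins$chrom <- as.character(bins$chrom)
  bins$start <- as.numeric(bins$start)
  bins$end <- as.numeric(bins$end)
  bins$bad <- as.logical(bins$bad)
  rownames(bins) <- NULL
  obj <- structure(bins,
                   genome_id = genome_id,
                   mode = mode,
                   chrom_lengths = chrom_lengths,
                   class = c("bin_scaffold", "data.frame"))
  validate_scaffold(obj)
  obj
}

validate_scaffold <- function(scaffold) {
  bins <- as.data.frame(scaffold)
  if (any(bins$end <= bins$start))
    stop("scaffold invalid: bins with end <= start")
  cl <- attr(scaffold, "chrom_lengths")
  for (chrom in unique(bins$chrom)) {
    b <- bins[bins$chrom == chrom, ]
    if (is.unsorted(b$start, strictly = TRUE))
      stop("scaffold invalid: bins not sorted on ", chrom)
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))
      stop("scaffold invalid: bins not contiguous on ", chrom)
    if (!is.null(cl)) {
      if (b$start[1] != 0 || b$end[nrow(b)] != cl[[chrom]])
        stop("scaffold invalid: bins do not cover ", chrom, " exactly")
    }
  }
  gc_ok <- is.na(bins$gc) | (bins$gc >= 0 & bins$gc <= 1)
  if (!all(gc_ok)) stop("scaffold invalid: gc outside [0,1]")
  if (any(!is.na(bins$gc) & is.nan(bins$gc))) stop("scaffold invalid: NaN gc")
  if (any(bins$weight <= 0)) stop("scaffold invalid: non-positive weight")
  invisible(scaffold)
}

#' @export
print.bin_scaffold <- function(x, ...) {
  cat(sprintf("bin_scaffold '%s' (%s mode): %d bins, %d chromosomes, %d masked\n",
              attr(x, "genome_id"), attr(x, "mode"), nrow(x),
              length(unique(x$chrom)), sum(x$bad)))
  invisible(x)
}

#' Build a fixed-width bin scaffold
#'
#' Tiles each chromosome with `floor(length / target_bin_bp)` bins of width
#' `target_bin_bp`; the last bin absorbs the remainder so each chromosome is
#' covered exactly. This is the fixed-width fallback used for synthetic
#' genomes; real scaffolds with mappability-derived variable bins come from
#' [build_weighted_scaffold()] or [read_scaffold()].
#'
#' @param chrom_lengths named numeric vector or list, chromosome lengths in bp.
#' @param target_bin_bp target bin width in bp.
#' @param genome_id label stored on the scaffold.
#' @param mode `"single_cell"` (~1.0 Mb bins) or `"te_biopsy"` (~2.5 Mb bins).
#' @return a `bin_scaffold`.
#' @export
build_uniform_scaffold <- function(chrom_lengths, target_bin_bp,
                                   genome_id = "synthetic",
                                   mode = c("single_cell", "te_biopsy")) {
  mode <- match.arg(mode)
  chrom_lengths <- unlist(chrom_lengths)
  stopifnot(length(chrom_lengths) > 0, target_bin_bp > 0)
  short <- names(chrom_lengths)[chrom_lengths < target_bin_bp]
  if (length(short))
    stop("chromosome(s) shorter than target bin size: ",
         paste(short, collapse = ", "))
  rows <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    n <- floor(len / target_bin_bp)
    starts <- (seq_len(n) - 1) * target_bin_bp
    ends <- c(starts[-1], len)
    data.frame(chrom = chrom, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  bins$gc <- NA_real_
  bins$bad <- FALSE
  bins$weight <- (bins$end - bins$start) / mean(bins$end - bins$start)
  new_scaffold(bins, genome_id, mode, as.list(chrom_lengths))
}

#' Build an equal-expected-read (variable-width) bin scaffold
#'
#' Places bin boundaries so that the cumulative weight of a density track
#' (expected reads per genomic window, e.g. a mappability track) is divided
#' as equally as possible among `n_bins` bins. Bins never cross chromosome
#' boundaries; chromosomes receive bin counts proportional to their total
#' weight (largest-remainder apportionment, at least one bin each).
#' Boundaries are placed by inverting the piecewise-linear cumulative weight
#' within windows, so zero-weight (e.g. telomeric) windows are absorbed into
#' a neighbouring bin rather than forming zero-weight bins.
#'
#' @param density_track data.frame with columns `chrom`, `start`, `end`,
#'   `weight` (non-negative), windows tiling each chromosome.
#' @param n_bins total number of bins across the genome.
#' @inheritParams build_uniform_scaffold
#' @return a `bin_scaffold` whose `weight` column holds each bin's share of
#'   the density (normalized to mean 1).
#' @export
build_weighted_scaffold <- function(density_track, n_bins,
                                    genome_id = "synthetic",
                                    mode = c("single_cell", "te_biopsy")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(density_track),
            all(c("chrom", "start", "end", "weight") %in% names(density_track)),
            n_bins >= 1)
  if (any(density_track$weight < 0)) stop("density weights must be non-negative")
  n_pos <- sum(density_track$weight > 0)
  if (n_bins > n_pos)
    stop("n_bins (", n_bins, ") exceeds the number of positive-weight windows (",
         n_pos, ")")
  chroms <- unique(density_track$chrom)
  chrom_w <- vapply(chroms, function(ch) {
    sum(density_track$weight[density_track$chrom == ch])
  }, numeric(1))
  if (any(chrom_w <= 0)) stop("chromosome with zero total weight: ",
                              paste(chroms[chrom_w <= 0], collapse = ", "))
  n_per <- apportion_largest_remainder(chrom_w, n_bins)
  chrom_lengths <- list()
  rows <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    win <- density_track[density_track$chrom == ch, , drop = FALSE]
    win <- win[order(win$start), , drop = FALSE]
    chrom_lengths[[ch]] <- max(win$end)
    edges <- quantile_cut_positions(win, n_per[k])
    starts <- edges[-length(edges)]
    ends <- edges[-1]
    w <- cum_weight_at(win, ends) - cum_weight_at(win, starts)
    rows[[k]] <- data.frame(chrom = ch, start = starts, end = ends,
                            weight = w, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, rows)
  bins$gc <- NA_real_
  bins$bad <- FALSE
  bins$weight <- bins$weight / mean(bins$weight)
  bins <- bins[, c("chrom", "start", "end", "gc", "bad", "weight")]
  new_scaffold(bins, genome_id, mode, chrom_lengths)
}

# n_i proportional to w, summing exactly to n, each >= 1.
apportion_largest_remainder <- function(w, n) {
  if (length(w) > n) stop("more chromosomes than bins requested")
  quota <- w / sum(w) * n
  base <- pmax(1L, floor(quota))
  while (sum(base) > n) { # pulling up to 1 each may overshoot
    i <- which.max(base - quota)
    base[i] <- base[i] - 1L
  }
  rem <- quota - base
  while (sum(base) < n) {
    i <- which.max(rem)
    base[i] <- base[i] + 1L
    rem[i] <- -Inf
  }
  as.integer(base)
}

# Piecewise-linear cumulative weight of windows, evaluated at bp positions.
cum_weight_at <- function(win, pos) {
  cw <- cumsum(win$weight)
  idx <- findInterval(pos, win$start, left.open = FALSE)
  idx[idx < 1] <- 1
  idx[idx > nrow(win)] <- nrow(win)
  prev <- c(0, cw)[idx]
  frac <- (pos - win$start[idx]) / (win$end[idx] - win$start[idx])
  frac <- pmin(pmax(frac, 0), 1)
  prev + frac * win$weight[idx]
}

# Integer bp edges splitting the chromosome into n bins of ~equal weight.
quantile_cut_positions <- function(win, n) {
  lo <- min(win$start); hi <- max(win$end)
  if (n == 1) return(c(lo, hi))
  total <- sum(win$weight)
  targets <- total * seq_len(n - 1) / n
  cw <- cumsum(win$weight)
  cuts <- vapply(targets, function(t) {
    j <- which(cw >= t)[1]
    prev <- if (j > 1) cw[j - 1] else 0
    if (win$weight[j] <= 0) return(win$start[j])
    win$start[j] + (t - prev) / win$weight[j] * (win$end[j] - win$start[j])
  }, numeric(1))
  edges <- c(lo, round(cuts), hi)
  # guard against duplicate edges from integer snapping
  for (i in 2:length(edges)) {
    if (edges[i] <= edges[i - 1]) edges[i] <- edges[i - 1] + 1
  }
  if (edges[length(edges)] > hi) stop("degenerate density: cannot place distinct bin edges")
  edges
}

#' Annotate scaffold bins with GC content
#'
#' Sets each bin's `gc` to (G+C)/(A+C+G+T) over the bin's sequence, ignoring
#' N bases. Bins that are entirely N get `gc = NA` and are flagged bad.
#' The source is either a genome FASTA (read with Biostrings) or a
#' data.frame of per-window GC fractions (`chrom`, `start`, `end`, `gc`),
#' which is averaged over each bin weighted by overlap length.
#'
#' @param scaffold a `bin_scaffold`.
#' @param sequence_source path to a FASTA file, or a per-window GC table.
#' @return the scaffold with `gc` (and possibly `bad`) updated.
#' @export
annotate_gc <- function(scaffold, sequence_source) {
  validate_scaffold(scaffold)
  if (is.character(sequence_source)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("Biostrings is required to read FASTA sequence sources")
    seqs <- Biostrings::readDNAStringSet(sequence_source)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    missing <- setdiff(unique(scaffold$chrom), names(seqs))
    if (length(missing))
      stop("sequence source lacks chromosome(s): ", paste(missing, collapse = ", "))
    for (i in seq_len(nrow(scaffold))) {
      sub <- Biostrings::subseq(seqs[[scaffold$chrom[i]]],
                                start = scaffold$start[i] + 1,
                                end = scaffold$end[i])
      freq <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
      tot <- sum(freq)
      if (tot == 0) {
        scaffold$gc[i] <- NA_real_
        scaffold$bad[i] <- TRUE
      } else {
        scaffold$gc[i] <- (freq[["C"]] + freq[["G"]]) / tot
      }
    }
  } else if (is.data.frame(sequence_source)) {
    stopifnot(all(c("chrom", "start", "end", "gc") %in% names(sequence_source)))
    missing <- setdiff(unique(scaffold$chrom), unique(sequence_source$chrom))
    if (length(missing))
      stop("sequence source lacks chromosome(s): ", paste(missing, collapse = ", "))
    for (i in seq_len(nrow(scaffold))) {
      win <- sequence_source[sequence_source$chrom == scaffold$chrom[i], ]
      ov <- pmin(win$end, scaffold$end[i]) - pmax(win$start, scaffold$start[i])
      keep <- ov > 0 & !is.na(win$gc)
      if (!any(keep)) {
        scaffold$gc[i] <- NA_real_
        scaffold$bad[i] <- TRUE
      } else {
        scaffold$gc[i] <- sum(win$gc[keep] * ov[keep]) / sum(ov[keep])
      }
    }
  } else stop("sequence_source must be a FASTA path or a GC window table")
  validate_scaffold(scaffold)
  scaffold
}

#' Mask bad bins by interval overlap
#'
#' Flags `bad = TRUE` for every bin whose overlap with the union of the
#' given intervals is at least 50% of the bin's span (threshold
#' configurable). Masked bins keep their coordinates; they are simply
#' excluded from all downstream statistics.
#'
#' @param scaffold a `bin_scaffold`.
#' @param bad_list data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. read from a 3-column BED.
#' @param min_overlap_frac minimum overlapped fraction of the bin span.
#' @return the scaffold with updated `bad` flags.
#' @export
mask_bad_bins <- function(scaffold, bad_list, min_overlap_frac = 0.5) {
  validate_scaffold(scaffold)
  if (is.null(bad_list) || nrow(bad_list) == 0) return(scaffold)
  stopifnot(all(c("chrom", "start", "end") %in% names(bad_list)))
  for (ch in unique(bad_list$chrom)) {
    iv <- coalesce_intervals(bad_list[bad_list$chrom == ch, c("start", "end")])
    sel <- which(scaffold$chrom == ch)
    for (i in sel) {
      ov <- sum(pmax(0, pmin(iv$end, scaffold$end[i]) -
                        pmax(iv$start, scaffold$start[i])))
      if (ov >= min_overlap_frac * (scaffold$end[i] - scaffold$start[i]))
        scaffold$bad[i] <- TRUE
    }
  }
  scaffold
}

coalesce_intervals <- function(iv) {
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) <= 1) return(iv)
  out_start <- iv$start[1]; out_end <- iv$end[1]
  starts <- c(); ends <- c()
  for (i in 2:nrow(iv)) {
    if (iv$start[i] <= out_end) {
      out_end <- max(out_end, iv$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- iv$start[i]; out_end <- iv$end[i]
    }
  }
  data.frame(start = c(starts, out_start), end = c(ends, out_end))
}

#' Write / read a scaffold as BED-like TSV
#'
#' The file is a tab-separated table (`chrom`, `start`, `end`, `gc`, `bad`,
#' `weight`) preceded by `#key<TAB>value` header lines recording the genome
#' id, mode, and chromosome lengths, so the round-trip is lossless.
#' `read_scaffold(one_based = TRUE)` accepts the 1-based inclusive dialect
#' (starts are shifted down by one on read).
#'
#' @param scaffold a `bin_scaffold`.
#' @param path file path.
#' @rdname scaffold_io
#' @export
write_scaffold <- function(scaffold, path) {
  validate_scaffold(scaffold)
  cl <- attr(scaffold, "chrom_lengths")
  meta <- c(genome_id = attr(scaffold, "genome_id"),
            mode = attr(scaffold, "mode"),
            chrom_lengths = paste(sprintf("%s:%.0f", names(cl), unlist(cl)),
                                  collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\t%s", names(meta), meta), con)
  utils::write.table(as.data.frame(scaffold), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param one_based if `TRUE`, input coordinates are 1-based inclusive and
#'   are converted to the internal 0-based half-open convention.
#' @rdname scaffold_io
#' @export
read_scaffold <- function(path, one_based = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", lines[h]), "\t")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  bins <- tryCatch(
    utils::read.table(text = body, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed scaffold file: ", conditionMessage(e)))
  need <- c("chrom", "start", "end", "gc", "bad", "weight")
  if (!all(need %in% names(bins)))
    stop("scaffold file missing columns: ",
         paste(setdiff(need, names(bins)), collapse = ", "))
  bad_rows <- which(is.na(bins$start) | is.na(bins$end))
  if (length(bad_rows))
    stop("malformed scaffold line ", bad_rows[1] + length(hdr) + 1)
  if (one_based) bins$start <- bins$start - 1
  cl <- NULL
  if (!is.null(meta$chrom_lengths)) {
    parts <- strsplit(strsplit(meta$chrom_lengths, ",")[[1]], ":")
    cl <- setNames(lapply(parts, function(p) as.numeric(p[2])),
                   vapply(parts, `[`, "", 1))
  } else {
    cl <- lapply(split(bins$end, bins$chrom), max)
  }
  new_scaffold(bins, meta$genome_id %||% "unknown",
               meta$mode %||% "single_cell", cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scaffold_chrom_index <- function(scaffold) {
  split(seq_len(nrow(scaffold)), scaffold$chrom)[unique(scaffold$chrom)]
}
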