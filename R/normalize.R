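#' Copy-ratio normalization
#'
#' Raw bin counts become copy ratios through three ordered stages:
#' depth normalization (divide by the cell's mean unmasked autosomal count),
#' LOWESS GC-bias correction, and plate-pooled control correction. After
#' every stage the profile is renormalized so that the mean over unmasked
#' autosomal bins is exactly 1; sex chromosomes never shift the baseline
#' (a male X/Y at copy number 1 would otherwise bias the genome mean).
#' A `ratio_profile` records the stage it has reached and the pipeline
#' refuses to apply control correction out of order.
#'
#' @name normalize
NULL

new_ratio_profile <- function(cell_id, ratios, stage,
                              plate_id = NA_character_, sex = "unknown") {
  structure(list(cell_id = cell_id, plate_id = plate_id, sex = sex,
                 ratios = as.numeric(ratios), stage = stage),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("ratio_profile %s (stage %s): %d bins\n",
              x$cell_id, x$stage, length(x$ratios)))
  invisible(x)
}

usable_autosomal <- function(scaffold) {
  !scaffold$bad & is_autosome(scaffold$chrom)
}

renormalize_ratios <- function(ratios, scaffold) {
  sel <- usable_autosomal(scaffold) & !is.na(ratios)
  m <- mean(ratios[sel])
  if (!is.finite(m) || m <= 0) stop("cannot renormalize: non-positive mean ratio")
  ratios / m
}

#' Depth-normalize a cell's bin counts
#'
#' `ratio_b = count_b / mean(count over unmasked autosomal bins)`. Masked
#' bins carry `NA`. A cell whose unmasked bins are all zero is unusable and
#' rejected.
#'
#' @param profile a `cell_profile`.
#' @param scaffold the matching `bin_scaffold`.
#' @return a `ratio_profile` at stage `"depth"`.
#' @export
depth_normalize <- function(profile, scaffold) {
  stopifnot(inherits(profile, "cell_profile"),
            length(profile$counts) == nrow(scaffold))
  sel <- usable_autosomal(scaffold)
  if (!any(profile$counts[sel] > 0))
    stop("cell ", profile$cell_id, " has no reads in unmasked bins; unusable")
  ratios <- profile$counts / mean(profile$counts[sel])
  ratios[scaffold$bad] <- NA_real_
  new_ratio_profile(profile$cell_id, ratios, "depth",
                    profile$plate_id, profile$sex)
}

#' LOWESS GC-bias correction
#'
#' Fits a locally weighted linear smoother of ratio against bin GC
#' fraction and divides each ratio by the fitted value (floored at
#' `floor_eps` so near-zero fits cannot explode the ratio), then
#' renormalizes. The curve is *estimated* on chromosome-median-flattened
#' ratios: each bin's response is first divided by its chromosome's
#' median ratio, which removes chromosome-scale copy-number structure
#' before the bin-scale covariate is fit — otherwise a whole-chromosome
#' gain inflates the robustness scale of the smoother and drags the curve
#' wherever that chromosome dominates a GC stratum. The fitted curve is
#' then applied to the raw ratios. With fewer than 30 unmasked
#' GC-annotated bins the fit is unstable, so the correction is skipped
#' with a warning (the stage still advances so the pipeline can proceed).
#'
#' @param profile a `ratio_profile` at stage `"depth"`.
#' @param scaffold the matching `bin_scaffold` with `gc` annotated.
#' @param span_fraction LOWESS span (fraction of points per local fit).
#' @param n_iter robustness iterations.
#' @param floor_eps lower floor applied to fitted values.
#' @return a `ratio_profile` at stage `"gc_corrected"`.
#' @export
gc_correct <- function(profile, scaffold, span_fraction = 0.3, n_iter = 3,
                       floor_eps = 0.05) {
  stopifnot(inherits(profile, "ratio_profile"),
            length(profile$ratios) == nrow(scaffold))
  if (profile$stage != "depth")
    stop("gc_correct expects a depth-normalized profile (stage 'depth'), got '",
         profile$stage, "'")
  sel <- which(!scaffold$bad & !is.na(scaffold$gc) & !is.na(profile$ratios))
  ratios <- profile$ratios
  if (length(sel) < 30) {
    warning("fewer than 30 unmasked GC-annotated bins; GC correction skipped")
  } else {
    gc <- scaffold$gc[sel]
    chrom_med <- tapply(ratios[sel], scaffold$chrom[sel], median)
    chrom_med[chrom_med <= 0] <- 1
    flat <- ratios[sel] / chrom_med[scaffold$chrom[sel]]
    fit <- lowess(gc, flat, f = span_fraction, iter = n_iter)
    pred <- approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y
    ratios[sel] <- ratios[sel] / pmax(pred, floor_eps)
    ratios <- renormalize_ratios(ratios, scaffold)
  }
  new_ratio_profile(profile$cell_id, ratios, "gc_corrected",
                    profile$plate_id, profile$sex)
}

#' Build a plate-pooled control profile
#'
#' Cells amplified on the same 96-well plate share a reproducible
#' amplification bias; pooling them gives a per-bin control that cancels
#' it. The control value per bin is a trimmed mean (default 10% each tail)
#' of the cells' GC-corrected ratios, renormalized to mean 1 over unmasked
#' autosomal bins. Trimming guards the control against aneuploid cells.
#' The cell under test is not excluded from its own plate control: with a
#' ~96-cell pool its self-contribution is ~1%.
#'
#' @param cells list of `ratio_profile` objects at stage `"gc_corrected"`,
#'   all from one plate.
#' @param scaffold the matching `bin_scaffold`.
#' @param trim trim fraction per tail for the per-bin mean.
#' @param min_cells minimum number of contributing cells.
#' @param exclude optional character vector of cell ids to leave out.
#' @return a `plate_control`: list with `plate_id`, `values` (per bin,
#'   `NA` at masked bins), `n_cells`.
#' @export
build_plate_control <- function(cells, scaffold, trim = 0.1, min_cells = 8,
                                exclude = NULL) {
  stopifnot(length(cells) > 0)
  plate <- cells[[1]]$plate_id
  stages <- vapply(cells, function(p) p$stage, "")
  if (any(stages != "gc_corrected"))
    stop("plate control requires gc_corrected profiles")
  if (!is.null(exclude))
    cells <- Filter(function(p) !(p$cell_id %in% exclude), cells)
  if (length(cells) < min_cells)
    stop("plate ", plate, ": only ", length(cells),
         " cells after exclusions (minimum ", min_cells, ")")
  mat <- do.call(cbind, lapply(cells, function(p) p$ratios))
  values <- apply(mat, 1, function(v) mean(v, trim = trim))
  values[scaffold$bad] <- NA_real_
  values <- renormalize_ratios(values, scaffold)
  # the control must carry amplification bias (including its level on
  # each chromosome) but never the cells' copy state: on a male plate
  # X/Y sit at ratio ~0.5 and dividing by the raw pool would erase the
  # true sex-chromosome copy number. The pool's expected copy ratio is
  # known from the cells' sexes, so it — and only it — is divided out.
  sexes <- vapply(cells, function(p) p$sex, "")
  exp_x <- mean(ifelse(sexes == "male", 0.5, 1))
  exp_y <- mean(ifelse(sexes == "male", 0.5, 0))
  for (norm in list(list(sel = is_x(scaffold$chrom), level = exp_x),
                    list(sel = is_y(scaffold$chrom), level = exp_y))) {
    idx <- which(norm$sel & !scaffold$bad)
    if (length(idx) && is.finite(norm$level) && norm$level > 0)
      values[idx] <- values[idx] / norm$level
  }
  structure(list(plate_id = plate, values = values, n_cells = length(cells)),
            class = "plate_control")
}

#' Apply plate-control correction
#'
#' Divides a GC-corrected profile by the plate control bin-by-bin and
#' renormalizes. Bins where the control is non-positive are treated as
#' masked for this cell. Applying this to a profile that has not been
#' GC-corrected is an error: the stage order depth -> GC -> control is
#' fixed.
#'
#' @param profile a `ratio_profile` at stage `"gc_corrected"`.
#' @param control a `plate_control` on the same scaffold.
#' @param scaffold the matching `bin_scaffold`.
#' @return a `ratio_profile` at stage `"control_corrected"`.
#' @export
control_correct <- function(profile, control, scaffold) {
  stopifnot(inherits(profile, "ratio_profile"),
            inherits(control, "plate_control"),
            length(profile$ratios) == length(control$values))
  if (profile$stage != "gc_corrected")
    stop("control_correct requires a gc_corrected profile, got stage '",
         profile$stage, "'")
  ratios <- profile$ratios
  ok <- !is.na(control$values) & control$values > 0
  ratios[ok] <- ratios[ok] / control$values[ok]
  ratios[!ok] <- NA_real_
  ratios <- renormalize_ratios(ratios, scaffold)
  new_ratio_profile(profile$cell_id, ratios, "control_corrected",
                    profile$plate_id, profile$sex)
}

#' Run the full normalization for a plate of cells
#'
#' Convenience wrapper: depth-normalizes and GC-corrects every cell, builds
#' the plate control, and control-corrects every cell.
#'
#' @param profiles list of `cell_profile` objects from one plate.
#' @param scaffold the matching `bin_scaffold`.
#' @param lowess_span,lowess_iters,control_trim,control_min_cells tuning
#'   parameters, see [gc_correct()] and [build_plate_control()].
#' @return named list of `ratio_profile` objects at stage
#'   `"control_corrected"`.
#' @export
normalize_plate <- function(profiles, scaffold, lowess_span = 0.3,
                            lowess_iters = 3, control_trim = 0.1,
                            control_min_cells = 8) {
  gc_cells <- lapply(profiles, function(p) {
    gc_correct(depth_normalize(p, scaffold), scaffold,
               span_fraction = lowess_span, n_iter = lowess_iters)
  })
  control <- build_plate_control(gc_cells, scaffold, trim = control_trim,
                                 min_cells = control_min_cells)
  out <- lapply(gc_cells, control_correct, control = control,
                scaffold = scaffold)
  names(out) <- vapply(out, function(p) p$cell_id, "")
  out
}

#' Write / read a ratio matrix
#'
#' Tab-separated matrix of per-bin copy ratios (one row per cell) with the
#' normalization stage recorded in a `#stage` header line, so a profile
#' cannot silently re-enter the pipeline at the wrong stage.
#'
#' @param profiles list of `ratio_profile` objects sharing one stage.
#' @param path file path.
#' @rdname ratio_matrix_io
#' @export
write_ratio_matrix <- function(profiles, path) {
  stopifnot(length(profiles) > 0)
  stages <- unique(vapply(profiles, function(p) p$stage, ""))
  if (length(stages) != 1)
    stop("profiles at mixed stages: ", paste(stages, collapse = ", "))
  mat <- do.call(rbind, lapply(profiles, function(p) p$ratios))
  colnames(mat) <- paste0("bin", seq_len(ncol(mat)))
  df <- data.frame(cell_id = vapply(profiles, function(p) p$cell_id, ""),
                   plate_id = vapply(profiles, function(p)
                     as.character(p$plate_id), ""),
                   sex = vapply(profiles, function(p) p$sex, ""),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#stage\t%s", stages), con)
  utils::write.table(cbind(df, mat), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param scaffold scaffold the matrix must match (bin count checked).
#' @return `read_ratio_matrix`: named list of `ratio_profile` objects.
#' @rdname ratio_matrix_io
#' @export
read_ratio_matrix <- function(path, scaffold) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  stage <- "unknown"
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", lines[h]), "\t")[[1]]
    if (length(kv) == 2 && kv[1] == "stage") stage <- kv[2]
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  bin_cols <- grep("^bin[0-9]+$", names(df))
  if (length(bin_cols) != nrow(scaffold))
    stop("ratio matrix has ", length(bin_cols), " bins but scaffold has ",
         nrow(scaffold))
  profs <- lapply(seq_len(nrow(df)), function(i) {
    new_ratio_profile(df$cell_id[i], as.numeric(df[i, bin_cols]), stage,
                      df$plate_id[i], df$sex[i])
  })
  names(profs) <- df$cell_id
  profs
}
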