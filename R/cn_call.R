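#' Integer copy-number calling
#'
#' Segment mean ratios are mapped to integer copy numbers by optimizing a
#' ploidy scale `D`: the grid value minimizing the bin-weighted squared
#' distance of `ratio * D` to the nearest integers, subject to a diploid
#' anchor (the modal copy number over autosomal bins must be 2). The
#' anchor removes the degenerate large-`D` minima of the integer-fit
#' objective in near-diploid cells; a genuinely non-diploid cell is
#' flagged non-callable rather than silently miscalled. The grid optimum
#' is refined on a 10x finer grid and polished by alternating
#' least-squares (fix the integer assignment, solve for `D` in closed
#' form), which makes the objective exactly 0 on noiseless integer
#' profiles.
#'
#' @name cn_call
NULL

# Weighted integer-fit objective: sum_s w_s * (m_s*D - round(m_s*D))^2,
# evaluated for every D at once (segments x grid matrix).
ploidy_objective_w <- function(m, w, D) {
  M <- outer(m, D)
  as.numeric(crossprod(w, (M - round_half_away(M))^2))
}

# Weighted modal copy number at each D.
modal_cn_w <- function(m, w, D) {
  M <- round_half_away(outer(m, D))
  vapply(seq_along(D), function(k) {
    agg <- tapply(w, M[, k], sum)
    as.numeric(names(agg)[which.max(agg)])
  }, numeric(1))
}

#' Optimize the ploidy scale
#'
#' @param segmented a `segmented_profile` (or a data.frame of segments with
#'   `chrom`, `n_bins`, `mean_ratio`).
#' @param d_min,d_max,d_step search grid for `D` (defaults 1.5-5.5,
#'   step 0.01; refined at step 0.001 around the optimum, then polished).
#' @return list with `D`, `objective` (per-bin mean squared rounding
#'   residual at `D`), `flagged` (TRUE when no `D` satisfies the diploid
#'   anchor).
#' @export
optimize_ploidy_scale <- function(segmented, d_min = 1.5, d_max = 5.5,
                                  d_step = 0.01) {
  segs <- if (inherits(segmented, "segmented_profile")) segmented$segments
          else segmented
  segs <- segs[is_autosome(segs$chrom), , drop = FALSE]
  if (nrow(segs) == 0) stop("no autosomal segments to optimize on")
  m <- segs$mean_ratio        # per-segment mean ratio
  w <- as.numeric(segs$n_bins) # bin-count weights (w_b = 1 per bin)
  n_bins_total <- sum(w)
  r_median <- median(rep(m, w))
  grid <- seq(d_min, d_max, by = d_step)
  obj <- ploidy_objective_w(m, w, grid)
  anchored <- modal_cn_w(m, w, grid) == 2
  if (!any(anchored)) {
    D0 <- grid[which.min(obj)]
    return(list(D = D0, objective = min(obj) / n_bins_total,
                flagged = TRUE))
  }
  cand <- grid[anchored]
  cobj <- obj[anchored]
  best <- cobj <= min(cobj) + 1e-15
  if (sum(best) > 1) { # ties: closest to 2 / median(r)
    target <- 2 / r_median
    D0 <- cand[best][which.min(abs(cand[best] - target))]
  } else D0 <- cand[best]
  # fine grid around the coarse optimum
  fine <- seq(max(d_min, D0 - d_step), min(d_max, D0 + d_step),
              by = d_step / 10)
  fine <- fine[modal_cn_w(m, w, fine) == 2]
  fobj <- ploidy_objective_w(m, w, fine)
  D <- fine[which.min(fobj)]
  # alternating least-squares polish: fix assignment, solve D, repeat
  for (it in 1:20) {
    cn <- round_half_away(m * D)
    D_new <- sum(w * m * cn) / sum(w * m * m)
    if (!is.finite(D_new) || D_new < d_min || D_new > d_max ||
        modal_cn_w(m, w, D_new) != 2) break
    if (abs(D_new - D) < 1e-12) { D <- D_new; break }
    D <- D_new
  }
  list(D = D, objective = ploidy_objective_w(m, w, D) / n_bins_total,
       flagged = FALSE)
}

#' Assign integer copy numbers to segments
#'
#' `cn = round(mean_ratio * D)` per segment, rounding half away from zero
#' (so 2.5 -> 3).
#'
#' @param segmented a `segmented_profile`.
#' @param D ploidy scale from [optimize_ploidy_scale()].
#' @param objective,flagged carried through from the optimizer.
#' @return a `cn_profile`: the segmented profile with a `cn` column plus
#'   `D`, `objective`, `flagged`.
#' @export
assign_integer_cn <- function(segmented, D, objective = NA_real_,
                              flagged = FALSE) {
  stopifnot(inherits(segmented, "segmented_profile"), D > 0)
  segs <- segmented$segments
  segs$cn <- as.integer(round_half_away(segs$mean_ratio * D))
  structure(list(cell_id = segmented$cell_id, plate_id = segmented$plate_id,
                 sex = segmented$sex, segments = segs, D = D,
                 objective = objective, flagged = flagged),
            class = c("cn_profile", "segmented_profile"))
}

#' Call CNA events from an integer copy-number profile
#'
#' The expected copy number is 2 on autosomes; for males it is 1 on both X
#' and Y; for females X is expected at 2 and the Y chromosome is not
#' considered at all. With unknown sex, X (expected 2) and Y (expected 1)
#' deviations are still reported but flagged indeterminate. Adjacent
#' deviant segments with the same copy number are merged before the length
#' filter; only events strictly longer than `min_len_bp` (default 10 Mb of
#' genomic span, masked gaps included) are reported.
#'
#' @param cn_profile a `cn_profile` from [assign_integer_cn()].
#' @param sex `"male"`, `"female"`, or `"unknown"` (defaults to the
#'   profile's recorded sex).
#' @param min_len_bp minimum genomic length; events at or below it are
#'   dropped.
#' @return data.frame of events: `cell_id`, `chrom`, `start_bp`, `end_bp`,
#'   `length_bp`, `direction` (`gain`/`loss`), `cn`, `expected_cn`,
#'   `indeterminate`.
#' @export
call_cna_events <- function(cn_profile, sex = NULL, min_len_bp = 10e6) {
  stopifnot(inherits(cn_profile, "cn_profile"))
  if (is.null(sex)) sex <- cn_profile$sex
  sex <- match.arg(sex, c("male", "female", "unknown"))
  segs <- cn_profile$segments
  if (sex == "female") segs <- segs[!is_y(segs$chrom), , drop = FALSE]
  expected <- ifelse(is_autosome(segs$chrom), 2L,
                     ifelse(is_x(segs$chrom), if (sex == "male") 1L else 2L,
                            1L))
  events <- list()
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    exp_cn <- expected[segs$chrom == ch][1]
    dev <- s$cn != exp_cn
    if (!any(dev)) next
    # merge runs of adjacent deviant segments sharing the same cn
    key <- ifelse(dev, paste0("dev", s$cn), "norm")
    run_id <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    for (g in split(seq_len(nrow(s)), run_id)) {
      if (!dev[g[1]]) next
      cn <- s$cn[g[1]]
      start_bp <- s$start_bp[g[1]]
      end_bp <- s$end_bp[g[length(g)]]
      events[[length(events) + 1]] <- data.frame(
        cell_id = cn_profile$cell_id, chrom = ch,
        start_bp = start_bp, end_bp = end_bp,
        length_bp = end_bp - start_bp,
        direction = if (cn > exp_cn) "gain" else "loss",
        cn = cn, expected_cn = exp_cn,
        indeterminate = sex == "unknown" && !is_autosome(ch),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(cell_id = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric(),
               length_bp = numeric(), direction = character(),
               cn = integer(), expected_cn = integer(),
               indeterminate = logical(), stringsAsFactors = FALSE)
  out[out$length_bp > min_len_bp, , drop = FALSE]
}

#' Write CNA events as BED-like TSV
#'
#' @param events data.frame from [call_cna_events()].
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
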