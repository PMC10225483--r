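# Independent oracles and small fixture builders used across the suite.
# The oracles are deliberately naive (double loops, direct formulas) so
# they share no code path with the implementation they check.

# Exhaustive O(n^2) scan for the maximal circular-arc t statistic.
# Enumerates boundary pairs 1 <= i < j <= n in order, arc = x[(i+1):j],
# strict improvement so ties resolve to the smallest (i, j).
oracle_max_t <- function(x) {
  n <- length(x)
  best <- list(i = 0, j = 0, T = 0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      arc <- x[(i + 1):j]
      rest <- x[-((i + 1):j)]
      m_in <- mean(arc)
      m_out <- mean(rest)
      ss <- sum((arc - m_in)^2) + sum((rest - m_out)^2)
      d <- abs(m_in - m_out)
      denom <- sqrt(ss / (n - 2) * (1 / length(arc) + 1 / length(rest)))
      T_ij <- if (denom > 0) d / denom
              else if (d > 1e-12 * (1 + max(abs(x)))) Inf else 0
      if (T_ij > best$T) best <- list(i = i, j = j, T = T_ij)
    }
  }
  best
}

# Exhaustive search over changepoint subsets under the same RSS criterion
# as prune_changepoints: the largest-removal subset whose RSS stays within
# (1 + slack) * RSS(full set). Feasible for few changepoints only.
oracle_prune <- function(y, cps, slack) {
  rss_of <- function(keep) {
    bounds <- c(0, sort(keep), length(y))
    rss <- 0
    for (k in seq_len(length(bounds) - 1)) {
      seg <- y[(bounds[k] + 1):bounds[k + 1]]
      rss <- rss + sum((seg - mean(seg))^2)
    }
    rss
  }
  limit <- (1 + slack) * rss_of(cps)
  best <- cps
  for (m in seq_along(cps)) {
    combs <- utils::combn(cps, length(cps) - m, simplify = FALSE)
    ok <- Filter(function(keep) rss_of(keep) <= limit, combs)
    if (length(ok)) best <- ok[[1]]
  }
  if (rss_of(integer(0)) <= limit) best <- integer(0)
  best
}

# Minimal single-chromosome scaffold: n_bins fixed-width bins with flat GC.
toy_scaffold <- function(n_bins, bin_bp = 1e6, chrom = "chr1", gc = 0.41) {
  sc <- build_uniform_scaffold(setNames(n_bins * bin_bp, chrom), bin_bp)
  sc$gc <- gc
  sc
}

# Wrap a ratio vector as a profile at a chosen stage.
as_ratio_profile <- function(ratios, cell_id = "cell",
                             stage = "control_corrected") {
  mosaicCNA:::new_ratio_profile(cell_id, ratios, stage)
}

# Build a cn_profile directly from a segment table (for event-rule tests).
as_cn_profile <- function(segments, cell_id = "cell", sex = "female",
                          D = 2) {
  seg <- structure(list(cell_id = cell_id, plate_id = NA_character_,
                        sex = sex, segments = segments,
                        params = cbs_params()),
                   class = "segmented_profile")
  assign_integer_cn(seg, D)
}

# Recover the mosaic fraction of a known whole-chromosome region from
# round-2 TE segments, bypassing the event-reporting floor.
te_recover_fraction <- function(segments, chrom) {
  s1 <- segments[segments$chrom == chrom, , drop = FALSE]
  other <- segments[mosaicCNA:::is_autosome(segments$chrom) &
                      segments$chrom != chrom, , drop = FALSE]
  base <- mosaicCNA:::weighted_median(other$mean_ratio, other$n_bins)
  m <- sum(s1$mean_ratio * s1$n_bins) / sum(s1$n_bins) / base
  estimate_mosaic_fraction(m)$fraction
}

# Segmented profile from segment-level means and bin counts.
make_seg_profile <- function(means, n_bins, chrom = "chr1",
                             bin_bp = 1e6, cell_id = "cell",
                             sex = "female") {
  ends <- cumsum(n_bins) * bin_bp
  starts <- c(0, head(ends, -1))
  segs <- data.frame(chrom = chrom, start_bin = c(1, head(cumsum(n_bins), -1) + 1),
                     end_bin = cumsum(n_bins) + 1, n_bins = n_bins,
                     mean_ratio = means, start_bp = starts, end_bp = ends,
                     flagged = FALSE, stringsAsFactors = FALSE)
  structure(list(cell_id = cell_id, plate_id = NA_character_, sex = sex,
                 segments = segs, params = cbs_params()),
            class = "segmented_profile")
}

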