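test_that("max-arc statistic matches the exhaustive oracle", {
  expect_equal(cbs_max_statistic(rep(1, 10)), list(i = 0, j = 0, T = 0))

  # perfect step: the second block is the maximal arc, infinite statistic
  step <- c(rep(0, 10), rep(1, 10))
  res <- cbs_max_statistic(step)
  expect_equal(res$i, 10)
  expect_equal(res$j, 20)
  expect_equal(res$T, Inf)

  set.seed(101)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    x <- rnorm(n)
    if (rep %% 3 == 0) x[seq_len(n %/% 2)] <- x[seq_len(n %/% 2)] + 2
    got <- cbs_max_statistic(x)
    want <- oracle_max_t(x)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$T, want$T, tolerance = 1e-9)
  }
})

test_that("hybrid significance: trivial, extreme and null cases", {
  params <- cbs_params()
  x <- rnorm(100)
  expect_equal(arc_significance(x, 0, 0, 0, params)$p_value, 1)

  # 20-sigma step on n = 100 is significant via the analytic stage
  set.seed(7)
  y <- c(rnorm(50), rnorm(50, 20))
  res <- cbs_max_statistic(y)
  sig <- arc_significance(y, res$i, res$j, res$T, params)
  expect_true(sig$significant)
  expect_equal(sig$stage, "analytic")
  expect_lt(sig$p_value, 1e-10)

  # pure noise: never significant at alpha = 1e-10 across replicates
  set.seed(8)
  n_sig <- 0
  for (rep in 1:100) {
    z <- rnorm(100)
    r <- cbs_max_statistic(z)
    if (arc_significance(z, r$i, r$j, r$T, params)$significant)
      n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 1)
})

test_that("analytic tail bound is monotone and calibrated at moderate T", {
  expect_equal(cbs_analytic_pvalue(Inf, 100), 0)
  expect_equal(cbs_analytic_pvalue(0, 100), 1)
  p <- vapply(c(4, 6, 8, 10), cbs_analytic_pvalue, numeric(1), n = 100)
  expect_true(all(diff(p) < 0))
  # union bound: permutation p-hat never exceeds it systematically
  set.seed(99)
  x <- rnorm(60)
  r <- cbs_max_statistic(x)
  perm <- mosaicCNA:::cpp_perm_exceed(x, r$T, 2000, 2000)
  p_hat <- (1 + perm$exceed) / (perm$n_done + 1)
  expect_lte(p_hat, min(1, cbs_analytic_pvalue(r$T, 60)) + 0.1)
})

test_that("segmentation recovers planted blocks and stays quiet on noise", {
  set.seed(55)
  sc <- toy_scaffold(100)

  # flat diploid chromosome: one segment
  flat <- as_ratio_profile(pmax(rnorm(100, 1, 0.1), 0.01))
  seg_flat <- segment_profile(flat, sc)
  expect_equal(nrow(seg_flat$segments), 1)

  # one 20-bin CN=3 block
  r <- pmax(rnorm(100, 1, 0.1), 0.01)
  r[41:60] <- rnorm(20, 1.5, 0.1)
  seg <- segment_profile(as_ratio_profile(r), sc)
  expect_equal(nrow(seg$segments), 3)
  mid <- seg$segments[2, ]
  expect_lte(abs(mid$start_bin - 41), 1)
  expect_lte(abs(mid$end_bin - 61), 1)
  expect_lt(abs(mid$mean_ratio - 1.5), 0.05)

  # whole-chromosome gain: one segment at the gained level
  gain <- as_ratio_profile(rep(1.5, 100))
  seg_gain <- segment_profile(gain, sc)
  expect_equal(nrow(seg_gain$segments), 1)
  expect_equal(seg_gain$segments$mean_ratio, 1.5)
})

test_that("chromosomes with too few usable bins become flagged segments", {
  sc <- toy_scaffold(3)
  seg <- segment_profile(as_ratio_profile(c(1, 1.4, 0.8)), sc)
  expect_equal(nrow(seg$segments), 1)
  expect_true(seg$segments$flagged)
})

test_that("pruning undoes spurious changepoints and matches brute force", {
  # two segments 10 sigma apart: nothing pruned
  y <- c(rnorm(10, 0, 0.1), rnorm(10, 1, 0.1))
  expect_equal(prune_changepoints(y, 10, 0.05), 10)

  # equal-mean split: pruned away
  set.seed(3)
  z <- rnorm(20)
  expect_length(prune_changepoints(z, 10, 0.05), 0)

  # marginal middle boundary: greedy matches exhaustive subset search
  set.seed(13)
  for (rep in 1:20) {
    y3 <- c(rnorm(6, 0), rnorm(6, runif(1, 0, 1)), rnorm(6, 2))
    cps <- c(6, 12)
    got <- prune_changepoints(y3, cps, 0.05)
    want <- oracle_prune(y3, cps, 0.05)
    expect_equal(got, want)
  }
})

test_that("segments reconstruct the chromosome exactly", {
  set.seed(77)
  sc <- toy_scaffold(80)
  sc$bad[c(5, 40)] <- TRUE
  r <- pmax(rnorm(80, 1, 0.1), 0.01)
  r[30:50] <- r[30:50] + 1
  prof <- as_ratio_profile(r)
  prof$ratios[sc$bad] <- NA
  seg <- segment_profile(prof, sc)
  s <- seg$segments
  # usable bins tile exactly once
  expect_equal(sum(s$n_bins), 78)
  # weighted mean of segment means equals the chromosome mean
  expect_equal(sum(s$mean_ratio * s$n_bins) / sum(s$n_bins),
               mean(prof$ratios[!sc$bad]), tolerance = 1e-9)
  # genomic spans nest inside the chromosome and are ordered
  expect_true(all(diff(s$start_bp) > 0))
})

test_that("lowering alpha never increases the changepoint count", {
  set.seed(21)
  sc <- toy_scaffold(100)
  r <- pmax(rnorm(100, 1, 0.15), 0.01)
  r[21:35] <- r[21:35] + 0.45
  r[61:80] <- r[61:80] - 0.35
  prof <- as_ratio_profile(r)
  counts <- vapply(c(1e-3, 1e-6, 1e-10), function(a) {
    set.seed(500)
    nrow(segment_profile(prof, sc, cbs_params(alpha = a))$segments)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is deterministic under a fixed seed", {
  sc <- toy_scaffold(60)
  set.seed(303)
  r <- pmax(rnorm(60, 1, 0.2), 0.01)
  set.seed(42)
  a <- segment_profile(as_ratio_profile(r), sc)
  set.seed(42)
  b <- segment_profile(as_ratio_profile(r), sc)
  expect_identical(a$segments, b$segments)
})

test_that("SEG output carries one row per segment", {
  sc <- toy_scaffold(50)
  seg <- segment_profile(as_ratio_profile(rep(1, 50)), sc)
  path <- tempfile(fileext = ".seg")
  write_seg(list(seg), path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(seg$segments))
  expect_named(tab, c("sample", "chrom", "start", "end", "n_bins", "mean"))
})
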