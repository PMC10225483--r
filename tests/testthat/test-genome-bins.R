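test_that("uniform scaffolds tile chromosomes exactly", {
  sc <- build_uniform_scaffold(c(chr1 = 10e6), 1e6)
  expect_equal(nrow(sc), 10)
  expect_true(all(sc$end - sc$start == 1e6))

  sc2 <- build_uniform_scaffold(c(chrA = 2.5e6), 1e6)
  expect_equal(sc2$start, c(0, 1e6))
  expect_equal(sc2$end, c(1e6, 2.5e6))

  # genome-scale bin count equals the per-chromosome floor sum
  lens <- setNames(round(seq(250e6, 45e6, length.out = 24)), paste0("c", 1:24))
  lens <- round(lens * 3.095e9 / sum(lens))
  sc3 <- build_uniform_scaffold(lens, 1.1e6)
  expect_equal(nrow(sc3), sum(floor(lens / 1.1e6)))
  expect_equal(sum(sc3$end - sc3$start), sum(lens))

  expect_error(build_uniform_scaffold(c(chr1 = 10e6, tiny = 5e5), 1e6),
               "tiny")
})

test_that("weighted scaffold equalizes cumulative weight", {
  win <- data.frame(chrom = "chr1", start = seq(0, 9e6, 1e6),
                    end = seq(1e6, 10e6, 1e6), weight = 1)
  sc_w <- build_weighted_scaffold(win, 10)
  sc_u <- build_uniform_scaffold(c(chr1 = 10e6), 1e6)
  expect_equal(sc_w$start, sc_u$start)
  expect_equal(sc_w$end, sc_u$end)

  # doubled density on the left half -> left bins ~half the width
  win2 <- win
  win2$weight <- rep(c(2, 1), each = 5)
  sc2 <- build_weighted_scaffold(win2, 6)
  widths <- sc2$end - sc2$start
  left <- sc2$end <= 5e6
  expect_true(mean(widths[left]) < 0.6 * mean(widths[!left]))
  # equal weight per bin (continuous interpolation, integer snapping only)
  expect_lt(max(sc2$weight) / min(sc2$weight), 1.01)

  # zero-weight telomeric window absorbed, never a zero-weight bin
  win3 <- win
  win3$weight[1] <- 0
  sc3 <- build_weighted_scaffold(win3, 5)
  expect_true(all(sc3$weight > 0))
  expect_equal(sc3$start[1], 0)

  expect_error(build_weighted_scaffold(win, 11), "positive-weight")
})

test_that("weighted scaffold beats uniform tiling on weight balance", {
  set.seed(41)
  for (rep in 1:5) {
    n_win <- sample(50:200, 1)
    win <- data.frame(chrom = "chr1",
                      start = seq(0, (n_win - 1) * 1e6, 1e6),
                      end = seq(1e6, n_win * 1e6, 1e6),
                      weight = runif(n_win, 0.2, 3))
    n_bins <- sample(5:20, 1)
    sc <- build_weighted_scaffold(win, n_bins)
    expect_equal(sum(sc$end - sc$start), n_win * 1e6)
    # per-bin weight spread <= that of the uniform-width tiling
    cw <- function(pos) mosaicCNA:::cum_weight_at(win, pos)
    spread <- function(edges) {
      w <- diff(cw(edges))
      max(w) / min(w)
    }
    uniform_edges <- seq(0, n_win * 1e6, length.out = n_bins + 1)
    expect_lte(spread(c(sc$start, sc$end[nrow(sc)])),
               spread(uniform_edges) + 1e-9)
  }
})

test_that("GC annotation from FASTA handles mixed and all-N bins", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1",
               paste0(strrep("ATGC", 25),   # bin 1: gc 0.5
                      strrep("G", 100),     # bin 2: gc 1.0
                      strrep("N", 100))),   # bin 3: all N
             fa)
  sc <- build_uniform_scaffold(c(chr1 = 300), 100)
  sc <- annotate_gc(sc, fa)
  expect_equal(sc$gc[1:2], c(0.5, 1.0))
  expect_true(is.na(sc$gc[3]))
  expect_true(sc$bad[3])

  expect_error(annotate_gc(build_uniform_scaffold(c(chr2 = 300), 100), fa),
               "chr2")
})

test_that("GC annotation from a window table averages by overlap", {
  sc <- build_uniform_scaffold(c(chr1 = 2e6), 1e6)
  tab <- data.frame(chrom = "chr1",
                    start = c(0, 0.5e6, 1e6),
                    end = c(0.5e6, 1e6, 2e6),
                    gc = c(0.3, 0.5, 0.6))
  sc <- annotate_gc(sc, tab)
  expect_equal(sc$gc, c(0.4, 0.6))
})

test_that("bad-bin masking follows the 50% overlap rule", {
  sc <- build_uniform_scaffold(c(chr1 = 5e6), 1e6)
  expect_identical(mask_bad_bins(sc, NULL), sc)
  expect_identical(mask_bad_bins(sc, data.frame(chrom = character(),
                                                start = numeric(),
                                                end = numeric())), sc)
  # one full bin
  m1 <- mask_bad_bins(sc, data.frame(chrom = "chr1", start = 1e6, end = 2e6))
  expect_equal(which(m1$bad), 2L)
  # 40% of a bin: below threshold
  m2 <- mask_bad_bins(sc, data.frame(chrom = "chr1", start = 0, end = 0.4e6))
  expect_false(any(m2$bad))
  # exactly 50%: flagged
  m3 <- mask_bad_bins(sc, data.frame(chrom = "chr1", start = 0, end = 0.5e6))
  expect_true(m3$bad[1])
  # two intervals jointly covering 60% are coalesced per-bin
  m4 <- mask_bad_bins(sc, data.frame(chrom = "chr1",
                                     start = c(0, 0.4e6),
                                     end = c(0.3e6, 0.7e6)))
  expect_true(m4$bad[1])
})

test_that("scaffold TSV round-trips losslessly and rejects bad files", {
  sc <- build_uniform_scaffold(c(chr1 = 5e6, chr2 = 3e6), 1e6)
  sc$gc <- round(runif(nrow(sc)), 3)
  sc$bad[2] <- TRUE
  path <- tempfile(fileext = ".tsv")
  write_scaffold(sc, path)
  back <- read_scaffold(path)
  expect_equal(as.data.frame(back), as.data.frame(sc))
  expect_equal(attr(back, "chrom_lengths"), attr(sc, "chrom_lengths"))
  expect_equal(attr(back, "mode"), attr(sc, "mode"))

  # overlapping bins rejected on read
  lines <- readLines(path)
  bad <- sub("^chr1\t1e\\+06", "chr1\t500000", lines)
  bad_path <- tempfile()
  writeLines(bad, bad_path)
  expect_error(read_scaffold(bad_path))

  # 1-based dialect: starts shift down by one
  one_based <- sc
  one_based$start <- one_based$start + 1
  p2 <- tempfile()
  utils::write.table(cbind(as.data.frame(one_based)), p2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  back2 <- read_scaffold(p2, one_based = TRUE)
  expect_equal(back2$start, sc$start)
})

test_that("coverage conservation holds for generated scaffolds", {
  set.seed(5)
  for (rep in 1:3) {
    lens <- setNames(sample(5:40, 4) * 1e6, paste0("chr", 1:4))
    sc <- build_uniform_scaffold(lens, 1e6)
    expect_equal(sum(sc$end - sc$start), sum(lens))
  }
})
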