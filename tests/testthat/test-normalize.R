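test_that("depth normalization divides by the unmasked autosomal mean", {
  sc <- toy_scaffold(4)
  p <- mosaicCNA:::new_cell_profile("c", c(2, 2, 2, 2), 8)
  expect_equal(depth_normalize(p, sc)$ratios, rep(1, 4))

  p2 <- mosaicCNA:::new_cell_profile("c", c(4, 0, 4, 0), 8)
  expect_equal(depth_normalize(p2, sc)$ratios, c(2, 0, 2, 0))

  set.seed(1)
  p3 <- mosaicCNA:::new_cell_profile("c", rpois(4, 30), 200)
  expect_equal(mean(depth_normalize(p3, sc)$ratios), 1)

  p0 <- mosaicCNA:::new_cell_profile("c", c(0, 0, 0, 0), 0)
  expect_error(depth_normalize(p0, sc), "unusable")
})

test_that("masked bins carry NA ratios and are excluded from the mean", {
  sc <- toy_scaffold(4)
  sc$bad[1] <- TRUE
  p <- mosaicCNA:::new_cell_profile("c", c(100, 2, 2, 2), 106)
  r <- depth_normalize(p, sc)
  expect_true(is.na(r$ratios[1]))
  expect_equal(r$ratios[2:4], rep(1, 3))
})

test_that("GC correction removes an injected monotone bias", {
  set.seed(31)
  n <- 1000
  sc <- toy_scaffold(n)
  sc$gc <- runif(n, 0.3, 0.6)
  base <- pmax(rnorm(n, 1, 0.1), 0.05)

  # flat trend: correction is nearly a no-op
  flat <- as_ratio_profile(base / mean(base), stage = "depth")
  out <- gc_correct(flat, sc)
  expect_lt(max(abs(out$ratios - flat$ratios / mean(flat$ratios))), 0.05)

  # multiplicative bias 0.5 + gc is flattened
  biased <- base * (0.5 + sc$gc)
  rp <- as_ratio_profile(biased / mean(biased), stage = "depth")
  corr <- gc_correct(rp, sc)
  rho <- cor(corr$ratios, sc$gc, method = "spearman")
  expect_lt(abs(rho), 0.05)

  # constant profile unchanged
  const <- as_ratio_profile(rep(1, n), stage = "depth")
  expect_equal(gc_correct(const, sc)$ratios, rep(1, n))
})

test_that("GC correction is skipped with a warning when bins are scarce", {
  sc <- toy_scaffold(10)
  rp <- as_ratio_profile(rep(1, 10), stage = "depth")
  expect_warning(out <- gc_correct(rp, sc), "skipped")
  expect_equal(out$stage, "gc_corrected")
})

test_that("plate control is a trimmed mean robust to outlier cells", {
  set.seed(8)
  sc <- toy_scaffold(50)
  make_cell <- function(id, spike = FALSE) {
    r <- rep(1, 50)
    if (spike) r[25] <- 10
    as_ratio_profile(r / mean(r), cell_id = id, stage = "gc_corrected")
  }
  cells <- c(lapply(1:19, function(k) make_cell(paste0("c", k))),
             list(make_cell("outlier", spike = TRUE)))
  ctrl <- build_plate_control(cells, sc)
  expect_equal(ctrl$n_cells, 20)
  expect_lt(abs(ctrl$values[25] - 1), 0.05)

  # identical cells: control equals each cell
  same <- lapply(1:10, function(k) make_cell(paste0("s", k)))
  ctrl2 <- build_plate_control(same, sc)
  expect_equal(ctrl2$values, same[[1]]$ratios)

  # exclusions below the minimum are rejected
  expect_error(build_plate_control(same, sc,
                                   exclude = paste0("s", 1:5)),
               "minimum")
  # wrong stage rejected
  bad <- lapply(same, function(p) { p$stage <- "depth"; p })
  expect_error(build_plate_control(bad, sc), "gc_corrected")
})

test_that("control correction cancels shared bias but keeps private CNAs", {
  set.seed(12)
  n <- 200
  sc <- toy_scaffold(n)
  wave <- exp(rnorm(n, 0, 0.3))  # shared lognormal bias
  cells <- lapply(1:12, function(k) {
    noisy <- wave * exp(rnorm(n, 0, 0.05))
    as_ratio_profile(noisy / mean(noisy), cell_id = paste0("c", k),
                     stage = "gc_corrected")
  })
  ctrl <- build_plate_control(cells, sc)
  corrected <- control_correct(cells[[1]], ctrl, sc)
  expect_lt(sd(corrected$ratios), 0.5 * sd(cells[[1]]$ratios))

  # control of all ones is the identity
  ones <- ctrl
  ones$values <- rep(1, n)
  ident <- control_correct(cells[[1]], ones, sc)
  expect_equal(ident$ratios, cells[[1]]$ratios / mean(cells[[1]]$ratios))

  # a cell-private CNA (ratio 1.5 on bins 50-99) survives correction
  cna <- wave
  cna[50:99] <- cna[50:99] * 1.5
  cna_cell <- as_ratio_profile(cna / mean(cna), cell_id = "cna",
                               stage = "gc_corrected")
  out <- control_correct(cna_cell, ctrl, sc)
  contrast <- mean(out$ratios[50:99]) / mean(out$ratios[-(50:99)])
  expect_lt(abs(contrast - 1.5), 0.075)
})

test_that("the stage order depth -> GC -> control is enforced", {
  sc <- toy_scaffold(40)
  rp <- as_ratio_profile(rep(1, 40), stage = "depth")
  ctrl <- structure(list(plate_id = "p", values = rep(1, 40), n_cells = 10),
                    class = "plate_control")
  expect_error(control_correct(rp, ctrl, sc), "gc_corrected")
  gc_done <- as_ratio_profile(rep(1, 40), stage = "gc_corrected")
  expect_error(gc_correct(gc_done, sc), "depth")
  expect_silent(control_correct(gc_done, ctrl, sc))
})

test_that("renormalization is idempotent", {
  set.seed(2)
  sc <- toy_scaffold(30)
  r <- runif(30, 0.5, 2)
  once <- mosaicCNA:::renormalize_ratios(r, sc)
  expect_equal(mosaicCNA:::renormalize_ratios(once, sc), once)
  expect_equal(mean(once), 1)
})

test_that("ratio matrices round-trip with their stage tag", {
  set.seed(44)
  sc <- toy_scaffold(12)
  profs <- lapply(1:3, function(k) {
    as_ratio_profile(runif(12, 0.5, 2), cell_id = paste0("r", k),
                     stage = "gc_corrected")
  })
  path <- tempfile(fileext = ".tsv")
  write_ratio_matrix(profs, path)
  back <- read_ratio_matrix(path, sc)
  expect_equal(back$r2$ratios, profs[[2]]$ratios)
  expect_equal(back$r1$stage, "gc_corrected")
  expect_error(read_ratio_matrix(path, toy_scaffold(11)), "scaffold")
  mixed <- profs
  mixed[[2]]$stage <- "depth"
  expect_error(write_ratio_matrix(mixed, tempfile()), "mixed")
})
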