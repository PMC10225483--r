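#' Synthetic MALBAC-style data generator
#'
#' Generates per-bin read counts with the statistical structure the
#' analysis assumes: a GC-dependent efficiency, a smooth plate-shared
#' amplification field (MALBAC coverage waves are largely reproducible
#' across cells of a plate — the premise of the pooled-plate control), a
#' smaller cell-private field of the same family, and overdispersed count
#' noise. The expected count in bin `b` of a cell is
#' `lambda_b = R * w_b * (cn_b / 2) * g(gc_b) * A_b * P_b`,
#' where `R` scales the total to the target read count, `w_b` is the bin
#' weight, `cn_b` the true copy number, `g` the GC-bias curve, `A_b` the
#' plate-shared and `P_b` the cell-private exponentiated AR(1) Gaussian
#' field. Every draw is recorded in a truth table so downstream stages can
#' be tested against known events.
#'
#' @name synthetic_data
NULL

#' Default synthetic genome
#'
#' Six autosomes with human-like lengths (240 down to 80 Mb), a 120 Mb X
#' and a 40 Mb Y: small enough to keep simulations fast, large enough that
#' chromosome-scale events, the >10 Mb rule and sex-chromosome handling
#' are all exercised at realistic chromosome/event size ratios.
#'
#' @return named numeric vector of chromosome lengths in bp.
#' @export
sim_chrom_lengths <- function() {
  c(chr1 = 240e6, chr2 = 200e6, chr3 = 160e6, chr4 = 120e6, chr5 = 100e6,
    chr6 = 80e6, chrX = 120e6, chrY = 40e6)
}

#' Simulation configuration
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin_bp target bin width (bp).
#' @param reads_per_cell mean usable reads per cell.
#' @param reads_cv_log sd of the per-cell log-normal library-size spread.
#' @param gc_bias_coef length-2 coefficients `(c1, c2)` of the GC
#'   efficiency `g(gc) = exp(c1 * (gc - 0.4) + c2 * (gc - 0.4)^2)`.
#' @param wga_sigma_shared log-sd of the plate-shared amplification field.
#' @param wga_sigma_private log-sd of the cell-private field; smaller than
#'   the shared one because MALBAC waves are largely reproducible within a
#'   plate.
#' @param wga_corr_len AR(1) autocorrelation length of the shared field,
#'   in bins (the smooth locus-specific amplification waves).
#' @param private_corr_len autocorrelation length of the cell-private
#'   field, in bins; short by construction — the long-range wave component
#'   of MALBAC bias is reproducible across cells (which is exactly why a
#'   pooled plate control can remove it), so what remains private is
#'   near-local amplification stochasticity.
#' @param count_model `"negative_binomial"` (default) or `"poisson"`.
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @param te_sigma_shared log-sd of the batch-shared amplification wave of
#'   bulk TE CNV-seq libraries; much smaller than the MALBAC single-cell
#'   field because bulk low-pass libraries start from many genome copies,
#'   and bounded above by the two-round design itself: pooling round-1
#'   event-free samples only works if residual shared bias stays below the
#'   mosaic reporting floor.
#' @param te_n_cells number of cells in a TE biopsy; the biopsy's private
#'   amplification field is the average over this many cell-level fields.
#' @param plate_size cells per plate.
#' @param bad_fraction fraction of bins flagged bad on the synthetic
#'   scaffold.
#' @param gc_sd spread of the synthetic per-bin GC track around 0.41.
#' @param gc_corr_len autocorrelation length of the GC track in bins;
#'   short, so that every GC stratum samples bins from all chromosomes
#'   (real Mb-scale GC fluctuates bin to bin) — a chromosome-collinear GC
#'   track would confound the LOWESS correction with true CNAs.
#' @param seed seed recorded in the config (callers still control the RNG
#'   stream with `set.seed`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = sim_chrom_lengths(), bin_bp = 1e6,
                       reads_per_cell = 1e6, reads_cv_log = 0.2,
                       gc_bias_coef = c(0.3, -2),
                       wga_sigma_shared = 0.25, wga_sigma_private = 0.08,
                       wga_corr_len = 10, private_corr_len = 2,
                       count_model = "negative_binomial",
                       nb_size = 20, te_sigma_shared = 0.04,
                       te_n_cells = 10, plate_size = 96,
                       bad_fraction = 0.02, gc_sd = 0.05, gc_corr_len = 2,
                       seed = 1L) {
  count_model <- match.arg(count_model, c("negative_binomial", "poisson"))
  stopifnot(wga_sigma_shared >= 0, wga_sigma_private >= 0,
            wga_corr_len >= 1, nb_size > 0, !is.null(seed))
  structure(list(chrom_lengths = chrom_lengths, bin_bp = bin_bp,
                 reads_per_cell = reads_per_cell,
                 reads_cv_log = reads_cv_log, gc_bias_coef = gc_bias_coef,
                 wga_sigma_shared = wga_sigma_shared,
                 wga_sigma_private = wga_sigma_private,
                 wga_corr_len = wga_corr_len,
                 private_corr_len = private_corr_len,
                 count_model = count_model,
                 nb_size = nb_size, te_sigma_shared = te_sigma_shared,
                 te_n_cells = te_n_cells, plate_size = plate_size,
                 bad_fraction = bad_fraction, gc_sd = gc_sd,
                 gc_corr_len = gc_corr_len, seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the synthetic scaffold for a configuration
#'
#' Fixed-width bins over the configured genome with a synthetic GC track
#' (AR(1) around 0.42, squashed smoothly into (0.30, 0.54) by a tanh so
#' the distribution has no atoms — a hard clamp would pile bins of one
#' chromosome onto a single GC value and distort the LOWESS fit) and a
#' random `bad_fraction` of bins masked. Draws from the current RNG
#' stream.
#'
#' @param config a [sim_config()].
#' @return a `bin_scaffold`.
#' @export
sim_scaffold <- function(config) {
  sc <- build_uniform_scaffold(config$chrom_lengths, config$bin_bp,
                               genome_id = "synthetic_genome",
                               mode = "single_cell")
  idx_by_chrom <- scaffold_chrom_index(sc)
  gc <- numeric(nrow(sc))
  for (ch in names(idx_by_chrom)) {
    n <- length(idx_by_chrom[[ch]])
    gc[idx_by_chrom[[ch]]] <- ar1_field(n, config$gc_sd,
                                        config$gc_corr_len)
  }
  sc$gc <- 0.42 + 0.12 * tanh(gc / 0.12)
  if (config$bad_fraction > 0) {
    n_bad <- round(config$bad_fraction * nrow(sc))
    if (n_bad > 0) sc$bad[sample(nrow(sc), n_bad)] <- TRUE
  }
  sc
}

# Stationary AR(1) Gaussian field: sd sigma, autocorrelation length in bins.
ar1_field <- function(n, sigma, corr_len) {
  if (sigma <= 0 || n == 0) return(numeric(n))
  rho <- exp(-1 / corr_len)
  z <- numeric(n)
  z[1] <- rnorm(1, 0, sigma)
  if (n > 1)
    for (b in 2:n) z[b] <- rho * z[b - 1] + rnorm(1, 0, sigma * sqrt(1 - rho^2))
  z
}

# Exponentiated AR(1) field with unit mean, drawn per chromosome.
wga_field <- function(scaffold, sigma, corr_len) {
  out <- numeric(nrow(scaffold))
  idx_by_chrom <- scaffold_chrom_index(scaffold)
  for (ch in names(idx_by_chrom)) {
    idx <- idx_by_chrom[[ch]]
    out[idx] <- exp(ar1_field(length(idx), sigma, corr_len) - sigma^2 / 2)
  }
  out
}

gc_efficiency <- function(gc, coef) {
  x <- gc - 0.4
  exp(coef[1] * x + coef[2] * x^2)
}

#' True copy number per bin for a karyotype
#'
#' @param scaffold a `bin_scaffold`.
#' @param events data.frame with `chrom`, `start_bp`, `end_bp`, `cn`
#'   (possibly empty) — a bin takes an event's `cn` when the event covers
#'   its midpoint.
#' @param sex `"male"` (X=1, Y=1), `"female"` (X=2, Y=0), or `"unknown"`
#'   (treated as female without Y signal).
#' @return integer vector of per-bin copy numbers.
#' @export
karyotype_cn <- function(scaffold, events = NULL, sex = "female") {
  cn <- rep(2L, nrow(scaffold))
  if (sex == "male") {
    cn[is_x(scaffold$chrom)] <- 1L
    cn[is_y(scaffold$chrom)] <- 1L
  } else {
    cn[is_y(scaffold$chrom)] <- 0L
  }
  if (!is.null(events) && nrow(events) > 0) {
    mid <- (scaffold$start + scaffold$end) / 2
    for (e in seq_len(nrow(events))) {
      hit <- scaffold$chrom == events$chrom[e] & mid >= events$start_bp[e] &
        mid < events$end_bp[e]
      cn[hit] <- events$cn[e]
    }
  }
  cn
}

#' Simulate one cell
#'
#' @param scaffold a `bin_scaffold` (from [sim_scaffold()]).
#' @param config a [sim_config()].
#' @param karyotype event data.frame (see [karyotype_cn()]), `NULL` for
#'   euploid.
#' @param shared_field plate-shared amplification field (from
#'   [wga_field()]); drawn fresh when `NULL`.
#' @param cell_id,plate_id,sex metadata.
#' @param reads target usable reads (default: log-normal around
#'   `config$reads_per_cell`).
#' @param lambda_override expectation vector to use instead of the cell's
#'   own model (used for "average cells").
#' @return list with `profile` (a `cell_profile`), `truth` (one-row
#'   data.frame), and `lambda` (the expectation used).
#' @export
simulate_cell <- function(scaffold, config, karyotype = NULL,
                          shared_field = NULL, cell_id = "cell",
                          plate_id = "plate1", sex = "female",
                          reads = NULL, lambda_override = NULL) {
  if (is.null(shared_field))
    shared_field <- wga_field(scaffold, config$wga_sigma_shared,
                              config$wga_corr_len)
  if (is.null(reads))
    reads <- config$reads_per_cell * rlnorm(1, -config$reads_cv_log^2 / 2,
                                            config$reads_cv_log)
  if (is.null(lambda_override)) {
    cn <- karyotype_cn(scaffold, karyotype, sex)
    private <- wga_field(scaffold, config$wga_sigma_private,
                         config$private_corr_len)
    raw <- scaffold$weight * (cn / 2) *
      gc_efficiency(scaffold$gc, config$gc_bias_coef) *
      shared_field * private
    lambda <- reads * raw / sum(raw)
  } else {
    lambda <- lambda_override * reads / sum(lambda_override)
    cn <- karyotype_cn(scaffold, karyotype, sex)
  }
  counts <- if (config$count_model == "poisson") rpois(length(lambda), lambda)
            else rnbinom(length(lambda), mu = lambda, size = config$nb_size)
  profile <- new_cell_profile(cell_id, counts,
                              total_usable_reads = sum(counts),
                              plate_id = plate_id, sex = sex)
  n_ev <- if (is.null(karyotype)) 0L else nrow(karyotype)
  truth <- data.frame(cell_id = cell_id, plate_id = plate_id, sex = sex,
                      n_events = n_ev,
                      events = if (n_ev) paste(sprintf(
                        "%s:%.0f-%.0f=%d", karyotype$chrom,
                        karyotype$start_bp, karyotype$end_bp,
                        karyotype$cn), collapse = ";") else "",
                      stringsAsFactors = FALSE)
  list(profile = profile, truth = truth, lambda = lambda, cn = cn)
}

#' Simulate a plate of cells
#'
#' One shared amplification field per plate; each cell draws a karyotype
#' from `karyotypes` with probabilities `probs` (the first entry is
#' conventionally the euploid karyotype, `NULL`). `carriers` forces an
#' exact set of cell indices to carry `karyotypes[[2]]` instead of random
#' assignment. In `average_cell` mode every cell's expectation is replaced
#' by the plate-mean expectation profile, emulating pooled nuclei evenly
#' re-split into wells — the validation design in which no CNAs should be
#' detected.
#'
#' @param scaffold a `bin_scaffold`.
#' @param config a [sim_config()].
#' @param n_cells cells on the plate.
#' @param karyotypes list of event data.frames (`NULL` = euploid).
#' @param probs per-karyotype assignment probabilities (sum to 1).
#' @param carriers optional integer indices of cells forced to karyotype 2.
#' @param plate_id,sex metadata.
#' @param average_cell logical, see above.
#' @return list with `profiles` (list of `cell_profile`), `truth`
#'   (data.frame), `shared_field`.
#' @export
simulate_plate <- function(scaffold, config, n_cells = config$plate_size,
                           karyotypes = list(NULL), probs = 1,
                           carriers = NULL, plate_id = "plate1",
                           sex = "female", average_cell = FALSE) {
  stopifnot(abs(sum(probs) - 1) < 1e-9, length(probs) == length(karyotypes))
  shared <- wga_field(scaffold, config$wga_sigma_shared, config$wga_corr_len)
  assign <- sample.int(length(karyotypes), n_cells, replace = TRUE,
                       prob = probs)
  if (!is.null(carriers)) {
    assign[] <- 1L
    assign[carriers] <- 2L
  }
  cells <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    cells[[k]] <- simulate_cell(
      scaffold, config, karyotype = karyotypes[[assign[k]]],
      shared_field = shared,
      cell_id = sprintf("%s_c%03d", plate_id, k),
      plate_id = plate_id, sex = sex)
  }
  if (average_cell) {
    lambda_bar <- Reduce(`+`, lapply(cells, `[[`, "lambda")) / n_cells
    for (k in seq_len(n_cells)) {
      cells[[k]] <- simulate_cell(
        scaffold, config, karyotype = NULL, shared_field = shared,
        cell_id = sprintf("%s_c%03d", plate_id, k), plate_id = plate_id,
        sex = sex, lambda_override = lambda_bar)
    }
  }
  profiles <- lapply(cells, `[[`, "profile")
  names(profiles) <- vapply(profiles, function(p) p$cell_id, "")
  truth <- do.call(rbind, lapply(cells, `[[`, "truth"))
  truth$karyotype_index <- if (average_cell) 1L else assign
  list(profiles = profiles, truth = truth, shared_field = shared)
}

#' Simulate a pseudobulk TE biopsy
#'
#' Expected counts follow the mixture copy-number profile
#' `f * cn_aneuploid + (1 - f) * 2` per bin, modulated by GC efficiency and
#' an amplification field split into a component shared across samples of
#' the batch (removable by the round-2 pooled control) and a sample-private
#' component. Unlike a MALBAC single cell, a biopsy is one reaction
#' amplifying `2 * n_cells` template copies per locus, so its private
#' field averages over copies (log-sd `wga_sigma_private /
#' sqrt(2 * n_cells)`) and its counts are Poisson — the overdispersion of
#' bulk low-pass WGS is carried by the amplification fields, not by
#' per-bin jackpotting. The mosaic fraction is quantized to whole cells
#' (`round(f * n_cells) / n_cells`): a biopsy contains an integer number
#' of aneuploid cells.
#'
#' @param scaffold the TE-mode `bin_scaffold`.
#' @param config a [sim_config()] (`te_sigma_shared`, `te_n_cells`,
#'   `wga_sigma_private` are the relevant noise inputs).
#' @param events aneuploid karyotype events (see [karyotype_cn()]).
#' @param f mosaic fraction in [0, 1].
#' @param n_cells cells in the biopsy (default `config$te_n_cells`).
#' @param reads total reads for the biopsy library.
#' @param shared_field optional batch-shared field (drawn with
#'   `te_sigma_shared` when `NULL`).
#' @param sample_id label.
#' @return list with `profile` (a `cell_profile`), `truth` row.
#' @export
simulate_te_biopsy <- function(scaffold, config, events, f,
                               n_cells = config$te_n_cells, reads = 2e6,
                               shared_field = NULL, sample_id = "te") {
  stopifnot(f >= 0, f <= 1, n_cells >= 1)
  f <- round(f * n_cells) / n_cells
  if (is.null(shared_field))
    shared_field <- wga_field(scaffold, config$te_sigma_shared,
                              config$wga_corr_len)
  cn_aneu <- karyotype_cn(scaffold, events, sex = "female")
  cn_mix <- f * cn_aneu + (1 - f) * 2
  cn_mix[is_y(scaffold$chrom)] <- 0
  private <- wga_field(scaffold,
                       config$wga_sigma_private / sqrt(2 * n_cells),
                       config$private_corr_len)
  raw <- scaffold$weight * (cn_mix / 2) *
    gc_efficiency(scaffold$gc, config$gc_bias_coef) * shared_field * private
  lambda <- reads * raw / sum(raw)
  counts <- rpois(length(lambda), lambda)
  profile <- new_cell_profile(sample_id, counts, sum(counts),
                              plate_id = "te_batch", sex = "unknown")
  truth <- data.frame(sample_id = sample_id, mosaic_fraction = f,
                      events = if (!is.null(events) && nrow(events))
                        paste(sprintf("%s:%.0f-%.0f=%d", events$chrom,
                                      events$start_bp, events$end_bp,
                                      events$cn), collapse = ";") else "",
                      stringsAsFactors = FALSE)
  list(profile = profile, truth = truth)
}

#' Emit synthetic reads as a barcoded BED file
#'
#' For each bin, writes `count_b` read records at uniform random positions
#' within the bin, with the cell barcode as the prefix of the BED name
#' field; counting the file back through [demultiplex_bed()] and
#' [count_in_bins()] reproduces the count vector exactly.
#'
#' @param profile a `cell_profile`.
#' @param scaffold the matching `bin_scaffold`.
#' @param path output BED path (append-safe: pass a connection-opened file
#'   for multi-cell output, or use `append = TRUE`).
#' @param barcode 8-nt cell barcode for the name field.
#' @param read_len read length used for the BED end coordinate.
#' @param append append to an existing file.
#' @return the path, invisibly.
#' @export
emit_bed <- function(profile, scaffold, path, barcode, read_len = 50,
                     append = FALSE) {
  rows <- list()
  serial <- 0L
  for (b in seq_len(nrow(scaffold))) {
    cnt <- profile$counts[b]
    if (cnt == 0) next
    pos <- scaffold$start[b] +
      floor(runif(cnt) * (scaffold$end[b] - scaffold$start[b]))
    rows[[length(rows) + 1]] <- data.frame(
      chrom = scaffold$chrom[b], start = pos,
      end = pmin(pos + read_len,
                 attr(scaffold, "chrom_lengths")[[scaffold$chrom[b]]]),
      name = sprintf("%s:%d", barcode, serial + seq_along(pos)),
      stringsAsFactors = FALSE)
    serial <- serial + cnt
  }
  if (length(rows)) {
    utils::write.table(do.call(rbind, rows), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE,
                       append = append)
  } else if (!append) {
    file.create(path)
  }
  invisible(path)
}
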