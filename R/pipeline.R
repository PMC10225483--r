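#' End-to-end orchestration
#'
#' [analyze_cells()] runs the single-cell stages in their fixed order
#' (depth -> GC -> plate control -> CBS -> ploidy/CN -> events -> QC) for a
#' set of cells; [simulate_cohort()] builds a synthetic multi-infant cohort
#' with TE biopsies; [run_pipeline()] wires the two together with the
#' concordance analysis and writes every artifact as TSV/JSON with a
#' provenance header (package version, seed, config hash), so re-running
#' with identical inputs reproduces identical files.
#'
#' @name pipeline
NULL

#' Analyze a set of single cells
#'
#' @param profiles named list of `cell_profile` objects (plate ids set).
#' @param scaffold the `bin_scaffold` the counts were made on.
#' @param params a [cbs_params()] object.
#' @param lowess_span,control_trim,control_min_cells normalization tuning.
#' @param cv_max,min_reads QC thresholds, see [apply_dna_qc()].
#' @param min_len_bp CNA event length floor.
#' @return list with `ratios` (control-corrected profiles), `cn`
#'   (cn_profiles), `events` (one data.frame over all cells), `qc`
#'   (QC table).
#' @export
analyze_cells <- function(profiles, scaffold, params = cbs_params(),
                          lowess_span = 0.3, control_trim = 0.1,
                          control_min_cells = 8, cv_max = 1.0,
                          min_reads = 3e5, min_len_bp = 10e6) {
  plate_ids <- vapply(profiles, function(p) as.character(p$plate_id), "")
  ratios <- list()
  for (plate in unique(plate_ids)) {
    members <- profiles[plate_ids == plate]
    ratios <- c(ratios, normalize_plate(
      members, scaffold, lowess_span = lowess_span,
      control_trim = control_trim, control_min_cells = control_min_cells))
  }
  ratios <- ratios[names(profiles)]
  cn_profiles <- list()
  events <- list()
  for (id in names(profiles)) {
    seg <- segment_profile(ratios[[id]], scaffold, params)
    opt <- optimize_ploidy_scale(seg)
    cn <- assign_integer_cn(seg, opt$D, opt$objective, opt$flagged)
    cn_profiles[[id]] <- cn
    events[[id]] <- call_cna_events(cn, min_len_bp = min_len_bp)
  }
  qc <- qc_table(profiles, scaffold, ratios = ratios,
                 cn_profiles = cn_profiles, cv_max = cv_max,
                 min_reads = min_reads)
  list(ratios = ratios, cn = cn_profiles,
       events = do.call(rbind, unname(events)), qc = qc)
}

#' Simulate a synthetic cohort of infants with TE biopsies
#'
#' Each infant row yields `n_cells` blood cells split across 96-well
#' plates (a trailing plate smaller than the control minimum is folded
#' into the previous one) and one pseudobulk TE biopsy at the requested
#' mosaic fraction. `carrier_fraction` of the cells (an exact count, drawn
#' without replacement) carry the TE event as a true somatic CNA. Extra
#' euploid biopsies are simulated in the same batch so the two-round TE
#' control can always be built.
#'
#' @param config a [sim_config()].
#' @param infants data.frame with columns `infant_id`, `n_cells`, `sex`,
#'   `te_chrom`, `te_start`, `te_end`, `te_cn`, `te_fraction`,
#'   `carrier_fraction`. `te_chrom = NA` means a euploid biopsy.
#' @param n_control_biopsies extra euploid biopsies for the TE batch.
#' @param te_reads reads per biopsy library.
#' @return list with `scaffold`, `scaffold_te`, `cells` (profiles),
#'   `manifest` (cell -> infant/plate/sex), `truth`, `te_profiles`,
#'   `te_truth`.
#' @export
simulate_cohort <- function(config, infants, n_control_biopsies = 4,
                            te_reads = 2e6) {
  scaffold <- sim_scaffold(config)
  config_te <- config
  config_te$bin_bp <- 2.5e6
  scaffold_te <- sim_scaffold(config_te)
  cells <- list(); manifest <- list(); truth <- list()
  te_profiles <- list(); te_truth <- list()
  te_shared <- wga_field(scaffold_te, config$te_sigma_shared,
                         config$wga_corr_len)
  for (i in seq_len(nrow(infants))) {
    inf <- infants[i, ]
    event <- NULL
    if (!is.na(inf$te_chrom))
      event <- data.frame(chrom = inf$te_chrom, start_bp = inf$te_start,
                          end_bp = inf$te_end, cn = inf$te_cn,
                          stringsAsFactors = FALSE)
    # near-equal plates: a tiny trailing plate would make a poor pooled
    # control, so cells are spread evenly over the minimum plate count
    n_plates <- max(1, ceiling(inf$n_cells / config$plate_size))
    sizes <- rep(floor(inf$n_cells / n_plates), n_plates)
    extra <- inf$n_cells - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    n_carrier <- round((inf$carrier_fraction %||% 0) * inf$n_cells)
    carrier_global <- if (n_carrier > 0 && !is.null(event))
      sort(sample.int(inf$n_cells, n_carrier)) else integer(0)
    offset <- 0
    for (p in seq_along(sizes)) {
      plate_id <- sprintf("%s_p%d", inf$infant_id, p)
      local_carriers <- carrier_global[carrier_global > offset &
                                         carrier_global <= offset + sizes[p]] -
        offset
      plate <- simulate_plate(
        scaffold, config, n_cells = sizes[p],
        karyotypes = list(NULL, event),
        probs = c(1, 0), carriers = if (length(local_carriers))
          local_carriers else NULL,
        plate_id = plate_id, sex = inf$sex)
      cells <- c(cells, plate$profiles)
      tr <- plate$truth
      tr$infant_id <- inf$infant_id
      truth[[length(truth) + 1]] <- tr
      manifest[[length(manifest) + 1]] <- data.frame(
        cell_id = tr$cell_id, infant_id = inf$infant_id,
        plate_id = plate_id, sex = inf$sex, stringsAsFactors = FALSE)
      offset <- offset + sizes[p]
    }
    te <- simulate_te_biopsy(scaffold_te, config, event,
                             f = if (is.null(event)) 0 else inf$te_fraction,
                             reads = te_reads, shared_field = te_shared,
                             sample_id = sprintf("%s_te", inf$infant_id))
    te_profiles[[te$profile$cell_id]] <- te$profile
    te_truth[[length(te_truth) + 1]] <- te$truth
  }
  for (k in seq_len(n_control_biopsies)) {
    te <- simulate_te_biopsy(scaffold_te, config, NULL, f = 0,
                             reads = te_reads, shared_field = te_shared,
                             sample_id = sprintf("ctrl%d_te", k))
    te_profiles[[te$profile$cell_id]] <- te$profile
    te_truth[[length(te_truth) + 1]] <- te$truth
  }
  list(scaffold = scaffold, scaffold_te = scaffold_te, cells = cells,
       manifest = do.call(rbind, manifest), truth = do.call(rbind, truth),
       te_profiles = te_profiles, te_truth = do.call(rbind, te_truth))
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulation -> single-cell analysis -> TE two-round analysis ->
#' per-infant concordance -> cohort report, with every table written under
#' `out_dir` carrying a provenance header. Byte-identical on re-runs with
#' the same seed and configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param infants infant specification, see [simulate_cohort()].
#' @param params a [cbs_params()] object.
#' @param seed integer seed for all randomness.
#' @return list with `summaries`, `report`, `analysis`, `te`, `sim`
#'   (invisibly returns paths in `files`).
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         infants = demo_infants(), params = cbs_params(),
                         seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sim <- simulate_cohort(config, infants)
  analysis <- analyze_cells(sim$cells, sim$scaffold, params)
  te <- te_pipeline(sim$te_profiles, sim$scaffold_te, params)
  summaries <- list()
  for (i in seq_len(nrow(infants))) {
    inf_id <- infants$infant_id[i]
    cell_ids <- sim$manifest$cell_id[sim$manifest$infant_id == inf_id]
    ev <- analysis$events[analysis$events$cell_id %in% cell_ids, ,
                          drop = FALSE]
    te_ev <- te[[sprintf("%s_te", inf_id)]]$events
    qc_sub <- analysis$qc[analysis$qc$cell_id %in% cell_ids, , drop = FALSE]
    summaries[[inf_id]] <- summarize_infant(inf_id, ev, te_ev, qc_sub)
  }
  report <- cohort_report(summaries)
  prov <- provenance_meta(config, seed)
  files <- c(
    qc = write_provenanced(analysis$qc, file.path(out_dir, "qc.tsv"), prov),
    events = write_provenanced(analysis$events,
                               file.path(out_dir, "cell_events.tsv"), prov),
    pairs = write_provenanced(
      do.call(rbind, lapply(summaries, `[[`, "pairs")),
      file.path(out_dir, "pair_classification.tsv"), prov),
    summary = write_provenanced(report$table,
                                file.path(out_dir, "infant_summary.tsv"),
                                prov),
    truth = write_provenanced(sim$truth, file.path(out_dir, "truth.tsv"),
                              prov))
  write_seg(analysis$cn, file.path(out_dir, "segments.seg"))
  jsonlite::write_json(
    list(provenance = as.list(prov), infants = report$table,
         mean_cna_fraction = report$mean_cna_fraction),
    file.path(out_dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(summaries = summaries, report = report,
                 analysis = analysis, te = te, sim = sim, files = files))
}

#' Demo cohort specification
#'
#' Three infants with ~200 cells each: one with a mosaic chr2 trisomy in
#' the TE biopsy and no carrier blood cells, one with a mosaic chr4
#' monosomy, one with a euploid biopsy.
#'
#' @return data.frame accepted by [simulate_cohort()].
#' @export
demo_infants <- function() {
  data.frame(
    infant_id = c("I01", "I02", "I03"),
    n_cells = c(200, 200, 200),
    sex = c("male", "female", "female"),
    te_chrom = c("chr2", "chr4", NA),
    te_start = c(0, 0, NA), te_end = c(200e6, 120e6, NA),
    te_cn = c(3, 1, NA), te_fraction = c(0.5, 0.5, NA),
    carrier_fraction = c(0, 0, 0),
    stringsAsFactors = FALSE)
}

provenance_meta <- function(config, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(config), tmp)
  c(package = sprintf("mosaicCNA %s",
                      as.character(utils::packageVersion("mosaicCNA"))),
    seed = as.character(seed),
    config_md5 = unname(tools::md5sum(tmp)))
}

write_provenanced <- function(df, path, prov) {
  con <- file(path, "w")
  writeLines(sprintf("#%s\t%s", names(prov), prov), con)
  if (!is.null(df) && nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines("#empty", con)
  }
  close(con)
  path
}
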