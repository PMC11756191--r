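#' Default pipeline configuration
#'
#' The synthetic "transformation" study conditions: a 3-chromosome, 60 Mb
#' genome at 100 kb working resolution (1 Mb coarse overview) with ~1 Mb
#' TADs nested inside ~3 Mb compartment blocks (compartment domains span
#' several TADs, as in real genomes), a CLL-like baseline (`alpha = 1`,
#' `delta_c = 0.6`, `delta_t = 1`, depth 1e7) and a DLBCL-like derived
#' condition with 4 TAD fusions, 20 compartment switches, 30% insulation
#' attenuation, a steeper distance decay (`decay_shift = 0.15`) and
#' strengthened B-B contacts (`bb_boost = 0.3`). Analysis parameters
#' follow the module defaults.
#'
#' @param path optional YAML file whose top-level keys override the
#'   defaults.
#' @return nested configuration list.
#' @export
default_config <- function(path = NULL) {
  cfg <- list(
    genome = list(chrom_names = c("chr1", "chr2", "chr3"),
                  chrom_lengths = c(2e7, 2e7, 2e7),
                  bin_size = 1e5),
    coarse_bin_size = 1e6,
    sim = list(n_tads_per_chrom = 20, compartment_block_len = 30,
               alpha = 1, delta_c = 0.6, delta_t = 1, depth = 1e7,
               min_tad_size = 5,
               n_fusions = 4, n_switches = 20,
               insulation_attenuation = 0.3,
               decay_shift = 0.15, bb_boost = 0.3,
               orientation_sd = 0.3,
               n_genes = 2000, frac_up = 0.5, enrichment_odds = 5),
    params = list(ice_tol = 1e-5, ice_max_iter = 200, mask_quantile = 0.02,
                  bins_per_decade = 8, w = 5, strength_min = 0.1,
                  min_tad = 3, fusion_tol = 1, fusion_min_delta = 0.25,
                  Q = 20, trim = 0.02,
                  corner_frac = 0.2, flank = 1, target_size = 30),
    seed = 1)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      if (is.list(user[[k]]) && is.list(cfg[[k]]))
        cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
      else cfg[[k]] <- user[[k]]
    }
  }
  stopifnot(cfg$coarse_bin_size %% cfg$genome$bin_size == 0)
  cfg
}

#' Run the full two-condition analysis on synthetic data
#'
#' Chains simulation, balancing, P(s) curves with crossover, the coarse
#' differential matrix, compartment calling with switches and saddles,
#' insulation/TAD/fusion analysis and DEG integration, writing every
#' intermediate as a text file under `outdir` and returning (and writing)
#' a run report of all summary metrics. Identical config and seed
#' reproduce every output byte-for-byte. A failed stage is recorded in the
#' report and downstream stages are skipped.
#'
#' @param cfg configuration from [default_config()].
#' @param outdir output directory (created if needed).
#' @param seed top-level seed; per-stage seeds are derived from it and the
#'   stage name.
#' @return the run report (list), invisibly written to
#'   `<outdir>/report.json`.
#' @export
run_pipeline <- function(cfg = default_config(), outdir, seed = cfg$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  report <- list(version = as.character(utils::packageVersion("tadfuse")),
                 seed = seed, stages = list(), metrics = list(),
                 parameters = cfg)
  failed <- FALSE
  stage <- function(name, expr) {
    if (failed) {
      report$stages[[name]] <<- "skipped"
      return(NULL)
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- paste("failed:", conditionMessage(res))
      failed <<- TRUE
      NULL
    } else {
      report$stages[[name]] <<- "ok"
      res
    }
  }

  sim <- stage("simulate", {
    spec <- genome_spec(cfg$genome$chrom_names, cfg$genome$chrom_lengths,
                        cfg$genome$bin_size)
    t1 <- generate_genome(spec, cfg$sim$n_tads_per_chrom,
                          cfg$sim$compartment_block_len,  # compartments span several TADs

                          seed = stage_seed(seed, "truth1"),
                          alpha = cfg$sim$alpha, delta_c = cfg$sim$delta_c,
                          delta_t = cfg$sim$delta_t, depth = cfg$sim$depth,
                          min_tad_size = cfg$sim$min_tad_size)
    t2 <- derive_condition_two(t1, cfg$sim$n_fusions, cfg$sim$n_switches,
                               cfg$sim$insulation_attenuation,
                               seed = stage_seed(seed, "truth2"),
                               decay_shift = cfg$sim$decay_shift,
                               bb_boost = cfg$sim$bb_boost)
    m1 <- simulate_contacts(t1, seed = stage_seed(seed, "contacts1"))
    m2 <- simulate_contacts(t2, seed = stage_seed(seed, "contacts2"))
    ori <- orientation_track(t1, sd = cfg$sim$orientation_sd,
                             seed = stage_seed(seed, "orientation"))
    write_truth_json(t1, file.path(outdir, "truth_condition1.json"))
    write_truth_json(t2, file.path(outdir, "truth_condition2.json"))
    write_contact_table(m1, file.path(outdir, "bins.tsv"),
                        file.path(outdir, "pixels_condition1.tsv"))
    write_contact_table(m2, file.path(outdir, "bins.tsv"),
                        file.path(outdir, "pixels_condition2.tsv"))
    write_bedgraph(ori, spec, file.path(outdir, "orientation.bedgraph"))
    list(spec = spec, t1 = t1, t2 = t2, m1 = m1, m2 = m2, ori = ori)
  })

  bal <- stage("balance", {
    b1 <- ice_balance(sim$m1, max_iter = p$ice_max_iter, tol = p$ice_tol,
                      mask_quantile = p$mask_quantile)
    b2 <- ice_balance(sim$m2, max_iter = p$ice_max_iter, tol = p$ice_tol,
                      mask_quantile = p$mask_quantile)
    list(b1 = b1, b2 = b2)
  })

  ps <- stage("ps_curve", {
    c1 <- contact_probability_curve(sim$m1, p$bins_per_decade)
    c2 <- contact_probability_curve(sim$m2, p$bins_per_decade)
    write_curve_tsv(c1, file.path(outdir, "ps_condition1.tsv"))
    write_curve_tsv(c2, file.path(outdir, "ps_condition2.tsv"))
    xo <- crossover_distance(c2, c1)   # condition 2 proximal gain
    report$metrics$crossover_bp <- xo
    # condition-2 curve above condition-1 below the crossover?
    below <- which(c1$centers < (xo %||% Inf))
    report$metrics$cond2_higher_below_crossover <-
      if (is.na(xo) || !length(below)) NA
      else mean(c2$prob[below] > c1$prob[below]) > 0.5
    list(c1 = c1, c2 = c2, crossover = xo)
  })

  stage("diff_matrix", {
    f <- as.integer(cfg$coarse_bin_size / cfg$genome$bin_size)
    cb1 <- ice_balance(coarsen(sim$m1, f))
    cb2 <- ice_balance(coarsen(sim$m2, f))
    dm <- differential_matrix(cb2, cb1)
    utils::write.table(round(dm$blocks[[1]], 6),
                       file.path(outdir, "diff_matrix_chr1_coarse.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    report$metrics$diff_matrix_mean_abs <-
      mean(abs(unlist(lapply(dm$blocks, function(b) b[is.finite(b)]))))
    NULL
  })

  comp <- stage("compartments", {
    oe1 <- observed_over_expected(bal$b1)
    oe2 <- observed_over_expected(bal$b2)
    e1a <- compartment_eigenvector(oe1, sim$ori)
    e1b <- compartment_eigenvector(oe2, sim$ori)
    write_bedgraph(e1a$E1, sim$spec, file.path(outdir, "E1_condition1.bedgraph"))
    write_bedgraph(e1b$E1, sim$spec, file.path(outdir, "E1_condition2.bedgraph"))
    sw <- classify_switches(e1a, e1b)
    utils::write.table(sw$table, file.path(outdir, "switches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    s1 <- saddle(oe1, e1a, Q = p$Q, trim = p$trim)
    s2 <- saddle(oe2, e1b, Q = p$Q, trim = p$trim)
    write_saddle_tsv(s1, file.path(outdir, "saddle_condition1.tsv"))
    write_saddle_tsv(s2, file.path(outdir, "saddle_condition2.tsv"))
    st1 <- compartment_strength(s1, p$corner_frac)
    st2 <- compartment_strength(s2, p$corner_frac)
    report$metrics$switch_counts <- as.list(sw$counts)
    report$metrics$strength_condition1 <- st1
    report$metrics$strength_condition2 <- st2
    report$metrics$bb_strength_change <- st2$BB - st1$BB
    list(oe1 = oe1, oe2 = oe2, e1a = e1a, e1b = e1b, sw = sw,
         st1 = st1, st2 = st2)
  })

  tad <- stage("tads", {
    i1 <- insulation_score(bal$b1, w = p$w)
    i2 <- insulation_score(bal$b2, w = p$w)
    write_bedgraph(i1$score, sim$spec,
                   file.path(outdir, "insulation_condition1.bedgraph"))
    write_bedgraph(i2$score, sim$spec,
                   file.path(outdir, "insulation_condition2.bedgraph"))
    bd1 <- call_boundaries(i1, strength_min = p$strength_min)
    bd2 <- call_boundaries(i2, strength_min = p$strength_min)
    sg1 <- segment_tads(bd1, sim$spec, min_tad = p$min_tad, track = i1)
    sg2 <- segment_tads(bd2, sim$spec, min_tad = p$min_tad, track = i2)
    write_tads_bed(sg1, sim$spec, file.path(outdir, "tads_condition1.bed"))
    write_tads_bed(sg2, sim$spec, file.path(outdir, "tads_condition2.bed"))
    r1 <- intra_inter_ratio(bal$b1, sg1)
    r2 <- intra_inter_ratio(bal$b2, sg1)  # same segmentation: comparable
    a1 <- aggregate_tads(comp$oe1, sg1, target_size = p$target_size)
    a2 <- aggregate_tads(comp$oe2, sg1, target_size = p$target_size)
    utils::write.table(round(a1$A, 6), file.path(outdir, "ata_condition1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(round(a2$A, 6), file.path(outdir, "ata_condition2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    fu <- detect_fusions(sg1, sg2, tol = p$fusion_tol,
                         track1 = i1, track2 = i2,
                         min_delta = p$fusion_min_delta)
    utils::write.table(fu, file.path(outdir, "fusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # insulation change at the boundaries the fusions lost
    off <- chrom_offsets(sim$spec)
    dins <- if (nrow(fu) > 0) {
      gb <- off[fu$chrom] + fu$lost_boundary
      mean(i2$score[gb] - i1$score[gb], na.rm = TRUE)
    } else NA_real_
    # detected vs planted fusion events (+-tol matching)
    ev <- sim$t2$fusion_events
    hit <- if (nrow(fu) > 0 && nrow(ev) > 0)
      vapply(seq_len(nrow(fu)), function(r)
        any(ev$chrom == fu$chrom[r] &
              abs(ev$boundary - fu$lost_boundary[r]) <= p$fusion_tol),
        logical(1)) else logical(0)
    report$metrics$n_boundaries_condition1 <- sum(lengths(bd1))
    report$metrics$n_boundaries_condition2 <- sum(lengths(bd2))
    report$metrics$n_fusions_detected <- nrow(fu)
    report$metrics$n_fusions_planted <- nrow(ev)
    report$metrics$fusion_recall <-
      if (nrow(ev) > 0) sum(hit) / nrow(ev) else NA_real_
    report$metrics$fusion_precision <-
      if (nrow(fu) > 0) mean(hit) else NA_real_
    report$metrics$intra_inter_ratio_condition1 <- r1$ratio
    report$metrics$intra_inter_ratio_condition2 <- r2$ratio
    report$metrics$insulation_change_at_lost_boundaries <- dins
    list(i1 = i1, i2 = i2, sg1 = sg1, sg2 = sg2, fu = fu)
  })

  stage("integrate", {
    dg <- simulate_deg_table(sim$t1, sim$t2, cfg$sim$n_genes,
                             cfg$sim$frac_up, cfg$sim$enrichment_odds,
                             seed = stage_seed(seed, "degs"),
                             flank = p$flank)
    write_deg_table(dg$degs, file.path(outdir, "degs.tsv"))
    off <- chrom_offsets(sim$spec)
    bnd_union <- sort(unique(unlist(lapply(sim$spec$chrom_names, function(ch)
      off[[ch]] + sort(unique(c(segmentation_boundaries(tad$sg1)[[ch]],
                                segmentation_boundaries(tad$sg2)[[ch]])))))))
    cls <- classify_degs(dg$degs, sim$spec, bnd_union, tad$fu,
                         flank = p$flank)
    utils::write.table(cls$table, file.path(outdir, "deg_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr <- enrichment_test(cls)
    utils::write.table(enr, file.path(outdir, "deg_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$metrics$deg_fractions <- as.list(cls$fractions)
    report$metrics$n_upg_tad <- length(cls$upg_tad)
    report$metrics$n_dwg_tad <- length(cls$dwg_tad)
    up_m <- enr[enr$direction == "up" & enr$category == "merged_tad", ]
    report$metrics$upg_tad_or <- up_m$or
    report$metrics$upg_tad_q <- up_m$q
    NULL
  })

  report$ok <- !failed
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(report)
}
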