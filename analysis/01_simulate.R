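#!/usr/bin/env Rscript
# Stage 1: fabricate the paired-condition study data with planted truth.
#
# Generates a CLL-like baseline genome architecture (TADs nested inside
# larger A/B compartment blocks), derives the transformed DLBCL-like
# condition (TAD fusions, compartment switches, insulation attenuation,
# steeper distance decay, strengthened B-B contacts), draws Poisson contact
# maps for both at the planted depth, and simulates the DEG table whose
# upregulated genes are enriched inside the fused TADs.
#
# Outputs (results/data/): bins+pixels TSVs, truth JSONs, orientation
# bedGraph, DEG TSV.

suppressMessages(library(tadfuse))
seed <- 20260928
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- if (file.exists("configs/default.yaml"))
  default_config("configs/default.yaml") else default_config()
spec <- genome_spec(cfg$genome$chrom_names, cfg$genome$chrom_lengths,
                    cfg$genome$bin_size)

t1 <- generate_genome(spec, cfg$sim$n_tads_per_chrom,
                      cfg$sim$compartment_block_len, seed = seed,
                      alpha = cfg$sim$alpha, delta_c = cfg$sim$delta_c,
                      delta_t = cfg$sim$delta_t, depth = cfg$sim$depth,
                      min_tad_size = cfg$sim$min_tad_size)
t2 <- derive_condition_two(t1, cfg$sim$n_fusions, cfg$sim$n_switches,
                           cfg$sim$insulation_attenuation, seed = seed + 1,
                           decay_shift = cfg$sim$decay_shift,
                           bb_boost = cfg$sim$bb_boost)
m1 <- simulate_contacts(t1, seed = seed + 2)
m2 <- simulate_contacts(t2, seed = seed + 3)
ori <- orientation_track(t1, sd = cfg$sim$orientation_sd, seed = seed + 4)
dg <- simulate_deg_table(t1, t2, cfg$sim$n_genes, cfg$sim$frac_up,
                         cfg$sim$enrichment_odds, seed = seed + 5,
                         flank = cfg$params$flank)

write_truth_json(t1, file.path(outdir, "truth_condition1.json"))
write_truth_json(t2, file.path(outdir, "truth_condition2.json"))
write_contact_table(m1, file.path(outdir, "bins.tsv"),
                    file.path(outdir, "pixels_condition1.tsv"))
write_contact_table(m2, file.path(outdir, "bins.tsv"),
                    file.path(outdir, "pixels_condition2.tsv"))
write_bedgraph(ori, spec, file.path(outdir, "orientation.bedgraph"))
write_deg_table(dg$degs, file.path(outdir, "degs.tsv"))

cat(sprintf(
  "genome: %d chrom(s), %d bins @ %g kb; depth %g per condition\n",
  length(spec$chrom_names), sum(spec$n_bins), spec$bin_size / 1e3,
  cfg$sim$depth))
cat(sprintf(
  "planted: %d TAD boundaries, %d fusions, %d switches, %d DEGs (omega=%g)\n",
  sum(lengths(t1$boundaries)), nrow(t2$fusion_events),
  nrow(t2$switch_bins), nrow(dg$degs), cfg$sim$enrichment_odds))
cat("wrote study data under", outdir, "\n")
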