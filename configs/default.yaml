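# Default study configuration: a desk-scale two-condition Hi-C comparison.
# Values here mirror default_config(); edit to change the simulated study.

genome:
  chrom_names: [chr1, chr2, chr3]
  chrom_lengths: [20000000, 20000000, 20000000]
  bin_size: 100000          # 100 kb working resolution

coarse_bin_size: 1000000     # 1 Mb whole-genome overview

sim:
  n_tads_per_chrom: 20     # ~1 Mb TADs
  compartment_block_len: 30  # ~3 Mb A/B blocks spanning several TADs
  min_tad_size: 5
  alpha: 1.0               # distance-decay exponent, baseline
  delta_c: 0.6             # same-compartment contact enrichment
  delta_t: 1.0             # same-TAD contact enrichment
  depth: 10000000             # expected cis contacts per condition
  n_fusions: 4
  n_switches: 20
  insulation_attenuation: 0.3
  decay_shift: 0.15        # condition-2 exponent = alpha + shift
  bb_boost: 0.3            # extra B-B contact factor in condition 2
  orientation_sd: 0.3
  n_genes: 2000
  frac_up: 0.5
  enrichment_odds: 5       # planted odds of up-genes inside fused TADs

params:
  ice_tol: 0.00001
  ice_max_iter: 200
  mask_quantile: 0.02
  bins_per_decade: 8
  w: 5                     # insulation window, bins
  strength_min: 0.1
  min_tad: 3
  fusion_tol: 1
  fusion_min_delta: 0.25
  Q: 20
  trim: 0.02
  corner_frac: 0.2
  flank: 1

seed: 1
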