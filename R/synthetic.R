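#' Generate a planted genome architecture
#'
#' Draws the hidden structure a two-condition Hi-C simulation is built on:
#' a TAD segmentation (each chromosome partitioned into `n_tads_per_chrom`
#' contiguous domains) and an A/B compartment checkerboard (labels
#' alternating in blocks of `compartment_block_len` bins with random phase
#' and random starting label). The returned truth also carries the
#' generative parameters used by [simulate_contacts()].
#'
#' Default parameters describe a CLL-like baseline condition: distance-decay
#' exponent `alpha = 1`, compartment contrast `delta_c = 0.6`, TAD contrast
#' `delta_t = 1`, and an expected cis depth of 1e7 contacts.
#'
#' @param spec a [genome_spec()]; the compartment/TAD working resolution is
#'   typically 100 kb.
#' @param n_tads_per_chrom number of TADs per chromosome (>= 1).
#' @param compartment_block_len compartment block length in bins (>= 1).
#' @param seed RNG seed; the same seed reproduces the truth exactly.
#' @param alpha power-law distance-decay exponent (> 0).
#' @param delta_c fractional contact enrichment for same-compartment pairs.
#' @param delta_t fractional contact enrichment for same-TAD pairs.
#' @param depth expected total cis contact count.
#' @param min_tad_size smallest TAD allowed when drawing boundaries (bins).
#' @return object of class `planted_truth` with fields `spec`, `labels`
#'   (per-bin "A"/"B"), `boundaries` (per chromosome, sorted 1-based bin
#'   indices of interior TAD starts), the generative parameters, and empty
#'   `fusion_events` / `switch_bins` tables.
#' @export
generate_genome <- function(spec, n_tads_per_chrom, compartment_block_len,
                            seed, alpha = 1, delta_c = 0.6, delta_t = 1,
                            depth = 1e7, min_tad_size = 3) {
  stopifnot(inherits(spec, "genome_spec"),
            n_tads_per_chrom >= 1, compartment_block_len >= 1)
  if (alpha <= 0) stop("alpha must be positive")
  if (any(spec$n_bins < n_tads_per_chrom))
    stop("a chromosome has fewer bins than n_tads_per_chrom")
  with_seed(seed, {
    boundaries <- list()
    labels <- character(0)
    for (k in seq_along(spec$chrom_names)) {
      n <- spec$n_bins[k]
      nt <- n_tads_per_chrom
      base <- min(min_tad_size, n %/% nt)
      extra <- n - nt * base
      # TAD sizes: minimum size plus a multinomial split of the remainder
      sizes <- base + as.vector(stats::rmultinom(1, extra, rep(1, nt)))
      boundaries[[spec$chrom_names[k]]] <-
        if (nt > 1) cumsum(sizes)[seq_len(nt - 1)] + 1L else integer(0)
      phase <- sample.int(compartment_block_len, 1) - 1L
      first <- sample(c("A", "B"), 1)
      blk <- ((seq_len(n) - 1L + phase) %/% compartment_block_len) %% 2L
      lab <- ifelse(blk == 0L, first, setdiff(c("A", "B"), first))
      labels <- c(labels, lab)
    }
    structure(list(spec = spec, labels = labels, boundaries = boundaries,
                   alpha = alpha, delta_c = delta_c, delta_t = delta_t,
                   depth = depth, bb_boost = 0,
                   fusion_events = data.frame(chrom = character(0),
                                              boundary = integer(0)),
                   switch_bins = data.frame(bin = integer(0),
                                            direction = character(0)),
                   seed = as.integer(seed)),
              class = "planted_truth")
  })
}

# per-chromosome TAD intervals [start, end) in 1-based bin indices
truth_tads <- function(boundaries, n_bins) {
  cuts <- c(1L, boundaries, n_bins + 1L)
  data.frame(start = cuts[-length(cuts)], end = cuts[-1])
}

# per-bin TAD id for one chromosome
tad_ids <- function(boundaries, n_bins) {
  findInterval(seq_len(n_bins), c(1L, boundaries))
}

#' Expected (noise-free) contact matrix of a planted truth
#'
#' The generative mean: for bins i != j of the same chromosome the expected
#' count is `K * |i-j|^(-alpha) * (1 + delta_c [same compartment]) *
#' (1 + delta_t [same TAD]) * (1 + bb_boost [both B])`, with the
#' chromosome's `K` set so expected counts sum to the chromosome's share of
#' `depth` (shares proportional to bin-pair counts). The diagonal is zero.
#'
#' @param truth a `planted_truth`.
#' @return `contact_matrix` of expectations (not balanced).
#' @export
expected_contacts <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  spec <- truth$spec
  off <- chrom_offsets(spec)
  npairs <- spec$n_bins * (spec$n_bins - 1) / 2
  share <- npairs / sum(npairs)
  blocks <- list()
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    lab <- truth$labels[(off[[chrom]] + 1):(off[[chrom]] + n)]
    tid <- tad_ids(truth$boundaries[[chrom]], n)
    d <- abs(row(diag(n)) - col(diag(n)))
    w <- matrix(0, n, n)
    sel <- d > 0
    w[sel] <- d[sel]^(-truth$alpha)
    same_c <- outer(lab, lab, "==")
    same_t <- outer(tid, tid, "==")
    both_b <- outer(lab == "B", lab == "B", "&")
    w <- w * (1 + truth$delta_c * same_c) * (1 + truth$delta_t * same_t) *
      (1 + truth$bb_boost * both_b)
    tot <- sum(w[upper.tri(w)])
    lambda <- w * (truth$depth * share[k] / tot)
    blocks[[chrom]] <- lambda
  }
  contact_matrix(spec, blocks, meta = list(expectation = TRUE))
}

#' Simulate a raw contact matrix from a planted truth
#'
#' Draws independent Poisson counts around the generative mean of
#' [expected_contacts()] for each bin pair (upper triangle, mirrored), so
#' the total count fluctuates around the planted depth. With
#' `noise = FALSE` the expectation itself is returned, which downstream
#' recovery tests use as noise-free input.
#'
#' @param truth a `planted_truth` (with `depth > 0`).
#' @param seed RNG seed; identical seeds give identical counts.
#' @param noise draw Poisson counts (default) or return the expectation.
#' @return raw-count `contact_matrix`.
#' @export
simulate_contacts <- function(truth, seed, noise = TRUE) {
  if (truth$depth <= 0) stop("depth must be positive")
  lam <- expected_contacts(truth)
  if (!noise) return(lam)
  with_seed(seed, {
    blocks <- lapply(lam$blocks, function(b) {
      n <- nrow(b)
      up <- upper.tri(b)
      x <- matrix(0, n, n)
      x[up] <- stats::rpois(sum(up), b[up])
      x + t(x)
    })
    contact_matrix(truth$spec, blocks, meta = list(simulated = TRUE,
                                                   seed = as.integer(seed)))
  })
}

#' Derive the transformed (condition-2) truth from a baseline truth
#'
#' Applies the structural changes that characterize the transformed state:
#' `n_fusions` randomly chosen interior TAD boundaries are removed (recorded
#' as fusion events), `n_switches` randomly chosen bins flip compartment
#' label (recorded with direction A->B or B->A), and the TAD contrast at the
#' retained boundaries is raised to `delta_t / (1 - insulation_attenuation)`
#' to emulate TAD compaction. Two optional knobs sharpen the contrast with
#' the baseline: `decay_shift` steepens the distance-decay exponent
#' (proximal contacts gain at the expense of distal ones) and `bb_boost`
#' multiplies B-B pair intensity by `1 + bb_boost` (strengthened inactive-
#' compartment interactions).
#'
#' @param truth baseline `planted_truth`.
#' @param n_fusions number of boundaries to remove (<= total interior
#'   boundaries).
#' @param n_switches number of bins whose compartment label flips.
#' @param insulation_attenuation in `[0, 1)`.
#' @param seed RNG seed.
#' @param decay_shift added to `alpha` for the derived condition.
#' @param bb_boost extra fractional enrichment for B-B bin pairs.
#' @return derived `planted_truth` with `fusion_events` and `switch_bins`
#'   filled in.
#' @export
derive_condition_two <- function(truth, n_fusions, n_switches,
                                 insulation_attenuation = 0, seed,
                                 decay_shift = 0, bb_boost = 0) {
  stopifnot(inherits(truth, "planted_truth"),
            insulation_attenuation >= 0, insulation_attenuation < 1)
  all_b <- do.call(rbind, lapply(names(truth$boundaries), function(ch) {
    b <- truth$boundaries[[ch]]
    if (length(b) == 0) NULL else data.frame(chrom = ch, boundary = b)
  }))
  n_avail <- if (is.null(all_b)) 0L else nrow(all_b)
  if (n_fusions > n_avail)
    stop("requested more fusions than interior boundaries (", n_avail, ")")
  n_total <- sum(truth$spec$n_bins)
  if (n_switches > n_total) stop("more switches than bins")
  with_seed(seed, {
    out <- truth
    out$fusion_events <- data.frame(chrom = character(0), boundary = integer(0))
    if (n_fusions > 0) {
      pick <- sort(sample.int(n_avail, n_fusions))
      ev <- all_b[pick, , drop = FALSE]
      rownames(ev) <- NULL
      out$fusion_events <- ev
      for (i in seq_len(nrow(ev)))
        out$boundaries[[ev$chrom[i]]] <-
          setdiff(out$boundaries[[ev$chrom[i]]], ev$boundary[i])
    }
    out$switch_bins <- data.frame(bin = integer(0), direction = character(0))
    if (n_switches > 0) {
      bins <- sort(sample.int(n_total, n_switches))
      dir <- ifelse(truth$labels[bins] == "A", "AB", "BA")
      out$labels[bins] <- ifelse(truth$labels[bins] == "A", "B", "A")
      out$switch_bins <- data.frame(bin = bins, direction = dir)
    }
    out$delta_t <- truth$delta_t / (1 - insulation_attenuation)
    out$alpha <- truth$alpha + decay_shift
    out$bb_boost <- bb_boost
    out$seed <- as.integer(seed)
    out
  })
}

#' Noisy orientation track for compartment sign assignment
#'
#' Stands in for the GC-content or gene-density track used to orient the
#' compartment eigenvector: the planted compartment indicator (+1 for A,
#' -1 for B) plus Gaussian noise.
#'
#' @param truth a `planted_truth`.
#' @param sd noise standard deviation (default 0.3).
#' @param seed RNG seed.
#' @return numeric per-bin vector.
#' @export
orientation_track <- function(truth, sd = 0.3, seed) {
  with_seed(seed, {
    ind <- ifelse(truth$labels == "A", 1, -1)
    ind + stats::rnorm(length(ind), 0, sd)
  })
}

# global 1-based bin ids lying strictly inside fused (merged) TADs:
# the condition-2 TAD containing each lost boundary, minus its two
# terminal bins
merged_tad_bins <- function(truth2) {
  spec <- truth2$spec
  off <- chrom_offsets(spec)
  ev <- truth2$fusion_events
  bins <- integer(0)
  if (nrow(ev) == 0) return(bins)
  for (ch in unique(ev$chrom)) {
    n <- spec$n_bins[match(ch, spec$chrom_names)]
    tads <- truth_tads(truth2$boundaries[[ch]], n)
    for (b in ev$boundary[ev$chrom == ch]) {
      i <- which(tads$start <= b & b < tads$end)
      s <- tads$start[i]; e <- tads$end[i]
      if (e - s > 2)
        bins <- c(bins, off[[ch]] + seq(s + 1L, e - 2L))
    }
  }
  sort(unique(bins))
}

# union of interior boundary bins over two truths, global 1-based ids
union_boundary_bins <- function(truth1, truth2) {
  off <- chrom_offsets(truth1$spec)
  out <- integer(0)
  for (ch in truth1$spec$chrom_names) {
    b <- sort(unique(c(truth1$boundaries[[ch]], truth2$boundaries[[ch]])))
    out <- c(out, off[[ch]] + b)
  }
  out
}

#' Simulate a differential-expression gene table with planted structure
#'
#' Places `n_genes` gene TSSs on the genome: downregulated genes uniformly
#' over bins, upregulated genes with sampling odds `enrichment_odds` for
#' bins inside merged (fused) TADs relative to all other bins. Every listed
#' gene is "significant" (adjusted p < 0.05); log2 fold-change signs match
#' the direction. The returned truth labels each gene with its structural
#' category using the same geometry the classifier sees: `boundary` within
#' `flank` bins of the union of both conditions' boundaries, else
#' `merged_tad` inside a fused-TAD interior, else `other`.
#'
#' @param truth1 baseline `planted_truth`.
#' @param truth2 derived truth carrying the fusion events.
#' @param n_genes number of genes (0 gives empty tables).
#' @param frac_up fraction upregulated.
#' @param enrichment_odds planted odds `omega >= 1` for up-genes inside
#'   merged TADs.
#' @param seed RNG seed.
#' @param flank boundary flank in bins used for truth categories.
#' @return list with `degs` (data.frame: gene, chrom, tss, log2fc, padj,
#'   direction) and `truth` (data.frame: gene, bin, direction, category),
#'   plus the planted `omega` and the merged/boundary bin sets.
#' @export
simulate_deg_table <- function(truth1, truth2, n_genes, frac_up = 0.5,
                               enrichment_odds = 1, seed, flank = 1) {
  if (enrichment_odds < 1) stop("enrichment_odds must be >= 1")
  stopifnot(n_genes >= 0)
  spec <- truth1$spec
  bins <- bin_table(spec)
  n_total <- nrow(bins)
  merged <- merged_tad_bins(truth2)
  bnd <- union_boundary_bins(truth1, truth2)
  bnd_flank <- unique(unlist(lapply(bnd, function(b)
    seq(b - flank, b + flank))))
  bnd_flank <- bnd_flank[bnd_flank >= 1 & bnd_flank <= n_total]
  empty <- list(
    degs = data.frame(gene = character(0), chrom = character(0),
                      tss = numeric(0), log2fc = numeric(0),
                      padj = numeric(0), direction = character(0)),
    truth = data.frame(gene = character(0), bin = integer(0),
                       direction = character(0), category = character(0)),
    omega = enrichment_odds, merged_bins = merged, boundary_bins = bnd_flank)
  if (n_genes == 0) return(empty)
  with_seed(seed, {
    n_up <- round(n_genes * frac_up)
    n_dn <- n_genes - n_up
    w_up <- rep(1, n_total)
    w_up[merged] <- enrichment_odds
    up_bins <- sample.int(n_total, n_up, replace = TRUE, prob = w_up)
    dn_bins <- sample.int(n_total, n_dn, replace = TRUE)
    bin_idx <- c(up_bins, dn_bins)
    direction <- c(rep("up", n_up), rep("down", n_dn))
    lfc <- ifelse(direction == "up", 1, -1) *
      (0.25 + abs(stats::rnorm(n_genes, 1, 0.75)))
    padj <- stats::runif(n_genes, 0, 0.049)
    tss <- bins$start[bin_idx] + floor(stats::runif(n_genes) * spec$bin_size)
    gene <- sprintf("g%05d", seq_len(n_genes))
    category <- ifelse(bin_idx %in% bnd_flank, "boundary",
                       ifelse(bin_idx %in% merged, "merged_tad", "other"))
    list(degs = data.frame(gene = gene, chrom = bins$chrom[bin_idx],
                           tss = tss, log2fc = lfc, padj = padj,
                           direction = direction),
         truth = data.frame(gene = gene, bin = bin_idx,
                            direction = direction, category = category),
         omega = enrichment_odds, merged_bins = merged,
         boundary_bins = bnd_flank)
  })
}
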