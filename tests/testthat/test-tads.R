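balanced_cm <- function(block) {
  m <- cm1(block)
  m$balanced <- TRUE
  m
}

test_that("insulation of a Toeplitz matrix is flat zero on interior bins", {
  n <- 20; w <- 3
  m <- balanced_cm(toeplitz_matrix(n, function(d) 5 / d))
  tr <- insulation_score(m, w = w)
  interior <- (w + 1):(n - w + 1)
  expect_equal(tr$score[interior], rep(0, length(interior)), tolerance = 1e-12)
  expect_true(all(is.na(tr$score[1:w])))
  expect_true(all(is.na(tr$score[(n - w + 2):n])))
})

test_that("insulation diamond matches hand enumeration on a two-block matrix", {
  n <- 12; w <- 2
  b <- matrix(1, n, n)
  b[1:6, 1:6] <- 10
  b[7:12, 7:12] <- 10
  diag(b) <- 0
  m <- balanced_cm(b)
  tr <- insulation_score(m, w = w)
  # raw at the junction bin 7: rows 5:6 x cols 7:8, all cross-block
  raw7 <- mean(b[5:6, 7:8])
  # reconstruct raw from the log track: score = log2(raw / geo mean)
  raws <- sapply((w + 1):(n - w + 1), function(i)
    mean(b[(i - w):(i - 1), i:(i + w - 1)]))
  geo <- exp(mean(log(raws)))
  expect_equal(tr$score[7], log2(raw7 / geo), tolerance = 1e-12)
  # the junction is the unique minimum
  expect_equal(which.min(tr$score), 7L)
})

test_that("boundary calling: flat track yields none; planted 2-TAD is exact", {
  n <- 20
  m <- balanced_cm(toeplitz_matrix(n, function(d) 5 / d))
  expect_length(call_boundaries(insulation_score(m, w = 3))$chr1, 0)
  sp <- spec1(40)
  tr <- generate_genome(sp, 2, 40, seed = 71, delta_c = 0, delta_t = 1)
  lam <- expected_contacts(tr)
  bal <- ice_balance(lam, mask_quantile = 0, tol = 1e-8)
  got <- call_boundaries(insulation_score(bal, w = 5))$chr1
  expect_equal(got, tr$boundaries$chr1)
})

test_that("segmentation tiles chromosomes and merges slivers", {
  sp <- spec1(30)
  seg0 <- segment_tads(list(chr1 = integer(0)), sp)
  expect_equal(nrow(seg0), 1)
  expect_equal(c(seg0$start_bin, seg0$end_bin), c(1, 31))
  seg <- segment_tads(list(chr1 = c(11, 21)), sp)
  expect_equal(seg$start_bin, c(1, 11, 21))
  expect_equal(seg$end_bin, c(11, 21, 31))
  # adjacent boundaries leave a 1-bin sliver that must be merged away
  seg2 <- segment_tads(list(chr1 = c(11, 12)), sp, min_tad = 3)
  expect_true(all(seg2$end_bin - seg2$start_bin >= 3))
  expect_equal(seg2$start_bin[1], 1)
  expect_equal(seg2$end_bin[nrow(seg2)], 31)
  expect_true(all(seg2$start_bin[-1] == head(seg2$end_bin, -1)))
})

test_that("intra/inter contact means match brute-force enumeration", {
  n <- 20
  b <- matrix(0, n, n)
  b[1:10, 1:10] <- 8
  b[11:20, 11:20] <- 6
  diag(b) <- 0
  m0 <- balanced_cm(b)
  seg <- segment_tads(list(chr1 = 11L), spec1(n))
  r0 <- intra_inter_ratio(m0, seg)
  expect_true(is.na(r0$ratio))
  expect_true(r0$inter_zero)
  set.seed(99)
  b[1:10, 11:20] <- matrix(runif(100, 0.5, 2), 10)
  b[11:20, 1:10] <- t(b[1:10, 11:20])
  m <- balanced_cm(b)
  r <- intra_inter_ratio(m, seg)
  intra_vals <- c(b[1:10, 1:10][upper.tri(b[1:10, 1:10])],
                  b[11:20, 11:20][upper.tri(b[11:20, 11:20])])
  tid <- rep(1:2, each = 10)
  inter_vals <- c()
  for (i in 1:19) for (j in (i + 1):20)
    if (tid[j] == tid[i] + 1 && j - i <= 10)
      inter_vals <- c(inter_vals, b[i, j])
  expect_equal(r$intra, mean(intra_vals))
  expect_equal(r$inter, mean(inter_vals))
  expect_equal(r$ratio, mean(intra_vals) / mean(inter_vals))
})

test_that("TAD aggregation: uniform input is flat; rescaling matches a bilinear oracle", {
  n <- 40
  b <- matrix(1, n, n); diag(b) <- 1
  m <- balanced_cm(b)
  seg <- segment_tads(list(chr1 = c(11, 21, 31)), spec1(n))
  agg <- aggregate_tads(m, seg, target_size = 10)
  expect_gte(agg$n_tads, 1)
  expect_equal(agg$A, matrix(1, 10, 10))
  # single TAD at native size (TAD 10 bins + 2x5 flank = 20) is the identity
  set.seed(7)
  bb <- random_counts(40, 12) / 10
  mm <- balanced_cm(bb)
  seg1 <- data.frame(chrom = "chr1", start_bin = 16L, end_bin = 26L)
  attr(seg1, "spec") <- spec1(n); class(seg1) <- c("tad_segmentation", class(seg1))
  a20 <- aggregate_tads(mm, seg1, target_size = 20)
  expect_equal(a20$n_tads, 1)
  src <- bb[11:30, 11:30]
  expect_equal(a20$A, (src + t(src)) / 2, tolerance = 1e-12)
  # rescale 20 -> 30 against an independent separable-interpolation oracle
  a30 <- aggregate_tads(mm, seg1, target_size = 30)
  u <- (seq_len(30) - 0.5) * 20 / 30 + 0.5
  u <- pmin(pmax(u, 1), 20)
  step1 <- apply(src, 2, function(col) approx(seq_len(20), col, xout = u)$y)
  oracle <- t(apply(step1, 1, function(row) approx(seq_len(20), row, xout = u)$y))
  expect_equal(a30$A, (oracle + t(oracle)) / 2, tolerance = 1e-9)
})

test_that("fusion detection applies the definition and the tolerance rule", {
  sp <- spec1(20)
  seg_a <- segment_tads(list(chr1 = 11L), sp)
  seg_b <- segment_tads(list(chr1 = integer(0)), sp)
  fu <- detect_fusions(seg_a, seg_b, tol = 1)
  expect_equal(nrow(fu), 1)
  expect_equal(fu$lost_boundary, 11L)
  expect_equal(c(fu$fused_start, fu$fused_end), c(1L, 21L))
  expect_equal(fu$n_merged, 2)
  expect_equal(nrow(detect_fusions(seg_a, seg_a, tol = 1)), 0)
  # boundary moved by 1 bin with tol 1: retained, not fused
  seg_c <- segment_tads(list(chr1 = 12L), sp)
  expect_equal(nrow(detect_fusions(seg_a, seg_c, tol = 1)), 0)
  # moved by 2 bins: the lost boundary's enclosing TAD no longer matches
  # condition-1 anchors, so it is a shift, not a fusion
  seg_d <- segment_tads(list(chr1 = 13L), sp)
  expect_equal(nrow(detect_fusions(seg_a, seg_d, tol = 1)), 0)
  # a genuine merge of 3 TADs into one reports both lost boundaries
  seg_e <- segment_tads(list(chr1 = c(7L, 14L)), sp)
  fu3 <- detect_fusions(seg_e, seg_b, tol = 1)
  expect_equal(sort(fu3$lost_boundary), c(7L, 14L))
  expect_equal(unique(fu3$n_merged), 3)
})

test_that("planted fusions are recovered exactly from noise-free matrices", {
  sp <- genome_spec(c("chr1", "chr2"), c(6e6, 6e6), 1e5)
  tr <- generate_genome(sp, 4, 60, seed = 81, delta_c = 0, delta_t = 1)
  t2 <- derive_condition_two(tr, n_fusions = 2, n_switches = 0,
                             insulation_attenuation = 0.3, seed = 82)
  segs <- lapply(list(tr, t2), function(t) {
    bal <- ice_balance(expected_contacts(t), mask_quantile = 0, tol = 1e-8)
    ins <- insulation_score(bal, w = 5)
    segment_tads(call_boundaries(ins), sp, track = ins)
  })
  fu <- detect_fusions(segs[[1]], segs[[2]], tol = 1)
  expect_equal(nrow(fu), nrow(t2$fusion_events))
  got <- fu[order(fu$chrom, fu$lost_boundary), c("chrom", "lost_boundary")]
  want <- t2$fusion_events[order(t2$fusion_events$chrom,
                                 t2$fusion_events$boundary), ]
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$lost_boundary, want$boundary)
})

test_that("fused boundaries lose insulation in the derived condition", {
  sp <- spec1(100)
  tr <- generate_genome(sp, 5, 100, seed = 91, delta_c = 0, delta_t = 1)
  t2 <- derive_condition_two(tr, 2, 0, 0.3, seed = 92)
  ins <- lapply(list(tr, t2), function(t)
    insulation_score(ice_balance(simulate_contacts(t, seed = 93),
                                 mask_quantile = 0), w = 5))
  lost <- t2$fusion_events$boundary
  kept <- setdiff(tr$boundaries$chr1, lost)
  d_lost <- mean(ins[[2]]$score[lost] - ins[[1]]$score[lost])
  d_kept <- mean(ins[[2]]$score[kept] - ins[[1]]$score[kept])
  expect_gt(d_lost, 0)
  expect_gt(d_lost, d_kept)
})
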