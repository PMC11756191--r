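# noise-free O/E of a planted truth, shared by several tests
planted_oe <- function(truth) {
  lam <- expected_contacts(truth)
  observed_over_expected(ice_balance(lam, mask_quantile = 0, tol = 1e-8))
}

test_that("eigenvector recovers a planted checkerboard from noise-free input", {
  sp <- spec1(120)
  tr <- generate_genome(sp, 4, 15, seed = 21, delta_c = 0.6)
  oe <- planted_oe(tr)
  ori <- orientation_track(tr, sd = 0.3, seed = 22)
  e1 <- compartment_eigenvector(oe, ori)
  expect_gte(label_agreement(e1, tr), 0.99)
  # negating the orientation track flips every label
  e1n <- compartment_eigenvector(oe, -ori)
  ok <- !is.na(e1$label) & !is.na(e1n$label)
  expect_true(all(e1$label[ok] != e1n$label[ok]))
  # unit variance per chromosome
  expect_equal(sd(e1$E1, na.rm = TRUE), 1, tolerance = 1e-6)
})

test_that("eigenvector signs follow an exact two-block structure", {
  # block O/E: enriched within two groups, depleted across
  n <- 24
  lab <- rep(c("A", "B"), each = 12)
  b <- outer(lab, lab, function(x, y) ifelse(x == y, 1.5, 0.6))
  diag(b) <- 0
  m <- cm1(b)
  m$balanced <- TRUE
  ori <- ifelse(lab == "A", 1, -1)
  e1 <- compartment_eigenvector(m, ori)
  expect_true(all(e1$label[1:12] == "A"))
  expect_true(all(e1$label[13:24] == "B"))
})

test_that("short chromosomes yield NA tracks with a warning", {
  sp <- spec1(6)
  b <- random_counts(6, 30)
  m <- cm1(b)
  expect_warning(e1 <- compartment_eigenvector(m, rep(1, 6)), "fewer than")
  expect_true(all(is.na(e1$E1)))
})

test_that("switch classification is the exact cross-tabulation", {
  mk <- function(labels) data.frame(chrom = "chr1",
                                    bin = seq_along(labels),
                                    E1 = ifelse(labels == "A", 1, -1),
                                    label = labels)
  t1 <- mk(c("A", "A", "B"))
  t2 <- mk(c("A", "B", "B"))
  sw <- classify_switches(t1, t2)
  expect_equal(sw$table$category, c("StableAA", "SwitchAB", "StableBB"))
  sw0 <- classify_switches(t1, t1)
  expect_equal(unname(sw0$counts[c("SwitchAB", "SwitchBA")]), c(0L, 0L))
  # NA propagates
  t3 <- mk(c("A", NA, "B"))
  expect_true(is.na(classify_switches(t1, t3)$table$category[2]))
})

test_that("planted switches are recovered exactly on noise-free input", {
  sp <- genome_spec(c("chr1", "chr2"), c(1.2e7, 1.2e7), 1e5)
  tr <- generate_genome(sp, 4, 15, seed = 31, delta_c = 0.6)
  t2 <- derive_condition_two(tr, 0, 12, 0, seed = 32)
  ori <- orientation_track(tr, sd = 0.3, seed = 33)
  e1a <- compartment_eigenvector(planted_oe(tr), ori)
  e1b <- compartment_eigenvector(planted_oe(t2), ori)
  sw <- classify_switches(e1a, e1b)
  expect_equal(unname(sw$counts["SwitchAB"] + sw$counts["SwitchBA"]), 12L)
  got <- sort(sw$table$bin[!is.na(sw$table$category) &
                             sw$table$category %in% c("SwitchAB", "SwitchBA")])
  expect_equal(got, t2$switch_bins$bin)
})

test_that("saddle of uniform O/E is all ones and Q=2 matches enumeration", {
  n <- 40
  b <- matrix(1, n, n); diag(b) <- 0
  m <- cm1(b); m$balanced <- TRUE
  track <- data.frame(chrom = "chr1", bin = 1:n,
                      E1 = seq(-2, 2, length.out = n),
                      label = rep(c("B", "A"), each = n / 2))
  s <- saddle(m, track, Q = 4, trim = 0)
  expect_equal(s$S, matrix(1, 4, 4))
  # Q = 2 against a direct two-group mean on a random O/E
  b2 <- random_counts(n, 44) / 50
  diag(b2) <- 0
  m2 <- cm1(b2); m2$balanced <- TRUE
  s2 <- saddle(m2, track, Q = 2, trim = 0)
  lo <- 1:(n / 2); hi <- (n / 2 + 1):n
  pairmean <- function(I, J) {
    tot <- cnt <- 0
    for (i in I) for (j in J) if (i < j) { tot <- tot + b2[i, j]; cnt <- cnt + 1 }
    for (i in J) for (j in I) if (i < j) { tot <- tot + b2[i, j]; cnt <- cnt + 1 }
    tot / cnt
  }
  expect_equal(s2$S[1, 1], pairmean(lo, lo))
  expect_equal(s2$S[2, 2], pairmean(hi, hi))
  expect_equal(s2$S[1, 2], pairmean(lo, hi))
  expect_equal(s2$S[1, 2], s2$S[2, 1])
})

test_that("planted compartment contrast appears in the saddle corners", {
  sp <- spec1(150)
  tr <- generate_genome(sp, 5, 25, seed = 41, delta_c = 0.5, delta_t = 0)
  oe <- planted_oe(tr)
  ori <- orientation_track(tr, sd = 0.1, seed = 42)
  e1 <- compartment_eigenvector(oe, ori)
  s <- saddle(oe, e1, Q = 5, trim = 0)
  # same-compartment pairs carry (1 + delta_c): corner ratio ~ 1.5 vs cross
  expect_gt(s$S[1, 1], s$S[1, 5])
  expect_gt(s$S[5, 5], s$S[1, 5])
  # brute-force oracle: group means recomputed by enumeration over bins
  grp_oracle <- function(p, q) {
    e <- e1$E1; ok <- which(is.finite(e) & !oe$mask)
    r <- rank(e[ok], ties.method = "first")
    g <- rep(NA_integer_, length(e))
    g[ok] <- pmin(5, ceiling(r / (length(ok) / 5)))
    tot <- cnt <- 0
    for (i in 1:149) for (j in (i + 1):150) {
      if (is.na(g[i]) || is.na(g[j])) next
      v <- oe$blocks$chr1[i, j]
      if (!is.finite(v)) next
      if ((g[i] == p && g[j] == q) || (g[i] == q && g[j] == p)) {
        tot <- tot + v; cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  expect_equal(s$S[1, 1], grp_oracle(1, 1), tolerance = 1e-12)
  expect_equal(s$S[2, 4], grp_oracle(2, 4), tolerance = 1e-12)
})

test_that("compartment strength is monotone in the planted contrast", {
  sp <- spec1(120)
  overall <- sapply(c(0.1, 0.2, 0.4, 0.6), function(dc) {
    tr <- generate_genome(sp, 4, 20, seed = 51, delta_c = dc, delta_t = 0)
    oe <- planted_oe(tr)
    ori <- orientation_track(tr, sd = 0.1, seed = 52)
    s <- saddle(oe, compartment_eigenvector(oe, ori), Q = 5, trim = 0.02)
    compartment_strength(s, corner_frac = 0.2)$overall
  })
  expect_equal(cor(overall, 1:4, method = "spearman"), 1)
  # all-ones saddle has zero overall strength
  s1 <- structure(list(S = matrix(1, 5, 5), counts = matrix(1, 5, 5),
                       Q = 5, trim = 0), class = "saddle_matrix")
  expect_equal(compartment_strength(s1)$overall, 0)
})

test_that("boosted B-B contacts raise BB strength in the derived condition", {
  sp <- spec1(120)
  tr <- generate_genome(sp, 4, 20, seed = 61, delta_c = 0.5, delta_t = 0)
  t2 <- derive_condition_two(tr, 0, 0, 0, seed = 62, bb_boost = 0.4)
  ori <- orientation_track(tr, sd = 0.1, seed = 63)
  oe1 <- planted_oe(tr); oe2 <- planted_oe(t2)
  s1 <- saddle(oe1, compartment_eigenvector(oe1, ori), Q = 5, trim = 0.02)
  s2 <- saddle(oe2, compartment_eigenvector(oe2, ori), Q = 5, trim = 0.02)
  expect_gt(compartment_strength(s2, corner_frac = 0.4)$BB,
            compartment_strength(s1, corner_frac = 0.4)$BB)
})

test_that("differential saddle is an exact antisymmetric log ratio", {
  s1 <- structure(list(S = matrix(c(2, 1, 1, 4), 2), Q = 2, trim = 0),
                  class = "saddle_matrix")
  s2 <- structure(list(S = matrix(c(1, 2, 2, 1), 2), Q = 2, trim = 0),
                  class = "saddle_matrix")
  d <- differential_saddle(s1, s2)
  expect_equal(d, log2(matrix(c(2, 0.5, 0.5, 4), 2)))
  expect_equal(differential_saddle(s2, s1), -d)
  expect_equal(differential_saddle(s1, s1), matrix(0, 2, 2))
})
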