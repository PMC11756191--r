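test_that("genome_spec enforces bin-size divisibility and bin_table tiles", {
  expect_error(genome_spec("chr1", 1050, 100), "multiple of bin_size")
  expect_error(genome_spec("chr1", 1000, 0), "positive")
  spec <- genome_spec(c("chrA", "chrB"), c(5e5, 3e5), 1e5)
  bins <- bin_table(spec)
  expect_equal(nrow(bins), 8)
  expect_equal(bins$bin_id, 0:7)
  expect_equal(bins$end - bins$start, rep(1e5, 8))
  expect_equal(bins$start[bins$chrom == "chrB"], c(0, 1e5, 2e5))
})

test_that("ICE balancing: constant matrix is a fixed point with uniform bias", {
  b <- matrix(3, 4, 4); diag(b) <- 0
  m <- ice_balance(cm1(b), mask_quantile = 0)
  rs <- rowSums(m$blocks$chr1)
  expect_equal(rs, rep(1, 4), tolerance = 1e-12)
  expect_equal(max(m$bias) / min(m$bias), 1, tolerance = 1e-12)
})

test_that("ICE balancing matches an independent iteration oracle", {
  w <- matrix(c(0, 5, 2, 1,
                5, 0, 7, 3,
                2, 7, 0, 9,
                1, 3, 9, 0), 4, 4)
  m <- ice_balance(cm1(w), tol = 1e-12, max_iter = 2000, mask_quantile = 0)
  expect_equal(m$blocks$chr1, ice_oracle(w), tolerance = 1e-10)
  expect_equal(rowSums(m$blocks$chr1), rep(1, 4), tolerance = 1e-10)
})

test_that("ICE masks empty rows and balances the remainder", {
  w <- matrix(c(0, 5, 2, 0,
                5, 0, 7, 0,
                2, 7, 0, 0,
                0, 0, 0, 0), 4, 4)
  m <- ice_balance(cm1(w), mask_quantile = 0)
  expect_true(m$mask[4])
  expect_false(any(m$mask[1:3]))
  expect_equal(m$blocks$chr1[4, ], rep(0, 4))
  expect_equal(rowSums(m$blocks$chr1)[1:3], rep(1, 3), tolerance = 1e-4)
})

test_that("ICE rejects all-zero and already-balanced input; warns on non-convergence", {
  expect_error(ice_balance(cm1(matrix(0, 4, 4))), "all-zero")
  m <- ice_balance(cm1(random_counts(6, 1)), mask_quantile = 0)
  expect_error(ice_balance(m), "already balanced")
  expect_warning(ice_balance(cm1(random_counts(6, 2)), max_iter = 1,
                             mask_quantile = 0, tol = 1e-12),
                 "did not converge")
})

test_that("re-balancing balanced values is a near-no-op (idempotence)", {
  m <- ice_balance(cm1(random_counts(8, 3)), mask_quantile = 0, tol = 1e-10)
  again <- ice_balance(cm1(m$blocks$chr1), mask_quantile = 0, tol = 1e-10)
  expect_equal(again$blocks$chr1, m$blocks$chr1, tolerance = 1e-6)
})

test_that("expected profile: 1/|i-j| matrix gives exactly 1/d", {
  n <- 8
  e <- expected_by_distance(cm1(toeplitz_matrix(n, function(d) 1 / d)))
  expect_equal(e$chr1, 1 / seq_len(n - 1))
})

test_that("expected profile matches a brute-force diagonal mean, honoring masks", {
  b <- random_counts(8, 4)
  m <- cm1(b)
  e <- expected_by_distance(m)
  for (d in 1:7) {
    vals <- sapply(seq_len(8 - d), function(i) b[i, i + d])
    expect_equal(e$chr1[d], mean(vals))
  }
  mm <- cm1(b, mask = c(FALSE, FALSE, TRUE, rep(FALSE, 5)))
  em <- expected_by_distance(mm)
  d <- 2
  pairs <- cbind(seq_len(8 - d), seq_len(8 - d) + d)
  keep <- pairs[, 1] != 3 & pairs[, 2] != 3
  expect_equal(em$chr1[d], mean(b[pairs[keep, , drop = FALSE]]))
})

test_that("O/E equals elementwise division and is 1 for self-expected input", {
  b <- toeplitz_matrix(6, function(d) 2 / d)
  oe <- observed_over_expected(cm1(b))
  expect_equal(oe$blocks$chr1[upper.tri(b)],
               rep(1, sum(upper.tri(b))))
  b2 <- random_counts(6, 5)
  m2 <- cm1(b2)
  e2 <- expected_by_distance(m2)
  oe2 <- observed_over_expected(m2, e2)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(oe2$blocks$chr1[i, j], b2[i, j] / e2$chr1[j - i])
  m3 <- cm1(b2, mask = c(TRUE, rep(FALSE, 5)))
  oe3 <- observed_over_expected(m3)
  expect_true(all(is.na(oe3$blocks$chr1[1, -1])))
})

test_that("P(s) on an analytic power law recovers the exponent", {
  n <- 300
  m <- cm1(toeplitz_matrix(n, function(d) d^(-1)))
  cv <- contact_probability_curve(m, bins_per_decade = 8)
  fit <- lm(log10(cv$prob) ~ log10(cv$centers))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.01)
  cv2 <- contact_probability_curve(cm1(toeplitz_matrix(n, function(d) d^(-1))),
                                   bins_per_decade = 8)
  expect_identical(cv, cv2)
})

test_that("crossover of two normalized power laws matches the closed form", {
  centers <- 10^seq(5, 8, by = 1 / 8)
  a_raw <- centers^(-1); b_raw <- centers^(-1.5)
  a <- contact_curve(centers, a_raw / sum(a_raw))
  b <- contact_curve(centers, b_raw / sum(b_raw))
  expect_true(is.na(crossover_distance(a, a)))
  # c1 s^-1 = c2 s^-1.5  =>  s* = (c2/c1)^2
  s_star <- (sum(a_raw) / sum(b_raw))^2
  got <- crossover_distance(b, a)
  expect_lt(abs(log10(got) - log10(s_star)), 1 / 8)
  # exactly one sign change for normalized power laws
  r <- sign(log2(b$prob / a$prob))
  expect_equal(sum(r[-1] != r[-length(r)]), 1)
})

test_that("coarsen sums blocks, conserves counts and pools remainders", {
  b <- random_counts(4, 6)
  m <- cm1(b)
  expect_identical(coarsen(m, 1), m)
  c2 <- coarsen(m, 2)
  expect_equal(c2$blocks$chr1[1, 2], sum(b[1:2, 3:4]))
  expect_equal(c2$blocks$chr1[1, 1] + c2$blocks$chr1[2, 2] +
                 2 * c2$blocks$chr1[1, 2],
               sum(b))
  expect_equal(sum(c2$blocks$chr1), sum(b))   # exact conservation
  b5 <- random_counts(5, 7)
  c5 <- coarsen(cm1(b5), 2)
  expect_equal(dim(c5$blocks$chr1), c(2, 2))
  expect_true(c5$meta$coarsen_remainder)
  expect_equal(sum(c5$blocks$chr1), sum(b5))
  expect_equal(c5$blocks$chr1[2, 2], sum(b5[3:5, 3:5]))
})

test_that("differential matrix is zero for equal or proportional inputs and antisymmetric", {
  a <- ice_balance(cm1(random_counts(6, 8)), mask_quantile = 0)
  d0 <- differential_matrix(a, a)
  expect_equal(max(abs(d0$blocks$chr1)), 0)
  b2 <- a; b2$blocks$chr1 <- 2 * a$blocks$chr1
  d1 <- differential_matrix(a, b2)
  expect_equal(max(abs(d1$blocks$chr1)), 0, tolerance = 1e-12)
  b <- ice_balance(cm1(random_counts(6, 9)), mask_quantile = 0)
  dab <- differential_matrix(a, b)
  dba <- differential_matrix(b, a)
  expect_equal(dab$blocks$chr1, -dba$blocks$chr1)
  # hand oracle after shared depth normalization and pseudocount
  an <- depth_normalize(a); bn <- depth_normalize(b)
  eps <- dab$pseudocount
  expect_equal(dab$blocks$chr1[2, 5],
               log2((an$blocks$chr1[2, 5] + eps) / (bn$blocks$chr1[2, 5] + eps)))
})

test_that("symmetry is preserved across the matrix operations", {
  b <- random_counts(10, 10)
  m <- cm1(b)
  for (x in list(ice_balance(m, mask_quantile = 0)$blocks$chr1,
                 coarsen(m, 2)$blocks$chr1,
                 observed_over_expected(ice_balance(m, mask_quantile = 0))$blocks$chr1)) {
    expect_lte(max(abs(x - t(x)), na.rm = TRUE), 1e-9)
  }
})
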