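# shared fixture builders; everything is generated in code, no stored data

# single-chromosome genome of n bins at 100 kb
spec1 <- function(n, bin_size = 1e5, name = "chr1")
  genome_spec(name, n * bin_size, bin_size)

# contact matrix from one explicit symmetric block
cm1 <- function(block, bin_size = 1e5, ...) {
  n <- nrow(block)
  contact_matrix(spec1(n, bin_size), list(chr1 = block), ...)
}

# symmetric random count matrix with positive marginals
random_counts <- function(n, seed, lambda = 50) {
  set.seed(seed)
  x <- matrix(rpois(n * n, lambda), n, n)
  x <- x + t(x)
  diag(x) <- 0
  x
}

# matrix whose entries depend only on |i - j| (Toeplitz), value v(d)
toeplitz_matrix <- function(n, v) {
  d <- abs(row(diag(n)) - col(diag(n)))
  m <- matrix(0, n, n)
  m[d > 0] <- v(d[d > 0])
  m
}

# independent straightforward ICE iteration used as balancing oracle
ice_oracle <- function(w, max_iter = 1000, tol = 1e-12) {
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    db <- s / mean(s)
    w <- w / outer(db, db)
    if (max(abs(db - 1)) < tol) break
  }
  w / mean(rowSums(w))
}

# fraction of bins where recovered A/B labels match planted ones
label_agreement <- function(track, truth) {
  ok <- !is.na(track$label)
  mean(track$label[ok] == truth$labels[ok])
}
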