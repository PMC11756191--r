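#' ICE (iterative correction) balancing
#'
#' Removes per-bin coverage bias by iterative correction: each chromosome
#' block is repeatedly divided by the outer product of its relative row sums
#' until unmasked row sums agree to within `tol`. The accumulated per-bin
#' multiplicative bias is returned so raw counts can be recovered.
#'
#' Bins with zero marginal, or with marginal below the `mask_quantile`
#' quantile of the nonzero marginals, are masked before iteration: low-
#' coverage rows otherwise dominate the correction and blow up the bias.
#' Balanced values are scaled so the mean unmasked row sum equals 1.
#'
#' @param m raw-count `contact_matrix`.
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance on the maximum relative row-sum
#'   deviation (default 1e-5).
#' @param mask_quantile fraction of lowest nonzero marginals masked
#'   (default 0.02, the 2nd percentile).
#' @return balanced `contact_matrix` with `bias` and updated `mask`;
#'   `meta$ice_converged` is `FALSE` (with a warning) if `max_iter` was hit.
#' @export
ice_balance <- function(m, max_iter = 200, tol = 1e-5, mask_quantile = 0.02) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$balanced) stop("matrix is already balanced")
  spec <- m$spec
  off <- chrom_offsets(spec)
  mask <- m$mask
  bias <- rep(NA_real_, sum(spec$n_bins))
  # marginal-based mask rule, genome-wide
  marg <- unlist(lapply(spec$chrom_names, function(ch) rowSums(m$blocks[[ch]])),
                 use.names = FALSE)
  if (all(marg == 0)) stop("all-zero contact matrix cannot be balanced")
  nz <- marg[marg > 0]
  cut <- stats::quantile(nz, mask_quantile, names = FALSE)
  mask <- mask | marg == 0 | marg < cut
  blocks <- m$blocks
  converged <- TRUE
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    idx <- (off[[chrom]] + 1):(off[[chrom]] + n)
    keep <- !mask[idx]
    b <- blocks[[chrom]]
    b[!keep, ] <- 0
    b[, !keep] <- 0
    if (sum(keep) == 0L || sum(b) == 0) {
      mask[idx] <- TRUE
      blocks[[chrom]] <- b * 0
      next
    }
    w <- b[keep, keep, drop = FALSE]
    bi <- rep(1, sum(keep))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      s <- rowSums(w)
      db <- s / mean(s)
      db[db == 0] <- 1
      w <- w / outer(db, db)
      bi <- bi * db
      if (max(abs(db - 1)) < tol) { ok <- TRUE; break }
    }
    if (!ok) converged <- FALSE
    # scale so mean unmasked row sum is 1
    sc <- mean(rowSums(w))
    w <- w / sc
    bi <- bi * sqrt(sc)
    b[keep, keep] <- w
    blocks[[chrom]] <- (b + t(b)) / 2
    bias[idx][keep] <- bi
  }
  if (!converged)
    warning("ICE did not converge within max_iter; results flagged")
  contact_matrix(spec, blocks, balanced = TRUE, bias = bias, mask = mask,
                 meta = c(m$meta, list(ice_converged = converged,
                                       ice_tol = tol)))
}
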