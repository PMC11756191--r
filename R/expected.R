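#' Expected contact value by genomic separation
#'
#' Per chromosome, the mean balanced value over unmasked bin pairs at each
#' separation `d = 1 .. n-1` (in bins). The self-diagonal `d = 0` is always
#' excluded. Separations with no valid pair are `NA` (flagged missing).
#'
#' @param m balanced `contact_matrix`.
#' @return list of class `expected_profile`: per chromosome a numeric vector
#'   of length `n - 1`, element `d` being the mean at separation `d`.
#' @export
expected_by_distance <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  spec <- m$spec
  out <- list()
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    b <- m$blocks[[chrom]]
    keep <- !chrom_mask(m, chrom)
    prof <- rep(NA_real_, max(n - 1L, 0L))
    if (n >= 2L) {
      ij <- which(upper.tri(b), arr.ind = TRUE)
      valid <- keep[ij[, 1]] & keep[ij[, 2]]
      d <- ij[valid, 2] - ij[valid, 1]
      v <- b[ij][valid]
      if (length(d) > 0L) {
        s <- tapply(v, d, mean)
        prof[as.integer(names(s))] <- as.numeric(s)
      }
    }
    out[[chrom]] <- prof
  }
  structure(out, class = "expected_profile", bin_size = spec$bin_size)
}

#' Observed-over-expected transform
#'
#' Divides every entry by the chromosome's expected value at the same
#' separation, removing distance decay so compartment and domain structure
#' stand out. Entries at separations with missing expected values become
#' `NA`; masked rows/columns become `NA`.
#'
#' @param m balanced `contact_matrix`.
#' @param e matching [expected_by_distance()] profile (computed from `m` if
#'   omitted).
#' @return `contact_matrix` of O/E values (meta flag `oe = TRUE`).
#' @export
observed_over_expected <- function(m, e = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (is.null(e)) e <- expected_by_distance(m)
  spec <- m$spec
  blocks <- list()
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    b <- m$blocks[[chrom]]
    prof <- e[[chrom]]
    oe <- matrix(NA_real_, n, n)
    if (n >= 2L) {
      d <- abs(row(b) - col(b))
      ed <- matrix(NA_real_, n, n)
      sel <- d >= 1L
      ed[sel] <- prof[d[sel]]
      oe <- b / ed
      oe[!is.finite(oe)] <- NA_real_
    }
    keep <- !chrom_mask(m, chrom)
    oe[!keep, ] <- NA_real_
    oe[, !keep] <- NA_real_
    diag(oe) <- 0
    blocks[[chrom]] <- oe
  }
  out <- m
  out$blocks <- blocks
  out$meta$oe <- TRUE
  out
}
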