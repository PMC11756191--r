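#' Construct a contact-probability curve
#'
#' @param centers distance-bin centers in bp (log-spaced, increasing).
#' @param prob contact probability per distance bin; normalized so that,
#'   summed over all cis pairs, probabilities total 1.
#' @param n_pairs optional number of pairs contributing per distance bin.
#' @param balanced_input logical flag recording whether the source matrix
#'   was balanced.
#' @return object of class `contact_curve`.
#' @export
contact_curve <- function(centers, prob, n_pairs = NULL,
                          balanced_input = NA) {
  stopifnot(length(centers) == length(prob), !is.unsorted(centers))
  structure(list(centers = as.numeric(centers), prob = as.numeric(prob),
                 n_pairs = n_pairs, balanced_input = balanced_input),
            class = "contact_curve")
}

#' Contact probability as a function of genomic separation, P(s)
#'
#' Pools all cis bin pairs genome-wide, converts values to per-pair
#' probabilities (each pair's value divided by the total cis sum), and
#' reduces them to log-spaced distance bins by the geometric mean of the
#' positive per-pair probabilities in each bin. Pairs with zero counts are
#' excluded from the geometric mean (their fraction is retained in
#' `n_pairs` vs the zero count); empty distance bins are dropped.
#'
#' @param m `contact_matrix`, raw or balanced (recorded in the curve).
#' @param bins_per_decade number of log-spaced distance bins per decade
#'   (default 8).
#' @return a [contact_curve()].
#' @export
contact_probability_curve <- function(m, bins_per_decade = 8) {
  stopifnot(inherits(m, "contact_matrix"), bins_per_decade >= 1)
  spec <- m$spec
  dist_all <- numeric(0)
  val_all <- numeric(0)
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    b <- m$blocks[[chrom]]
    n <- spec$n_bins[k]
    if (n < 2L) next
    keep <- !chrom_mask(m, chrom)
    ij <- which(upper.tri(b), arr.ind = TRUE)
    valid <- keep[ij[, 1]] & keep[ij[, 2]]
    dist_all <- c(dist_all, (ij[valid, 2] - ij[valid, 1]) * spec$bin_size)
    val_all <- c(val_all, b[ij][valid])
  }
  if (length(val_all) == 0L || sum(val_all, na.rm = TRUE) <= 0)
    stop("no valid cis pairs to build a P(s) curve from")
  p <- val_all / sum(val_all, na.rm = TRUE)
  lo <- floor(log10(min(dist_all)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(dist_all)) * bins_per_decade) / bins_per_decade
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  grp <- findInterval(dist_all, edges, rightmost.closed = TRUE)
  centers <- sqrt(edges[-length(edges)] * edges[-1])
  gm <- tapply(p, grp, geometric_mean)
  np <- tapply(p, grp, length)
  used <- as.integer(names(gm))
  ok <- is.finite(gm)
  contact_curve(centers[used[ok]], as.numeric(gm[ok]),
                n_pairs = as.numeric(np[ok]),
                balanced_input = m$balanced)
}

#' Crossover distance between two P(s) curves
#'
#' The smallest separation at which `log2(a/b)` changes sign, linearly
#' interpolated in log10-distance between the flanking distance bins.
#' Mirrors the comparison of proximal vs distal contact probability between
#' two conditions: below the crossover one condition dominates, above it the
#' other does.
#'
#' @param a,b [contact_curve()] objects on identical distance bins.
#' @return crossover distance in bp, or `NA` if the log-ratio never changes
#'   sign.
#' @export
crossover_distance <- function(a, b) {
  stopifnot(inherits(a, "contact_curve"), inherits(b, "contact_curve"))
  shared <- intersect(signif(a$centers, 12), signif(b$centers, 12))
  ia <- match(shared, signif(a$centers, 12))
  ib <- match(shared, signif(b$centers, 12))
  if (length(shared) < 2L) stop("curves share fewer than 2 distance bins")
  r <- log2(a$prob[ia] / b$prob[ib])
  x <- log10(a$centers[ia])
  ok <- is.finite(r)
  r <- r[ok]; x <- x[ok]
  if (length(r) < 2L) return(NA_real_)
  nz <- which(sign(r) != 0)
  if (length(nz) < 2L || length(unique(sign(r[nz]))) == 1L)
    return(NA_real_)      # identical curves or one-sided ratio: no crossover
  k <- which(sign(r[nz[-1]]) != sign(r[nz[-length(nz)]]))[1]
  i <- nz[k]; j <- nz[k + 1]
  zero_between <- which(sign(r) == 0 & seq_along(r) > i & seq_along(r) < j)
  if (length(zero_between) > 0L) return(10^x[zero_between[1]])
  x0 <- x[i] + (x[j] - x[i]) * (0 - r[i]) / (r[j] - r[i])
  10^x0
}
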