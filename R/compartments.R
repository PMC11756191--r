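#' A/B compartment eigenvector (E1)
#'
#' Per chromosome, the compartment eigenvector of the Pearson correlation
#' matrix of the unmasked O/E rows: among the three leading eigenvectors,
#' the one most correlated (in absolute value) with the orientation track
#' (GC content, gene density, or the synthetic compartment indicator) is
#' taken — at weak compartment contrast the very first eigenvector can
#' instead track residual distance structure — then oriented so its
#' correlation with the track is non-negative and scaled to unit variance.
#' Bins with positive E1 are labelled A (active), negative B (inactive);
#' E1 of exactly zero and masked bins are `NA`.
#'
#' @param oe O/E `contact_matrix` (from [observed_over_expected()]).
#' @param orientation per-bin numeric track over the same bins.
#' @param min_bins minimum unmasked bins per chromosome (default 10);
#'   shorter chromosomes get an all-`NA` track with a warning.
#' @return data.frame with columns `chrom`, `bin` (1-based global), `E1`,
#'   `label` ("A"/"B"/`NA`).
#' @export
compartment_eigenvector <- function(oe, orientation, min_bins = 10) {
  stopifnot(inherits(oe, "contact_matrix"))
  spec <- oe$spec
  n_total <- sum(spec$n_bins)
  stopifnot(length(orientation) == n_total)
  off <- chrom_offsets(spec)
  e1 <- rep(NA_real_, n_total)
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    idx <- (off[[chrom]] + 1):(off[[chrom]] + n)
    keep <- which(!chrom_mask(oe, chrom))
    if (length(keep) < min_bins) {
      warning("chromosome ", chrom, " has fewer than ", min_bins,
              " unmasked bins; E1 set to NA")
      next
    }
    sub <- oe$blocks[[chrom]][keep, keep, drop = FALSE]
    diag(sub) <- NA_real_          # self-pairs carry no compartment signal
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    # zero-variance or all-missing rows yield all-NA correlation columns
    bad <- colMeans(is.na(cc)) > 0.5
    if (any(bad)) {
      keep <- keep[!bad]
      if (length(keep) < min_bins) {
        warning("chromosome ", chrom, " degenerate after filtering; E1 NA")
        next
      }
      cc <- cc[!bad, !bad, drop = FALSE]
    }
    cc[is.na(cc)] <- 0             # isolated missing pairs carry no weight
    cc <- (cc + t(cc)) / 2
    es <- eigen(cc, symmetric = TRUE)
    top <- order(es$values, decreasing = TRUE)[1:min(3, ncol(cc))]
    ori <- orientation[idx][keep]
    cors <- suppressWarnings(vapply(top, function(e)
      stats::cor(es$vectors[, e], ori), numeric(1)))
    cors[!is.finite(cors)] <- 0
    pick <- top[which.max(abs(cors))]
    v <- es$vectors[, pick]
    if (cors[which.max(abs(cors))] < 0) v <- -v
    sdv <- stats::sd(v)
    if (is.finite(sdv) && sdv > 0) v <- v / sdv
    e1[idx[keep]] <- v
  }
  bins <- bin_table(spec)
  label <- ifelse(is.na(e1) | e1 == 0, NA_character_,
                  ifelse(e1 > 0, "A", "B"))
  data.frame(chrom = bins$chrom, bin = seq_len(n_total), E1 = e1,
             label = label, stringsAsFactors = FALSE)
}

#' Classify per-bin compartment changes between two conditions
#'
#' Cross-tabulates the A/B labels of the two conditions into StableAA,
#' StableBB, SwitchAB (A in condition 1, B in condition 2) and SwitchBA.
#' Bins with a missing label in either condition are `NA`.
#'
#' @param t1,t2 tracks from [compartment_eigenvector()] on the same bins.
#' @return list with `table` (data.frame: bin, category) and `counts`
#'   (named category counts).
#' @export
classify_switches <- function(t1, t2) {
  stopifnot(nrow(t1) == nrow(t2))
  cat <- rep(NA_character_, nrow(t1))
  ok <- !is.na(t1$label) & !is.na(t2$label)
  cat[ok] <- paste0(ifelse(t1$label[ok] == t2$label[ok], "Stable", "Switch"),
                    t1$label[ok], t2$label[ok])
  counts <- table(factor(cat, levels = c("StableAA", "StableBB",
                                         "SwitchAB", "SwitchBA")))
  list(table = data.frame(bin = seq_len(nrow(t1)), chrom = t1$chrom,
                          category = cat, stringsAsFactors = FALSE),
       counts = as.integer(counts) |> stats::setNames(names(counts)))
}

#' Saddle plot: mean O/E stratified by compartment-eigenvector quantile
#'
#' Bins are ranked by E1 genome-wide; after discarding the extreme `trim`
#' fraction at each tail, the remainder is cut into `Q` equal-occupancy
#' groups (group 1 = most negative E1, i.e. strongest B; group Q =
#' strongest A). Cell (p, q) is the mean O/E over all unmasked cis bin
#' pairs with one bin in group p and the other in group q.
#'
#' @param oe O/E `contact_matrix`.
#' @param track E1 track from [compartment_eigenvector()].
#' @param Q number of quantile groups (default 20).
#' @param trim fraction trimmed from each E1 tail (default 0.02).
#' @return list of class `saddle_matrix` with `S` (Q x Q means), `counts`
#'   (pair counts), `Q`, `trim`.
#' @export
saddle <- function(oe, track, Q = 20, trim = 0.02) {
  stopifnot(inherits(oe, "contact_matrix"), Q >= 2, trim >= 0, trim < 0.5)
  spec <- oe$spec
  e1 <- track$E1
  grp <- rep(NA_integer_, length(e1))
  ok <- which(is.finite(e1) & !oe$mask)
  qs <- stats::quantile(e1[ok], c(trim, 1 - trim), names = FALSE)
  ok <- ok[e1[ok] >= qs[1] & e1[ok] <= qs[2]]
  r <- rank(e1[ok], ties.method = "first")
  grp[ok] <- pmin(Q, ceiling(r / (length(ok) / Q)))
  S <- matrix(0, Q, Q)
  N <- matrix(0L, Q, Q)
  off <- chrom_offsets(spec)
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    idx <- (off[[chrom]] + 1):(off[[chrom]] + n)
    g <- grp[idx]
    sel <- which(!is.na(g))
    if (length(sel) < 2) next
    b <- oe$blocks[[chrom]][sel, sel, drop = FALSE]
    gg <- g[sel]
    ut <- which(upper.tri(b), arr.ind = TRUE)
    v <- b[ut]
    fin <- is.finite(v)
    p <- gg[ut[fin, 1]]; q <- gg[ut[fin, 2]]; v <- v[fin]
    # accumulate both orderings so the saddle is symmetric by construction
    key <- c((q - 1L) * Q + p, (p - 1L) * Q + q)
    vv <- c(v, v)
    off_diag <- c(p != q, rep(TRUE, length(v)))
    ssum <- rowsum(vv[off_diag], key[off_diag])
    scnt <- tabulate(key[off_diag], nbins = Q * Q)
    kk <- as.integer(rownames(ssum))
    S[kk] <- S[kk] + ssum[, 1]
    N <- N + matrix(scnt, Q, Q)
  }
  M <- S / N
  M[N == 0] <- NA_real_
  structure(list(S = M, counts = N, Q = Q, trim = trim),
            class = "saddle_matrix")
}

#' Compartment interaction strengths from a saddle matrix
#'
#' AA strength is the mean of the top-E1 corner block (strong A with strong
#' A), BB the bottom corner, AB the mean of the two anti-diagonal corners.
#' The overall compartmentalization score is `log2(AA * BB / AB^2)`.
#'
#' @param s a `saddle_matrix`.
#' @param corner_frac fraction of the Q groups forming a corner
#'   (default 0.2; `Q * corner_frac >= 1` required).
#' @return list with `AA`, `BB`, `AB`, `overall`.
#' @export
compartment_strength <- function(s, corner_frac = 0.2) {
  stopifnot(inherits(s, "saddle_matrix"))
  k <- floor(s$Q * corner_frac)
  if (k < 1) stop("Q * corner_frac must be >= 1")
  lo <- seq_len(k)               # strongest B
  hi <- seq(s$Q - k + 1, s$Q)    # strongest A
  AA <- mean(s$S[hi, hi], na.rm = TRUE)
  BB <- mean(s$S[lo, lo], na.rm = TRUE)
  AB <- mean(c(s$S[lo, hi], s$S[hi, lo]), na.rm = TRUE)
  list(AA = AA, BB = BB, AB = AB, overall = log2(AA * BB / AB^2))
}

#' Differential saddle between two conditions
#'
#' Elementwise `log2(s1 / s2)`; swapping the arguments flips the sign.
#'
#' @param s1,s2 `saddle_matrix` objects with equal `Q`.
#' @return signed Q x Q matrix.
#' @export
differential_saddle <- function(s1, s2) {
  stopifnot(inherits(s1, "saddle_matrix"), inherits(s2, "saddle_matrix"),
            s1$Q == s2$Q)
  log2(s1$S / s2$S)
}
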