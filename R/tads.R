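#' Insulation score along each chromosome
#'
#' The raw score at bin `i` is the mean balanced contact over unmasked
#' pairs in the `w x w` diamond spanning the junction at the left edge of
#' bin `i` (rows `i-w .. i-1` against columns `i .. i+w-1`); a TAD boundary
#' between bins `i-1` and `i` therefore produces a minimum exactly at `i`.
#' The reported track is `log2(raw / geometric chromosome mean of raw)`
#' (geometric, to be robust to heavy-tailed rows), so a Toeplitz matrix has
#' a flat zero track on interior bins. Boundary strength at each bin is the
#' mean elevation of the two flanking `ceil(w/2)`-bin windows of the track
#' above the bin's own value (a delta-style prominence).
#'
#' @param m balanced `contact_matrix`.
#' @param w diamond half-width in bins (default 5, i.e. 500 kb at 100 kb
#'   resolution).
#' @return data.frame of class `insulation_track` with columns `chrom`,
#'   `bin` (1-based global), `score` (log2 track; `NA` near edges and at
#'   masked bins) and `strength`. Attribute `w` records the window.
#' @export
insulation_score <- function(m, w = 5) {
  stopifnot(inherits(m, "contact_matrix"), w >= 1)
  spec <- m$spec
  off <- chrom_offsets(spec)
  n_total <- sum(spec$n_bins)
  raw <- rep(NA_real_, n_total)
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    if (n <= 2 * w) {
      warning("chromosome ", chrom, " too short for window w = ", w)
      next
    }
    b <- m$blocks[[chrom]]
    keep <- !chrom_mask(m, chrom)
    bb <- b
    bb[!keep, ] <- NA_real_
    bb[, !keep] <- NA_real_
    for (i in (w + 1):(n - w + 1)) {
      win <- bb[(i - w):(i - 1), i:(i + w - 1), drop = FALSE]
      v <- win[is.finite(win)]
      raw[off[[chrom]] + i] <- if (length(v)) mean(v) else NA_real_
    }
    idx <- (off[[chrom]] + 1):(off[[chrom]] + n)
    raw[idx][!keep] <- NA_real_
  }
  score <- rep(NA_real_, n_total)
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    idx <- (off[[chrom]] + 1):(off[[chrom]] + spec$n_bins[k])
    g <- geometric_mean(raw[idx])
    if (is.finite(g) && g > 0) score[idx] <- log2(raw[idx] / g)
  }
  h <- max(1L, ceiling(w / 2))
  strength <- rep(NA_real_, n_total)
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    idx <- (off[[chrom]] + 1):(off[[chrom]] + n)
    sc <- score[idx]
    for (i in seq_len(n)) {
      if (!is.finite(sc[i])) next
      li <- max(1, i - h):(i - 1)
      ri <- (i + 1):min(n, i + h)
      if (i - h < 1 || i + h > n) next
      lm <- mean(sc[li], na.rm = TRUE)
      rm_ <- mean(sc[ri], na.rm = TRUE)
      if (is.finite(lm) && is.finite(rm_))
        strength[idx[i]] <- (lm - sc[i] + rm_ - sc[i]) / 2
    }
  }
  bins <- bin_table(spec)
  out <- data.frame(chrom = bins$chrom, bin = seq_len(n_total),
                    score = score, strength = strength,
                    stringsAsFactors = FALSE)
  attr(out, "w") <- w
  class(out) <- c("insulation_track", class(out))
  out
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are local minima of the insulation score with boundary
#' strength at least `strength_min`; a plateau of tied minima resolves to
#' its leftmost bin, and chromosome-edge bins (where the track is
#' undefined) are never called.
#'
#' @param track an [insulation_score()] result.
#' @param strength_min minimum boundary strength (default 0.1).
#' @return named list per chromosome of sorted 1-based local bin indices;
#'   index `b` means the boundary sits between bins `b-1` and `b`.
#' @export
call_boundaries <- function(track, strength_min = 0.1) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    sc <- track$score[track$chrom == chrom]
    st <- track$strength[track$chrom == chrom]
    found <- integer(0)
    # compare against nearest *defined* neighbors so isolated masked bins
    # do not hide a minimum
    def <- which(is.finite(sc))
    v <- sc[def]
    k <- 2L
    while (k <= length(v) - 1L) {
      if (v[k] < v[k - 1]) {
        j <- k
        while (j < length(v) && v[j + 1] == v[j]) j <- j + 1L
        if (j < length(v) && v[j + 1] > v[j]) {
          i <- def[k]                   # leftmost bin of the plateau
          if (is.finite(st[i]) && st[i] >= strength_min)
            found <- c(found, i)
        }
        k <- j + 1L
        next
      }
      k <- k + 1L
    }
    out[[chrom]] <- found
  }
  out
}

#' Segment chromosomes into TADs from called boundaries
#'
#' Consecutive boundaries (plus the chromosome ends) define half-open TAD
#' intervals. Intervals shorter than `min_tad` bins are merged into a
#' neighbor: the flanking boundary with the weaker insulation dip (higher
#' score) is dropped, or the left one when no track is supplied.
#'
#' @param boundaries named per-chromosome list of 1-based boundary bins
#'   (as from [call_boundaries()]).
#' @param spec the [genome_spec()].
#' @param min_tad minimum TAD length in bins (default 3).
#' @param track optional [insulation_score()] used to pick which boundary
#'   of an undersized interval to drop.
#' @return data.frame of class `tad_segmentation`: `chrom`, `start_bin`,
#'   `end_bin` (1-based, half-open), tiling each chromosome exactly.
#' @export
segment_tads <- function(boundaries, spec, min_tad = 3, track = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  off <- chrom_offsets(spec)
  rows <- list()
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    b <- sort(unique(boundaries[[chrom]] %||% integer(0)))
    stopifnot(all(b > 1), all(b <= n))
    repeat {
      cuts <- c(1L, b, n + 1L)
      len <- diff(cuts)
      small <- which(len < min_tad)
      if (length(small) == 0L || length(b) == 0L) break
      s <- small[1]
      left_b <- if (s > 1) cuts[s] else NA_integer_
      right_b <- if (s < length(cuts) - 1) cuts[s + 1] else NA_integer_
      drop <- if (is.na(left_b)) right_b
              else if (is.na(right_b)) left_b
              else if (!is.null(track)) {
                sl <- track$score[off[[chrom]] + left_b]
                sr <- track$score[off[[chrom]] + right_b]
                if (isTRUE(sr > sl)) right_b else left_b
              } else left_b
      b <- setdiff(b, drop)
    }
    cuts <- c(1L, b, n + 1L)
    rows[[chrom]] <- data.frame(chrom = chrom,
                                start_bin = cuts[-length(cuts)],
                                end_bin = cuts[-1],
                                stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, rows)
  rownames(seg) <- NULL
  class(seg) <- c("tad_segmentation", class(seg))
  attr(seg, "spec") <- spec
  seg
}

# interior boundaries implied by a segmentation, per chromosome
segmentation_boundaries <- function(seg) {
  out <- list()
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, ]
    out[[chrom]] <- s$start_bin[s$start_bin > 1]
  }
  out
}

#' Mean intra-TAD and inter-TAD (adjacent) contacts
#'
#' `intra` is the mean balanced value over unmasked pairs inside a TAD
#' (excluding the diagonal); `inter` the mean over pairs spanning two
#' adjacent TADs at separations no larger than the longest TAD, so both
#' averages cover a comparable distance range. `ratio = intra / inter`
#' (`NA` with `inter_zero = TRUE` if no inter contact exists).
#'
#' @param m balanced `contact_matrix`.
#' @param seg a [segment_tads()] result on the same bins.
#' @return list with `intra`, `inter`, `ratio`, `inter_zero`.
#' @export
intra_inter_ratio <- function(m, seg) {
  spec <- m$spec
  off <- chrom_offsets(spec)
  max_span <- max(seg$end_bin - seg$start_bin)
  intra_s <- intra_n <- inter_s <- inter_n <- 0
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    n <- spec$n_bins[k]
    b <- m$blocks[[chrom]]
    keep <- !chrom_mask(m, chrom)
    s <- seg[seg$chrom == chrom, ]
    tid <- rep(seq_len(nrow(s)), s$end_bin - s$start_bin)
    ij <- which(upper.tri(b), arr.ind = TRUE)
    valid <- keep[ij[, 1]] & keep[ij[, 2]]
    ij <- ij[valid, , drop = FALSE]
    v <- b[ij]
    ti <- tid[ij[, 1]]; tj <- tid[ij[, 2]]
    d <- ij[, 2] - ij[, 1]
    same <- ti == tj
    adj <- (tj == ti + 1L) & d <= max_span
    intra_s <- intra_s + sum(v[same]); intra_n <- intra_n + sum(same)
    inter_s <- inter_s + sum(v[adj]); inter_n <- inter_n + sum(adj)
  }
  intra <- if (intra_n > 0) intra_s / intra_n else NA_real_
  inter <- if (inter_n > 0) inter_s / inter_n else NA_real_
  inter_zero <- !is.na(inter) && inter == 0
  list(intra = intra, inter = inter,
       ratio = if (isTRUE(inter > 0)) intra / inter else NA_real_,
       inter_zero = inter_zero)
}

# bilinear rescale of a square matrix to target x target
bilinear_rescale <- function(S, target) {
  m <- nrow(S)
  if (m == target) return(S)
  u <- (seq_len(target) - 0.5) * m / target + 0.5
  u <- pmin(pmax(u, 1), m)
  lo <- floor(u); hi <- ceiling(u); fr <- u - lo
  out <- matrix(0, target, target)
  for (a in seq_len(target)) for (b2 in seq_len(target)) {
    out[a, b2] <-
      S[lo[a], lo[b2]] * (1 - fr[a]) * (1 - fr[b2]) +
      S[hi[a], lo[b2]] * fr[a] * (1 - fr[b2]) +
      S[lo[a], hi[b2]] * (1 - fr[a]) * fr[b2] +
      S[hi[a], hi[b2]] * fr[a] * fr[b2]
  }
  out
}

#' Aggregate TAD analysis (average rescaled domain)
#'
#' Each TAD at least 3 bins long, extended by a half-TAD flank on each side
#' (TADs whose flank would leave the chromosome are skipped), is cut out of
#' the O/E map, rescaled to `target_size x target_size` by bilinear
#' interpolation, and averaged elementwise across TADs. Missing entries are
#' carried through the interpolation as zero weight is not applied; they are
#' excluded by the elementwise mean.
#'
#' @param oe O/E `contact_matrix`.
#' @param seg a [segment_tads()] result.
#' @param target_size output side length in pixels (default 30, >= 5).
#' @return list with `A` (the aggregate matrix), `n_tads` used.
#' @export
aggregate_tads <- function(oe, seg, target_size = 30) {
  stopifnot(target_size >= 5)
  spec <- oe$spec
  acc <- matrix(0, target_size, target_size)
  cnt <- matrix(0, target_size, target_size)
  used <- 0L
  for (r in seq_len(nrow(seg))) {
    chrom <- seg$chrom[r]
    n <- spec$n_bins[match(chrom, spec$chrom_names)]
    s <- seg$start_bin[r]; e <- seg$end_bin[r]
    L <- e - s
    if (L < 3) next
    fl <- floor(L / 2)
    a <- s - fl; b2 <- e + fl - 1L
    if (a < 1 || b2 > n) next
    S <- oe$blocks[[chrom]][a:b2, a:b2, drop = FALSE]
    S[!is.finite(S)] <- NA_real_
    R <- bilinear_rescale(S, target_size)
    ok <- is.finite(R)
    acc[ok] <- acc[ok] + R[ok]
    cnt[ok] <- cnt[ok] + 1
    used <- used + 1L
  }
  A <- acc / cnt
  A[cnt == 0] <- NA_real_
  A <- (A + t(A)) / 2
  list(A = A, n_tads = used)
}

#' Detect TAD fusions between two segmentations
#'
#' A condition-2 TAD is a fusion if (i) both its endpoints match a
#' condition-1 boundary or chromosome end within `tol` bins, and (ii) it
#' contains at least one condition-1 interior boundary that has no
#' condition-2 boundary within `tol` (a lost boundary). One event is
#' emitted per lost boundary, carrying the enclosing condition-2 interval
#' and the condition-1 intervals it merged.
#'
#' Optionally, events can be corroborated by the physical signature of a
#' fusion — a rise of the insulation score at the lost boundary: with
#' `min_delta` set and both insulation tracks supplied, events whose score
#' did not increase by at least `min_delta` (or whose score is undefined in
#' either condition) are discarded. This suppresses apparent losses caused
#' by a boundary's called position wobbling beyond `tol` while the boundary
#' itself persists.
#'
#' @param seg1,seg2 [segment_tads()] results on the same genome (condition
#'   1 = baseline, condition 2 = derived).
#' @param tol matching tolerance in bins (default 1).
#' @param track1,track2 optional [insulation_score()] tracks for the two
#'   conditions (required when `min_delta` is set).
#' @param min_delta optional minimum insulation increase (condition 2 minus
#'   condition 1, log2 units) at the lost boundary; `NULL` (default)
#'   disables corroboration.
#' @return data.frame of class `tad_fusion_events`: `chrom`,
#'   `lost_boundary`, `fused_start`, `fused_end` (1-based half-open bins),
#'   `n_merged` (condition-1 TADs merged).
#' @export
detect_fusions <- function(seg1, seg2, tol = 1, track1 = NULL,
                           track2 = NULL, min_delta = NULL) {
  b1 <- segmentation_boundaries(seg1)
  b2 <- segmentation_boundaries(seg2)
  rows <- list()
  for (chrom in unique(seg2$chrom)) {
    s1 <- seg1[seg1$chrom == chrom, ]
    s2 <- seg2[seg2$chrom == chrom, ]
    anchors1 <- c(1L, b1[[chrom]], max(s1$end_bin))  # boundaries + chrom ends
    for (r in seq_len(nrow(s2))) {
      st <- s2$start_bin[r]; en <- s2$end_bin[r]
      if (min(abs(anchors1 - st)) > tol) next
      if (min(abs(anchors1 - en)) > tol) next
      inside <- b1[[chrom]][b1[[chrom]] > st & b1[[chrom]] < en]
      if (length(inside) == 0) next
      lost <- inside[vapply(inside, function(bb)
        length(b2[[chrom]]) == 0 || min(abs(b2[[chrom]] - bb)) > tol,
        logical(1))]
      if (length(lost) == 0) next
      merged <- s1[s1$end_bin > st & s1$start_bin < en, , drop = FALSE]
      for (bb in lost)
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = chrom, lost_boundary = bb,
                     fused_start = st, fused_end = en,
                     n_merged = nrow(merged), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chrom = character(0), lost_boundary = integer(0),
                         fused_start = integer(0), fused_end = integer(0),
                         n_merged = integer(0))
  if (!is.null(min_delta) && nrow(out) > 0) {
    stopifnot(!is.null(track1), !is.null(track2))
    spec <- attr(seg1, "spec")
    off <- chrom_offsets(spec)
    g <- off[out$chrom] + out$lost_boundary
    delta <- track2$score[g] - track1$score[g]
    out <- out[!is.na(delta) & delta >= min_delta, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("tad_fusion_events", class(out))
  out
}
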