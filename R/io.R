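#' Write a contact matrix as bins + pixels text tables
#'
#' The cooler-style COO text dialect: a bins table (`chrom`, `start`,
#' `end`; 0-based half-open bp) and a pixels table (`bin1_id`, `bin2_id`,
#' `count`) storing the upper triangle (`bin1_id <= bin2_id`) of nonzero
#' cis values with 0-based global bin ids. Values are written at full
#' precision so a write/read round trip is lossless.
#'
#' @param m a `contact_matrix`.
#' @param bins_path,pixels_path output TSV paths.
#' @return invisibly, the number of pixels written.
#' @export
write_contact_table <- function(m, bins_path, pixels_path) {
  bins <- bin_table(m$spec)
  utils::write.table(bins[, c("chrom", "start", "end")], bins_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  off <- chrom_offsets(m$spec)
  px <- list()
  for (k in seq_along(m$spec$chrom_names)) {
    chrom <- m$spec$chrom_names[k]
    b <- m$blocks[[chrom]]
    ij <- which(upper.tri(b, diag = TRUE) & b != 0 & is.finite(b),
                arr.ind = TRUE)
    if (nrow(ij) == 0) next
    px[[chrom]] <- data.frame(bin1_id = off[[chrom]] + ij[, 1] - 1L,
                              bin2_id = off[[chrom]] + ij[, 2] - 1L,
                              count = b[ij])
  }
  px <- if (length(px)) do.call(rbind, px)
        else data.frame(bin1_id = integer(0), bin2_id = integer(0),
                        count = numeric(0))
  px <- px[order(px$bin1_id, px$bin2_id), ]
  fmt <- px
  fmt$count <- formatC(px$count, format = "g", digits = 17)
  utils::write.table(fmt, pixels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(nrow(px))
}

#' Read a contact matrix from bins + pixels text tables
#'
#' Validates the bins table (sorted, uniform width, half-open tiling),
#' accepts upper-triangle or mixed-triangle pixel storage, sums duplicate
#' pixels (including `(i, j)` alongside `(j, i)`), drops trans pixels with
#' a note, and materializes symmetric per-chromosome blocks.
#'
#' @param bins_path,pixels_path input TSV paths.
#' @return a raw `contact_matrix`.
#' @export
read_contact_table <- function(bins_path, pixels_path) {
  bins <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)))
  widths <- unique(bins$end - bins$start)
  if (length(widths) != 1L)
    stop("non-uniform bin widths in bins table: ",
         paste(widths, collapse = ", "))
  ord <- order(match(bins$chrom, unique(bins$chrom)), bins$start)
  if (!identical(ord, seq_len(nrow(bins))))
    stop("bins table is not sorted by (chrom, start)")
  chroms <- unique(bins$chrom)
  lengths <- vapply(chroms, function(ch) max(bins$end[bins$chrom == ch]),
                    numeric(1))
  spec <- genome_spec(chroms, lengths, widths)
  if (nrow(bins) != sum(spec$n_bins) ||
      any(bins$start != bin_table(spec)$start))
    stop("bins table does not tile its chromosomes")
  px <- utils::read.table(pixels_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("bin1_id", "bin2_id", "count") %in% names(px)))
  n_total <- nrow(bins)
  bad <- px$bin1_id < 0 | px$bin1_id >= n_total |
         px$bin2_id < 0 | px$bin2_id >= n_total
  if (any(bad))
    stop("pixel line ", which(bad)[1] + 1L, ": bin id out of range")
  ch1 <- bins$chrom[px$bin1_id + 1L]
  ch2 <- bins$chrom[px$bin2_id + 1L]
  trans <- ch1 != ch2
  if (any(trans))
    message(sum(trans), " trans pixel(s) dropped (cis-only model)")
  px <- px[!trans, , drop = FALSE]
  off <- chrom_offsets(spec)
  blocks <- list()
  for (k in seq_along(chroms)) {
    chrom <- chroms[k]
    n <- spec$n_bins[k]
    blocks[[chrom]] <- matrix(0, n, n)
  }
  chx <- bins$chrom[px$bin1_id + 1L]
  for (k in seq_along(chroms)) {
    chrom <- chroms[k]
    sel <- chx == chrom
    if (!any(sel)) next
    i <- px$bin1_id[sel] - off[[chrom]] + 1L
    j <- px$bin2_id[sel] - off[[chrom]] + 1L
    lo <- pmin(i, j); hi <- pmax(i, j)
    b <- blocks[[chrom]]
    # duplicate and mirrored pixels sum
    agg <- rowsum(px$count[sel], paste(lo, hi))
    key <- do.call(rbind, strsplit(rownames(agg), " "))
    ii <- as.integer(key[, 1]); jj <- as.integer(key[, 2])
    b[cbind(ii, jj)] <- agg[, 1]
    b[cbind(jj, ii)] <- agg[, 1]
    blocks[[chrom]] <- b
  }
  contact_matrix(spec, blocks)
}

#' Write a per-bin track as bedGraph
#'
#' @param track numeric per-bin vector over the genome's bins (NAs are
#'   skipped).
#' @param spec the [genome_spec()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, spec, path) {
  bins <- bin_table(spec)
  stopifnot(length(track) == nrow(bins))
  ok <- is.finite(track)
  df <- data.frame(bins$chrom[ok], bins$start[ok], bins$end[ok],
                   formatC(track[ok], format = "g", digits = 17))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(sum(ok))
}

#' Read a bedGraph into a per-bin track
#'
#' @param path bedGraph path (chrom, start, end, value; no header).
#' @param spec the [genome_spec()] whose bins the track is matched to.
#' @return numeric per-bin vector (`NA` where no record covers the bin).
#' @export
read_bedgraph <- function(path, spec) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  bins <- bin_table(spec)
  key <- paste(bins$chrom, bins$start)
  out <- rep(NA_real_, nrow(bins))
  idx <- match(paste(df$chrom, df$start), key)
  ok <- !is.na(idx)
  out[idx[ok]] <- df$value[ok]
  out
}

#' Write TAD intervals (or boundaries) as BED
#'
#' @param seg a [segment_tads()] result.
#' @param spec the [genome_spec()].
#' @param path output BED path (0-based half-open; name = TAD id).
#' @export
write_tads_bed <- function(seg, spec, path) {
  df <- data.frame(seg$chrom,
                   (seg$start_bin - 1) * spec$bin_size,
                   (seg$end_bin - 1) * spec$bin_size,
                   sprintf("tad_%04d", seq_len(nrow(seg))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}

#' Write / read a DEG table
#'
#' @param degs DEG data.frame (`gene`, `chrom`, `tss`, `log2fc`, `padj`,
#'   `direction`).
#' @param path TSV path.
#' @export
write_deg_table <- function(degs, path) {
  utils::write.table(degs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(nrow(degs))
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "log2fc", "padj", "direction")
  stopifnot(all(need %in% names(df)))
  bad <- (df$log2fc > 0 & df$direction != "up") |
         (df$log2fc < 0 & df$direction != "down")
  if (any(bad)) stop("direction inconsistent with log2fc sign at line ",
                     which(bad)[1] + 1L)
  if (any(df$padj < 0 | df$padj > 1)) stop("padj outside [0, 1]")
  df
}

#' Serialize a planted truth to JSON (and back)
#'
#' @param truth a `planted_truth`.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  x <- list(chrom_names = truth$spec$chrom_names,
            chrom_lengths = truth$spec$chrom_lengths,
            bin_size = truth$spec$bin_size,
            labels = truth$labels,
            boundaries = truth$boundaries,
            alpha = truth$alpha, delta_c = truth$delta_c,
            delta_t = truth$delta_t, depth = truth$depth,
            bb_boost = truth$bb_boost,
            fusion_events = truth$fusion_events,
            switch_bins = truth$switch_bins,
            seed = truth$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- genome_spec(x$chrom_names, x$chrom_lengths, x$bin_size)
  bnd <- lapply(x$boundaries, as.integer)
  if (length(bnd) == 0) bnd <- stats::setNames(list(), character(0))
  fe <- as.data.frame(x$fusion_events)
  if (nrow(fe) == 0) fe <- data.frame(chrom = character(0),
                                      boundary = integer(0))
  sw <- as.data.frame(x$switch_bins)
  if (nrow(sw) == 0) sw <- data.frame(bin = integer(0),
                                      direction = character(0))
  structure(list(spec = spec, labels = x$labels, boundaries = bnd,
                 alpha = x$alpha, delta_c = x$delta_c, delta_t = x$delta_t,
                 depth = x$depth, bb_boost = x$bb_boost %||% 0,
                 fusion_events = fe, switch_bins = sw,
                 seed = as.integer(x$seed)),
            class = "planted_truth")
}

#' Write a P(s) curve or saddle matrix as TSV
#'
#' @param curve a [contact_curve()].
#' @param path output path.
#' @export
write_curve_tsv <- function(curve, path) {
  df <- data.frame(distance_bp = curve$centers,
                   prob = formatC(curve$prob, format = "g", digits = 17))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(df))
}

#' @rdname write_curve_tsv
#' @param s a `saddle_matrix` (for `write_saddle_tsv`).
#' @export
write_saddle_tsv <- function(s, path) {
  utils::write.table(s$S, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(s$Q)
}
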