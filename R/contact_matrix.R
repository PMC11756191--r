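#' Construct a cis contact matrix
#'
#' Container for per-chromosome symmetric contact maps over a shared bin
#' table. Only within-chromosome (cis) contacts are represented; the
#' whole-genome view is a block-diagonal mosaic of the cis blocks.
#'
#' @param spec a [genome_spec()].
#' @param blocks named list (one per chromosome) of square symmetric numeric
#'   matrices of raw counts or balanced values (simulated matrices carry a
#'   zero diagonal; coarsened ones keep within-coarse-bin sums on it).
#' @param balanced logical; `TRUE` once [ice_balance()] has been applied.
#' @param bias per-bin multiplicative bias vector (present iff balanced).
#' @param mask logical per-bin vector, `TRUE` for bins excluded from
#'   analysis; masked rows/columns are zeroed.
#' @param meta free-form list of provenance notes.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(spec, blocks, balanced = FALSE, bias = NULL,
                           mask = NULL, meta = list()) {
  stopifnot(inherits(spec, "genome_spec"))
  stopifnot(identical(sort(names(blocks)), sort(spec$chrom_names)))
  blocks <- blocks[spec$chrom_names]
  n_total <- sum(spec$n_bins)
  if (is.null(mask)) mask <- rep(FALSE, n_total)
  stopifnot(length(mask) == n_total)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    n <- spec$n_bins[k]
    if (!is.matrix(b) || nrow(b) != n || ncol(b) != n)
      stop("block for ", spec$chrom_names[k], " is not ", n, "x", n)
    if (any(b < 0, na.rm = TRUE)) stop("negative contact values")
    asym <- max(abs(b - t(b)), na.rm = TRUE)
    if (is.finite(asym) && asym > 1e-9)
      stop("block for ", spec$chrom_names[k], " is asymmetric (", asym, ")")
    blocks[[k]] <- b
  }
  structure(list(spec = spec, blocks = blocks, balanced = balanced,
                 bias = bias, mask = mask, meta = meta),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d chrom(s), %d bins @ %g bp, %s, %d masked\n",
              length(x$spec$chrom_names), sum(x$spec$n_bins),
              x$spec$bin_size, if (x$balanced) "balanced" else "raw",
              sum(x$mask)))
  invisible(x)
}

# logical mask restricted to one chromosome (local indexing)
chrom_mask <- function(m, chrom) {
  off <- chrom_offsets(m$spec)[[chrom]]
  n <- m$spec$n_bins[match(chrom, m$spec$chrom_names)]
  m$mask[(off + 1):(off + n)]
}

#' Total cis contact sum over unmasked bin pairs
#'
#' @param m a `contact_matrix`.
#' @return numeric scalar; each unordered pair counted once.
#' @export
cis_total <- function(m) {
  tot <- 0
  for (chrom in m$spec$chrom_names) {
    b <- m$blocks[[chrom]]
    keep <- !chrom_mask(m, chrom)
    bb <- b[keep, keep, drop = FALSE]
    tot <- tot + sum(bb[upper.tri(bb)], na.rm = TRUE)
  }
  tot
}

#' Scale two matrices to equal sequencing depth
#'
#' Divides every entry by the matrix's total unmasked cis sum so both
#' conditions sit on a common scale before any differential computation.
#'
#' @param m a `contact_matrix`.
#' @param target total unmasked cis sum after scaling (default 1).
#' @return rescaled `contact_matrix`.
#' @export
depth_normalize <- function(m, target = 1) {
  tot <- cis_total(m)
  if (tot <= 0) stop("cannot depth-normalize an all-zero matrix")
  m$blocks <- lapply(m$blocks, function(b) b * (target / tot))
  m$meta$depth_normalized <- TRUE
  m
}

#' Coarsen a contact matrix to a lower resolution
#'
#' Sums counts within `factor` x `factor` blocks, e.g. to turn 100 kb
#' working-resolution maps into the 1 Mb whole-genome overview. When a
#' chromosome's bin count is not a multiple of `factor` the remainder bins
#' are pooled into the final coarse bin (recorded in `meta$coarsen_remainder`)
#' rather than erroring.
#'
#' @param m a `contact_matrix` (raw counts).
#' @param factor integer >= 1; number of fine bins per coarse bin.
#' @return a `contact_matrix` at the coarser resolution. Total counts are
#'   conserved exactly.
#' @export
coarsen <- function(m, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(m)
  spec <- m$spec
  n_coarse <- pmax(1L, spec$n_bins %/% factor)
  # coarse spec keeps exact divisibility by construction: lengths rounded to
  # the coarse grid; remainder pooling is a property of the values only
  coarse_spec <- genome_spec(spec$chrom_names,
                             n_coarse * spec$bin_size * factor,
                             spec$bin_size * factor)
  blocks <- list()
  mask_out <- logical(0)
  for (k in seq_along(spec$chrom_names)) {
    chrom <- spec$chrom_names[k]
    b <- m$blocks[[chrom]]
    n <- spec$n_bins[k]
    nc <- n_coarse[k]
    grp <- pmin(((seq_len(n) - 1L) %/% factor) + 1L, nc)
    agg <- rowsum(b, grp)                 # sum rows within coarse groups
    agg <- t(rowsum(t(agg), grp))         # then columns
    agg <- (agg + t(agg)) / 2             # exact symmetry against fp order
    blocks[[chrom]] <- agg
    cm <- chrom_mask(m, chrom)
    mask_out <- c(mask_out, as.vector(tapply(cm, grp, all)))
  }
  contact_matrix(coarse_spec, blocks, balanced = m$balanced,
                 mask = unname(mask_out),
                 meta = c(m$meta, list(coarsen_factor = factor,
                                       coarsen_remainder = any(spec$n_bins %% factor != 0))))
}

#' Differential (log-ratio) matrix between two conditions
#'
#' Depth-normalizes both balanced matrices to equal unmasked cis totals, then
#' forms `log2((a + eps) / (b + eps))` entrywise. Swapping the arguments
#' flips the sign exactly. Bins masked in either input are masked out.
#'
#' @param a,b balanced `contact_matrix` objects on the same bin table.
#' @param pseudocount `eps`; default `1e-6` times the mean unmasked entry of
#'   the two depth-normalized matrices (shared by both, preserving
#'   antisymmetry).
#' @return list with `blocks` (named list of signed matrices), `mask`,
#'   `pseudocount` and the `genome_spec`.
#' @export
differential_matrix <- function(a, b, pseudocount = NULL) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (!identical(a$spec[c("chrom_names", "n_bins", "bin_size")],
                 b$spec[c("chrom_names", "n_bins", "bin_size")]))
    stop("conditions are on different bin tables")
  if (!a$balanced || !b$balanced)
    stop("differential_matrix expects balanced matrices")
  mask <- a$mask | b$mask
  a <- depth_normalize(a); b <- depth_normalize(b)
  if (is.null(pseudocount)) {
    vals <- c(unlist(lapply(a$spec$chrom_names, function(ch) {
      keep <- !mask[(chrom_offsets(a$spec)[[ch]] + 1):(chrom_offsets(a$spec)[[ch]] + a$spec$n_bins[match(ch, a$spec$chrom_names)])]
      c(a$blocks[[ch]][keep, keep], b$blocks[[ch]][keep, keep])
    })))
    pseudocount <- 1e-6 * mean(vals)
  }
  blocks <- list()
  for (chrom in a$spec$chrom_names) {
    d <- log2((a$blocks[[chrom]] + pseudocount) /
              (b$blocks[[chrom]] + pseudocount))
    keep <- !mask[(chrom_offsets(a$spec)[[chrom]] + 1):(chrom_offsets(a$spec)[[chrom]] + a$spec$n_bins[match(chrom, a$spec$chrom_names)])]
    d[!keep, ] <- NA_real_
    d[, !keep] <- NA_real_
    diag(d) <- 0
    blocks[[chrom]] <- d
  }
  list(spec = a$spec, blocks = blocks, mask = mask, pseudocount = pseudocount)
}
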