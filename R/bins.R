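#' Define a genome for binned contact-map analysis
#'
#' A genome specification fixes the chromosome names, their lengths in bp and
#' the bin size (resolution). Chromosome lengths must be exact multiples of
#' the bin size: partial terminal bins are rejected rather than padded, so
#' that every bin has identical width and half-open coordinates
#' `[start, end)` tile each chromosome exactly.
#'
#' @param chrom_names character vector of chromosome labels.
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (e.g. `1e5` for the 100 kb working
#'   resolution, `1e6` for a whole-genome overview).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_names, chrom_lengths, bin_size) {
  stopifnot(length(chrom_names) == length(chrom_lengths),
            length(chrom_names) >= 1L)
  bin_size <- as.numeric(bin_size)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (bin_size <= 0) stop("bin_size must be positive")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (any(chrom_lengths %% bin_size != 0))
    stop("every chromosome length must be a multiple of bin_size ",
         "(partial terminal bins are not supported)")
  if (anyDuplicated(chrom_names)) stop("duplicate chromosome names")
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = chrom_lengths,
         bin_size = bin_size,
         n_bins = as.integer(chrom_lengths / bin_size)),
    class = "genome_spec")
}

#' Bin table for a genome specification
#'
#' Expands a [genome_spec()] into the per-bin table shared by all matrices
#' and tracks: one row per bin with chromosome, half-open bp interval and a
#' 0-based global bin id (the id convention of the bins/pixels text format).
#'
#' @param spec a `genome_spec`.
#' @return data.frame with columns `chrom`, `start`, `end`, `bin_id`.
#' @export
bin_table <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  chrom <- rep(spec$chrom_names, spec$n_bins)
  local <- unlist(lapply(spec$n_bins, function(n) seq_len(n) - 1L),
                  use.names = FALSE)
  data.frame(chrom = chrom,
             start = local * spec$bin_size,
             end = (local + 1) * spec$bin_size,
             bin_id = seq_along(chrom) - 1L,
             stringsAsFactors = FALSE)
}

# offset (0-based global id of a chromosome's first bin) per chromosome
chrom_offsets <- function(spec) {
  off <- cumsum(c(0L, spec$n_bins))[seq_along(spec$n_bins)]
  names(off) <- spec$chrom_names
  off
}
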