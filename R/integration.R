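#' Map gene TSSs to genomic bins
#'
#' Each gene is assigned to the unique bin whose half-open interval
#' `[start, end)` contains its TSS (so a TSS exactly on a bin edge belongs
#' to the downstream bin). Genes on chromosomes absent from the bin table
#' are skipped with a warning and counted.
#'
#' @param degs data.frame with at least `gene`, `chrom`, `tss`.
#' @param spec the [genome_spec()].
#' @return list with `bin` (named integer vector of 1-based global bin ids
#'   for mapped genes) and `n_skipped`.
#' @export
map_genes_to_bins <- function(degs, spec) {
  stopifnot(inherits(spec, "genome_spec"))
  off <- chrom_offsets(spec)
  known <- degs$chrom %in% spec$chrom_names
  if (any(!known))
    warning(sum(!known), " gene(s) on unknown chromosomes skipped")
  d <- degs[known, , drop = FALSE]
  if (nrow(d) == 0)
    return(list(bin = stats::setNames(integer(0), character(0)),
                n_skipped = sum(!known)))
  n_chrom <- spec$n_bins[match(d$chrom, spec$chrom_names)]
  local <- floor(d$tss / spec$bin_size) + 1L
  bad <- local < 1L | local > n_chrom
  if (any(bad)) {
    warning(sum(bad), " gene(s) with TSS outside the chromosome skipped")
    d <- d[!bad, , drop = FALSE]
    local <- local[!bad]
  }
  bin <- off[d$chrom] + local
  list(bin = stats::setNames(as.integer(bin), d$gene),
       n_skipped = sum(!known) + sum(bad))
}

#' Classify differentially expressed genes by chromatin-structure context
#'
#' Each mapped gene falls into exactly one category: `boundary` if its bin
#' lies within `flank` bins of any TAD boundary in the supplied boundary
#' set (by default the union over both conditions), else `merged_tad` if
#' its bin lies strictly inside a fused-TAD interval (the fusion interval
#' minus its two terminal bins), else `other`. Boundary takes precedence so
#' the categories partition the gene set. Genes with adjusted p >= 0.05 are
#' dropped (the input is expected pre-filtered; the filter is re-asserted)
#' and the dropped count reported.
#'
#' @param degs DEG data.frame (`gene`, `chrom`, `tss`, `log2fc`, `padj`,
#'   `direction`).
#' @param spec the [genome_spec()].
#' @param boundary_bins integer vector of 1-based global boundary bins
#'   (union of both conditions, from segmentations or planted truth).
#' @param fusions a [detect_fusions()] table (or any data.frame with
#'   `chrom`, `fused_start`, `fused_end`).
#' @param flank boundary flank in bins (default 1).
#' @return list of class `deg_classification`: `table` (gene, bin,
#'   direction, category), `fractions` (boundary fraction among all / up /
#'   down genes, and merged-TAD fractions), `upg_tad` / `dwg_tad` gene
#'   lists, `n_dropped_padj`, `n_skipped`.
#' @export
classify_degs <- function(degs, spec, boundary_bins, fusions, flank = 1) {
  keep <- degs$padj < 0.05
  n_dropped <- sum(!keep)
  degs <- degs[keep, , drop = FALSE]
  mp <- map_genes_to_bins(degs, spec)
  degs <- degs[degs$gene %in% names(mp$bin), , drop = FALSE]
  bin <- mp$bin[degs$gene]
  n_total <- sum(spec$n_bins)
  bnd <- unique(unlist(lapply(boundary_bins, function(b)
    seq(b - flank, b + flank))))
  bnd <- bnd[bnd >= 1 & bnd <= n_total]
  off <- chrom_offsets(spec)
  merged <- integer(0)
  if (nrow(fusions) > 0) {
    fu <- unique(fusions[, c("chrom", "fused_start", "fused_end")])
    for (r in seq_len(nrow(fu))) {
      s <- fu$fused_start[r]; e <- fu$fused_end[r]
      if (e - s > 2)
        merged <- c(merged, off[[fu$chrom[r]]] + seq(s + 1L, e - 2L))
    }
    merged <- sort(unique(merged))
  }
  category <- ifelse(bin %in% bnd, "boundary",
                     ifelse(bin %in% merged, "merged_tad", "other"))
  tab <- data.frame(gene = degs$gene, bin = as.integer(bin),
                    direction = degs$direction, category = category,
                    stringsAsFactors = FALSE)
  frac <- function(sel, cat) {
    if (sum(sel) == 0) return(NA_real_)
    mean(tab$category[sel] == cat)
  }
  up <- tab$direction == "up"; dn <- tab$direction == "down"
  fractions <- c(
    boundary_all = frac(rep(TRUE, nrow(tab)), "boundary"),
    boundary_up = frac(up, "boundary"),
    boundary_down = frac(dn, "boundary"),
    merged_all = frac(rep(TRUE, nrow(tab)), "merged_tad"),
    merged_up = frac(up, "merged_tad"),
    merged_down = frac(dn, "merged_tad"))
  structure(list(table = tab, fractions = fractions,
                 upg_tad = tab$gene[up & tab$category == "merged_tad"],
                 dwg_tad = tab$gene[dn & tab$category == "merged_tad"],
                 boundary_bins = bnd, merged_bins = merged,
                 n_dropped_padj = n_dropped, n_skipped = mp$n_skipped),
            class = "deg_classification")
}

# 2x2 odds ratio with Haldane 0.5 correction when any cell is zero,
# plus a Wald 95% CI on the log odds
odds_ratio <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5
                              c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(or = or, lo = exp(log(or) - 1.96 * se), hi = exp(log(or) + 1.96 * se))
}

#' Enrichment tests for structural categories by gene direction
#'
#' For each direction (up/down) and structural category (boundary,
#' merged_tad), tests whether genes of that direction are over-represented
#' in the category relative to the remaining classified genes: odds ratio
#' with Haldane correction, upper-tail hypergeometric p, and
#' Benjamini-Hochberg q across the emitted tables.
#'
#' @param cls a [classify_degs()] result (the background universe is the
#'   full classified gene set).
#' @return data.frame with `direction`, `category`, cell counts `a`-`d`
#'   (a = direction genes in category), `or`, `or_lo`, `or_hi`, `p`, `q`.
#' @export
enrichment_test <- function(cls) {
  tab <- cls$table
  rows <- list()
  for (dir in c("up", "down")) for (cat in c("boundary", "merged_tad")) {
    in_dir <- tab$direction == dir
    in_cat <- tab$category == cat
    a <- sum(in_dir & in_cat); b <- sum(in_dir & !in_cat)
    c2 <- sum(!in_dir & in_cat); d <- sum(!in_dir & !in_cat)
    or <- odds_ratio(a, b, c2, d)
    # P(X >= a) drawing the direction genes from the classified universe
    p <- stats::phyper(a - 1, a + c2, b + d, a + b, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(direction = dir, category = cat, a = a, b = b, c = c2,
                 d = d, or = or[["or"]], or_lo = or[["lo"]],
                 or_hi = or[["hi"]], p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
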