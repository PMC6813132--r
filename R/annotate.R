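## CpG genomic-context annotation and enrichment statistics.

#' Annotate CpG sites by their relation to CpG islands
#'
#' Categories are mutually exclusive and assigned by minimal distance to
#' the nearest island on the same chromosome: inside an island ->
#' `island`; within (0, 2000] bp -> `shore`; within (2000, 4000] bp ->
#' `shelf`; otherwise `open_sea`. CpGs on chromosomes without any island
#' annotation fall in `open_sea` with a warning.
#'
#' @param cpgs `data.frame` with columns `chrom` and `pos` (1-based CpG
#'   cytosine position).
#' @param islands CpG island intervals: a
#'   [GenomicRanges::GRanges] object, or a `data.frame` with `chrom`,
#'   `start`, `end` in BED convention (half-open, 0-based starts).
#' @param shoreWidth,shelfWidth flank widths in bp (defaults 2000 each;
#'   boundaries inclusive, so a CpG exactly 2000 bp away is shore).
#' @return factor of categories (`island`, `shore`, `shelf`, `open_sea`),
#'   one per CpG.
#' @export
annotateCpGContext <- function(cpgs, islands, shoreWidth = 2000,
                               shelfWidth = 2000) {
  if (is.data.frame(islands)) {
    islands <- GenomicRanges::GRanges(
      islands$chrom,
      IRanges::IRanges(start = islands$start + 1L, end = islands$end))
  }
  gr <- GenomicRanges::GRanges(cpgs$chrom,
                               IRanges::IRanges(cpgs$pos, width = 1L))
  cat <- rep("open_sea", length(gr))
  unknown <- !(as.character(GenomicRanges::seqnames(gr)) %in%
                 as.character(GenomicRanges::seqnames(islands)))
  if (any(unknown)) {
    warning(sum(unknown), " CpG(s) on chromosomes without island ",
            "annotation assigned to open_sea")
  }
  hit <- IRanges::overlapsAny(gr, islands)
  cat[hit] <- "island"
  near <- GenomicRanges::distanceToNearest(gr, islands)
  idx <- S4Vectors::queryHits(near)
  ## GRanges distance counts the gap (adjacent = 0); bp offset is gap + 1
  bp <- S4Vectors::mcols(near)$distance + 1L
  shore <- idx[!hit[idx] & bp <= shoreWidth]
  shelf <- idx[!hit[idx] & bp > shoreWidth & bp <= shoreWidth + shelfWidth]
  cat[shore] <- "shore"
  cat[shelf] <- "shelf"
  factor(cat, levels = c("island", "shore", "shelf", "open_sea"))
}

#' Read CpG island intervals from a BED file
#'
#' Thin wrapper around `rtracklayer::import` returning a `GRanges` suitable
#' for [annotateCpGContext()].
#'
#' @param path BED file path.
#' @return a `GRanges` of island intervals (1-based closed, as GRanges).
#' @export
readIslandsBed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    return(rtracklayer::import(path, format = "BED"))
  }
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  GenomicRanges::GRanges(tab[[1]],
                         IRanges::IRanges(start = tab[[2]] + 1L,
                                          end = tab[[3]]))
}

#' Enrichment of mQTL-associated CpGs in a genomic category
#'
#' Builds the 2-by-2 table (mCpG vs non-mCpG) x (in category vs not) and
#' reports the Fisher exact p-value alongside the log2 odds ratio with a
#' Woolf-type 95% confidence interval (0.5 continuity correction applied
#' when any cell is zero).
#'
#' @param mcpg logical flags: CpG has an associated mQTL?
#' @param context factor from [annotateCpGContext()].
#' @param category category level to test.
#' @return list with `log2_or`, `ci` (length-2), `p_value`, and `table`.
#' @export
enrichmentTest <- function(mcpg, context, category) {
  inCat <- context == category
  if (!any(inCat) || all(inCat)) {
    return(list(log2_or = NA_real_, ci = c(NA_real_, NA_real_),
                p_value = NA_real_, table = table(mcpg, inCat)))
  }
  a <- sum(mcpg & inCat);  b <- sum(mcpg & !inCat)
  cc <- sum(!mcpg & inCat); d <- sum(!mcpg & !inCat)
  tab <- matrix(c(a, cc, b, d), 2)
  p <- fisher.test(tab)$p.value
  if (any(tab == 0)) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  lor <- log2((a * d) / (b * cc))
  sel <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d) / log(2)
  list(log2_or = lor, ci = lor + c(-1, 1) * qnorm(0.975) * sel,
       p_value = p, table = tab)
}

#' CpG-disruption rate among mQTL vs non-mQTL pairs
#'
#' A pair is "disrupted" when the SNP position falls on either base of the
#' CpG dinucleotide (the cytosine at `posCpg` or the guanine at
#' `posCpg + 1`), which abolishes the CpG on the alternate allele. Returns
#' the disrupted fraction among mCpG and non-mCpG pairs and a Fisher exact
#' p-value for their difference.
#'
#' @param posSnp,posCpg 1-based positions on the same coordinate system
#'   (`posCpg` = cytosine position).
#' @param mcpg logical flags: pair is a detected mQTL?
#' @return list with `disrupted` (logical per pair), `frac_mcpg`,
#'   `frac_non_mcpg`, `p_value`.
#' @export
disruptionRate <- function(posSnp, posCpg, mcpg) {
  disrupted <- posSnp == posCpg | posSnp == posCpg + 1
  fm <- mean(disrupted[mcpg])
  fn <- mean(disrupted[!mcpg])
  p <- if (length(unique(mcpg)) == 2L && length(unique(disrupted)) == 2L) {
    fisher.test(table(disrupted, mcpg))$p.value
  } else NA_real_
  list(disrupted = disrupted, frac_mcpg = fm, frac_non_mcpg = fn,
       p_value = p)
}
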