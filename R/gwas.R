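#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

# Internal convention: all coordinates are 0-based half-open. GRanges is
# 1-based closed, so conversion is start + 1 at construction only.
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

#' Restrict an annotation to the analysis gene universe
#'
#' The universe is autosomal protein-coding and lincRNA genes, mirroring the
#' background used for differential expression testing.
#'
#' @param annotation Gene annotation data.frame (gene_id, chrom, start, end,
#'   biotype, autosomal).
#' @return The filtered annotation.
#' @export
gene_universe <- function(annotation) {
  annotation[annotation$autosomal &
               annotation$biotype %in% c("protein_coding", "lincRNA"), ,
             drop = FALSE]
}

#' Expand credible intervals by a symmetric flank
#'
#' Each interval \code{[start, end)} becomes
#' \code{[max(0, start - flank), end + flank)}; locus ids and all other
#' columns are preserved.
#'
#' @param intervals Credible-interval data.frame (locus_id, trait, chrom,
#'   start, end, ...).
#' @param flank_kb Flank in kilobases, >= 0.
#' @return The expanded data.frame.
#' @export
expand_intervals <- function(intervals, flank_kb) {
  if (length(flank_kb) != 1L || !is.finite(flank_kb) || flank_kb < 0)
    stop("flank_kb must be a single non-negative number")
  f <- flank_kb * 1000
  intervals$start <- pmax(0, intervals$start - f)
  intervals$end <- intervals$end + f
  intervals
}

#' Map genes to the credible intervals that capture them
#'
#' A gene is captured by a locus when its gene body overlaps the
#' flank-expanded interval by at least 1 bp under half-open arithmetic
#' (\code{gene.start < iv.end & iv.start < gene.end}); partial containment
#' suffices. Returns every capturing locus per gene.
#'
#' @param annotation Gene annotation data.frame.
#' @param intervals Credible-interval data.frame.
#' @param flank_kb Flank applied to the intervals before overlap (kb).
#' @return data.frame: gene_id, locus_id, flank_kb (one row per captured
#'   gene x capturing locus).
#' @export
genes_in_intervals <- function(annotation, intervals, flank_kb = 0) {
  if (nrow(intervals) > 0) {
    unmatched <- setdiff(unique(intervals$chrom), unique(annotation$chrom))
    if (length(unmatched))
      stop(sprintf("interval chromosome(s) absent from annotation: %s",
                   paste(unmatched, collapse = ", ")))
  }
  iv <- expand_intervals(intervals, flank_kb)
  if (nrow(iv) == 0L || nrow(annotation) == 0L)
    return(data.frame(gene_id = character(0), locus_id = character(0),
                      flank_kb = numeric(0), stringsAsFactors = FALSE))
  hits <- GenomicRanges::findOverlaps(
    as_granges0(annotation$chrom, annotation$start, annotation$end),
    as_granges0(iv$chrom, iv$start, iv$end))
  out <- data.frame(gene_id = annotation$gene_id[S4Vectors::queryHits(hits)],
                    locus_id = iv$locus_id[S4Vectors::subjectHits(hits)],
                    flank_kb = rep(flank_kb, length(hits)),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$locus_id), , drop = FALSE]
}

#' Genes sharing a capturing locus with a given gene
#'
#' @param capture Capture map from \code{\link{genes_in_intervals}}.
#' @param gene_id A gene id. A gene absent from the map returns an empty set.
#' @return Character vector of co-member gene ids (\code{gene_id} excluded).
#' @export
comembers <- function(capture, gene_id) {
  loci <- capture$locus_id[capture$gene_id == gene_id]
  if (!length(loci)) return(character(0))
  setdiff(unique(capture$gene_id[capture$locus_id %in% loci]), gene_id)
}

#' Subset loci carrying a tag
#'
#' Tags are comma-separated labels in the \code{tags} column. The standard
#' vocabulary (\code{beta_cell}, \code{monogenic_overlap}) is always
#' recognised even when no locus carries it (giving an empty subset); any
#' other tag must occur in the table, otherwise an error lists the known
#' tags.
#'
#' @param intervals Credible-interval data.frame with a \code{tags} column.
#' @param tag A tag label.
#' @return The loci carrying \code{tag}.
#' @export
subset_loci <- function(intervals, tag) {
  tag_list <- strsplit(ifelse(is.na(intervals$tags), "", intervals$tags), ",")
  tag_list <- lapply(tag_list, trimws)
  known <- union(setdiff(unique(unlist(tag_list)), ""),
                 c("beta_cell", "monogenic_overlap"))
  if (!(tag %in% known))
    stop(sprintf("unknown tag '%s'; known tags: %s", tag,
                 if (length(known)) paste(known, collapse = ", ") else "(none)"))
  intervals[vapply(tag_list, function(x) tag %in% x, logical(1)), , drop = FALSE]
}
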