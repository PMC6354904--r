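#' Write / read the pipeline's tab-separated interchange files
#'
#' Plain TSV with header, no quoting, no row names. Coordinates stay 0-based
#' half-open in all files except BED-specific readers/writers, where BED's
#' native 0-based half-open convention coincides with the internal one.
#'
#' @param x Object to write.
#' @param path File path.
#' @return \code{write_tsv} returns \code{path} invisibly; \code{read_tsv}
#'   returns a data.frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write counts and sample metadata
#'
#' \code{counts.tsv} holds gene_id plus one column per sample;
#' \code{samples.tsv} holds sample_id, donor, stage.
#'
#' @param x A \code{\link{stage_counts}}.
#' @param counts_path,samples_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "stage_counts"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(x$samples, samples_path)
  invisible(c(counts_path, samples_path))
}

#' Read counts and sample metadata written by \code{\link{write_counts}}
#'
#' @param counts_path,samples_path Input paths.
#' @param stages Optional ordered stage levels (default: order of first
#'   appearance in the sample table).
#' @return A \code{\link{stage_counts}}.
#' @export
read_counts <- function(counts_path, samples_path, stages = NULL) {
  cdf <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(m) <- cdf$gene_id
  samples <- read_tsv(samples_path)
  if (is.null(stages)) stages <- unique(samples$stage)
  stage_counts(m, samples, stages)
}

#' Write / read gene annotation as BED6
#'
#' The name field carries the gene id; score and strand are 0 and "*".
#' Biotype and autosomal status are not representable in BED6, so the reader
#' fills \code{biotype = "protein_coding"} and \code{autosomal = TRUE} unless
#' a side table is supplied.
#'
#' @param annotation Gene annotation data.frame.
#' @param path BED file path.
#' @return \code{read_genes_bed} returns an annotation data.frame.
#' @export
write_genes_bed <- function(annotation, path) {
  gr <- as_granges0(annotation$chrom, annotation$start, annotation$end)
  names(gr) <- annotation$gene_id
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(gene_id = as.character(gr$name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             biotype = "protein_coding", autosomal = TRUE,
             stringsAsFactors = FALSE)
}

#' Write / read credible-interval sets
#'
#' TSV with columns locus_id, trait, chrom, start, end, tags (comma
#' separated, possibly empty).
#'
#' @param intervals Credible-interval data.frame.
#' @param path File path.
#' @return \code{read_credible_sets} returns the data.frame.
#' @export
write_credible_sets <- function(intervals, path) {
  cols <- c("locus_id", "trait", "chrom", "start", "end", "tags")
  write_tsv(intervals[, cols], path)
}

#' @rdname write_credible_sets
#' @export
read_credible_sets <- function(path) {
  iv <- read_tsv(path)
  iv$tags <- ifelse(is.na(iv$tags), "", as.character(iv$tags))
  iv
}

#' Write a JSON run manifest recording configuration and seeds
#'
#' @param config Named list of settings.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("stageDE"))
  config$r_version <- R.version.string
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
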