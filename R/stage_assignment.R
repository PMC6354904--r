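#' Assign each DE gene to its stage of peak upregulation
#'
#' A gene qualifies when it meets the DE criterion (\code{is_de}) in at least
#' one contrast. Qualifying genes are assigned to the stage with the largest
#' log2 fold change versus the baseline; by default the argmax runs over all
#' contrasts, not only the significant ones (\code{argmax_over = "de"}
#' restricts it). When the peak log2FC is not positive the gene falls back to
#' the baseline stage (zero is not upregulation). Exact ties break toward the
#' earlier stage in differentiation order.
#'
#' @param table A \code{"de_table"} with is_de set (see \code{\link{call_de}});
#'   every gene must carry all non-baseline contrasts.
#' @param stages_ordered Ordered stage names including the baseline first;
#'   defaults to the attribute stored on the table.
#' @param argmax_over \code{"all"} (default) or \code{"de"}.
#' @return data.frame: gene_id, assigned_stage, peak_log2fc, qualifying.
#' @export
assign_stages <- function(table, stages_ordered = attr(table, "stages"),
                          argmax_over = c("all", "de")) {
  argmax_over <- match.arg(argmax_over)
  stopifnot(all(c("gene_id", "contrast", "log2fc", "is_de") %in% names(table)))
  if (is.null(stages_ordered)) stop("stages_ordered must be supplied")
  baseline <- stages_ordered[1]
  contrasts <- setdiff(stages_ordered, baseline)

  genes <- unique(table$gene_id)
  got <- table(factor(table$gene_id, levels = genes),
               factor(table$contrast, levels = contrasts))
  bad <- rownames(got)[apply(got != 1L, 1, any)]
  if (length(bad))
    stop(sprintf("incomplete DE table: gene(s) missing a contrast: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))

  lfc <- matrix(NA_real_, length(genes), length(contrasts),
                dimnames = list(genes, contrasts))
  lfc[cbind(match(table$gene_id, genes), match(table$contrast, contrasts))] <-
    table$log2fc
  de <- matrix(FALSE, length(genes), length(contrasts),
               dimnames = list(genes, contrasts))
  de[cbind(match(table$gene_id, genes), match(table$contrast, contrasts))] <-
    table$is_de

  qualifying <- rowSums(de) > 0L
  cand <- lfc
  if (argmax_over == "de") cand[!de] <- -Inf
  peak_idx <- max.col(cand, ties.method = "first")
  peak <- cand[cbind(seq_along(genes), peak_idx)]
  assigned <- ifelse(peak <= 0, baseline, contrasts[peak_idx])

  out <- data.frame(gene_id = genes, assigned_stage = assigned,
                    peak_log2fc = peak, qualifying = qualifying,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "stages") <- stages_ordered
  out
}

#' Genes assigned to one stage
#'
#' @param assignments \code{\link{assign_stages}} output.
#' @param stage A stage name (baseline included).
#' @return Character vector of qualifying gene ids assigned to \code{stage};
#'   the union over all stages partitions the qualifying genes.
#' @export
stage_set <- function(assignments, stage) {
  stages <- attr(assignments, "stages")
  known <- if (is.null(stages)) unique(assignments$assigned_stage) else stages
  if (!(stage %in% known))
    stop(sprintf("unknown stage '%s'; known stages: %s", stage,
                 paste(known, collapse = ", ")))
  assignments$gene_id[assignments$qualifying &
                        assignments$assigned_stage == stage]
}
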