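#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least \code{n_overlap} target genes when
#' \code{n_stage} genes are sampled without replacement from a universe of
#' \code{n_universe} genes containing \code{n_target} targets. Evaluated in
#' log space for numerical stability of small tails.
#'
#' @param n_universe,n_target,n_stage,n_overlap Consistent counts.
#' @return The p-value P(X >= n_overlap) in (0, 1].
#' @export
hypergeom_p <- function(n_universe, n_target, n_stage, n_overlap) {
  if (n_target > n_universe || n_stage > n_universe ||
      n_overlap > min(n_target, n_stage) || any(c(n_universe, n_target,
                                                  n_stage, n_overlap) < 0))
    stop("inconsistent counts: need overlap <= min(target, stage) <= universe")
  exp(stats::phyper(n_overlap - 1, n_target, n_universe - n_target, n_stage,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Permutation p-value for gene-set overlap
#'
#' Draws \code{n_perm} random gene sets of size \code{|stage_set|} uniformly
#' without replacement from the universe and compares their overlap with the
#' target set to the observed overlap. The p-value carries a pseudocount,
#' \code{(1 + #(null >= observed)) / (n_perm + 1)}, so it is never 0.
#'
#' @param stage_set,target_set Character vectors, subsets of \code{universe}.
#' @param universe Background gene ids (all genes tested for differential
#'   expression).
#' @param n_perm Number of permutations.
#' @param seed Integer seed (recorded in the result).
#' @return list: p_perm, observed, null_overlaps, n_perm, seed.
#' @export
permutation_p <- function(stage_set, target_set, universe, n_perm = 10000,
                          seed = 1L) {
  stage_set <- unique(stage_set); target_set <- unique(target_set)
  universe <- unique(universe)
  if (!all(stage_set %in% universe) || !all(target_set %in% universe))
    stop("stage_set and target_set must be subsets of the universe")
  if (length(stage_set) > length(universe))
    stop("stage set larger than universe")
  observed <- length(intersect(stage_set, target_set))
  is_target <- universe %in% target_set
  n <- length(universe); k <- length(stage_set)
  null_overlaps <- with_substream(seed, 0L, {
    vapply(seq_len(n_perm),
           function(i) sum(is_target[sample.int(n, k)]), integer(1))
  })
  list(p_perm = (1 + sum(null_overlaps >= observed)) / (n_perm + 1),
       observed = observed, null_overlaps = null_overlaps,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Remove an exclusion list (optionally with locus co-members) from a set
#'
#' In \code{genes_and_comembers} mode every gene sharing a capturing locus
#' with an excluded gene is removed too, mirroring sensitivity analyses that
#' drop e.g. monogenic diabetes genes and anything in the same credible
#' interval.
#'
#' @param stage_set Character vector of gene ids.
#' @param exclude_genes Gene ids to remove.
#' @param capture Capture map (needed for co-member mode).
#' @param mode \code{"genes_only"} or \code{"genes_and_comembers"}.
#' @return The filtered gene set.
#' @export
exclusion_filter <- function(stage_set, exclude_genes, capture = NULL,
                             mode = c("genes_only", "genes_and_comembers")) {
  mode <- match.arg(mode)
  drop <- unique(exclude_genes)
  if (mode == "genes_and_comembers") {
    if (is.null(capture))
      stop("capture map required for genes_and_comembers mode")
    drop <- unique(c(drop, unlist(lapply(exclude_genes,
                                         function(g) comembers(capture, g)))))
  }
  setdiff(stage_set, drop)
}

#' Gene-based association scores from SNP summary statistics
#'
#' Each SNP within \code{window_kb} of a gene body is assigned to that gene;
#' the raw gene score is the minimum SNP p-value. With \code{adjust = TRUE}
#' the -log10 raw scores are regressed on log10 gene length and
#' log10(n_snps + 1), and the residual ranks are mapped to (0, 1] so that
#' confounding by gene size and SNP count is removed (the MAGENTA-style
#' correction). Genes with no SNP in their window carry no score.
#'
#' @param snps data.frame: chrom, pos, p (positions 0-based).
#' @param annotation Gene annotation data.frame.
#' @param window_kb Symmetric window around the gene body (kb).
#' @param adjust Apply the confounder adjustment (default TRUE).
#' @param alpha Significance cut-off on the score (default 0.05).
#' @return data.frame: gene_id, raw_p, n_snps, score_p, adjusted,
#'   significant.
#' @export
score_genes <- function(snps, annotation, window_kb = 50, adjust = TRUE,
                        alpha = 0.05) {
  win <- expand_intervals(
    data.frame(locus_id = annotation$gene_id, chrom = annotation$chrom,
               start = annotation$start, end = annotation$end,
               stringsAsFactors = FALSE), window_kb)
  shared <- intersect(unique(snps$chrom), unique(win$chrom))
  snp_use <- snps[snps$chrom %in% shared, , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(
    as_granges0(snp_use$chrom, snp_use$pos, snp_use$pos + 1),
    as_granges0(win$chrom, win$start, win$end))
  if (!length(hits)) stop("no SNP falls within any gene window")
  gene <- win$locus_id[S4Vectors::subjectHits(hits)]
  p <- snp_use$p[S4Vectors::queryHits(hits)]
  raw <- tapply(p, gene, min)
  nsnp <- tapply(p, gene, length)
  out <- data.frame(gene_id = names(raw), raw_p = as.numeric(raw),
                    n_snps = as.integer(nsnp), row.names = NULL,
                    stringsAsFactors = FALSE)
  if (adjust) {
    len <- annotation$end[match(out$gene_id, annotation$gene_id)] -
      annotation$start[match(out$gene_id, annotation$gene_id)]
    y <- -log10(out$raw_p)
    fit <- stats::lm(y ~ log10(len) + log10(out$n_snps + 1))
    r <- stats::residuals(fit)
    # larger residual = more significant than expected for its size
    out$score_p <- rank(-r, ties.method = "average") / length(r)
  } else {
    out$score_p <- out$raw_p
  }
  out$adjusted <- adjust
  out$significant <- out$score_p < alpha
  out
}

# Running-sum enrichment statistic for set positions `sel` (sorted or not)
# in a list of length L whose |metric|^exponent values are `wts`.
# baseline "complement": misses step down by 1/(L - S) (two-sample KS);
# baseline "uniform": every position steps down by 1/L (one-sample KS).
es_stat <- function(wts, sel, L, baseline) {
  S <- length(sel)
  steps <- if (baseline == "complement") rep(-1 / (L - S), L) else rep(-1 / L, L)
  w <- wts[sel]
  tot <- sum(w)
  if (tot == 0) w <- rep(1 / S, S) else w <- w / tot
  steps[sel] <- steps[sel] + if (baseline == "complement") w + 1 / (L - S) else w
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Weighted Kolmogorov-Smirnov gene set enrichment (GSEA)
#'
#' Genes are ordered by decreasing ranking metric; in-set genes increment a
#' running sum by their normalised \code{|metric|^weight_exponent}, out-of-set
#' genes decrement it, and the enrichment score ES is the extremum of the
#' running sum. The null distribution comes from random same-size gene sets;
#' NES is ES over the mean |null ES| of the same sign and the permutation p
#' carries a pseudocount.
#'
#' Two decrement conventions are available: \code{"complement"} (the classic
#' two-sample running sum, misses step down by 1/(L - S)) and
#' \code{"uniform"} (one-sample KS against the uniform baseline, every
#' position steps down by 1/L). They locate the same extremum in the
#' unweighted case and differ only by the factor L/(L - S).
#'
#' @param metric Named numeric vector: ranking metric per gene (finite).
#' @param gene_set Character vector; must intersect \code{names(metric)} and
#'   not exceed it.
#' @param weight_exponent Exponent on |metric| for hit weights (0 =
#'   unweighted KS; default 1).
#' @param n_perm Number of null gene sets (default 1000).
#' @param seed Integer seed.
#' @param baseline Decrement convention, see Details.
#' @param set_name Label carried into the result.
#' @return data.frame row of class \code{"gsea_result"}: set_name, n_set, ES,
#'   NES, p_perm, n_perm, seed, flag.
#' @export
gsea <- function(metric, gene_set, weight_exponent = 1, n_perm = 1000,
                 seed = 1L, baseline = c("complement", "uniform"),
                 set_name = "set") {
  baseline <- match.arg(baseline)
  if (is.null(names(metric)) || any(!is.finite(metric)))
    stop("metric must be a named vector of finite values")
  ord <- order(metric, decreasing = TRUE)
  metric <- metric[ord]
  L <- length(metric)
  sel <- which(names(metric) %in% gene_set)
  S <- length(sel)
  if (S == 0L) stop("gene_set does not intersect the ranked list")
  if (length(unique(gene_set)) > L) stop("gene set larger than ranked list")
  if (S == L) {
    # running sum returns to 0 with no excursions: no enrichment information
    return(structure(data.frame(set_name = set_name, n_set = S, ES = 0,
                                NES = NA_real_, p_perm = 1,
                                n_perm = as.integer(n_perm),
                                seed = as.integer(seed), flag = "set_is_universe",
                                stringsAsFactors = FALSE),
                     class = c("gsea_result", "data.frame")))
  }
  wts <- abs(metric)^weight_exponent
  es <- es_stat(wts, sel, L, baseline)
  null_es <- with_substream(seed, 0L, {
    vapply(seq_len(n_perm),
           function(i) es_stat(wts, sample.int(L, S), L, baseline), numeric(1))
  })
  same <- null_es * sign(es) >= 0
  nes <- if (any(same)) es / mean(abs(null_es[same])) else NA_real_
  # p conditional on the observed sign, with a pseudocount so p > 0; under a
  # random set this is approximately uniform
  p <- (1 + sum(same & abs(null_es) >= abs(es))) / (1 + sum(same))
  structure(data.frame(set_name = set_name, n_set = S, ES = es, NES = nes,
                       p_perm = p, n_perm = as.integer(n_perm),
                       seed = as.integer(seed), flag = "",
                       stringsAsFactors = FALSE),
            class = c("gsea_result", "data.frame"))
}

#' GSEA over a family of gene sets with BH-adjusted q-values
#'
#' @param metric Named ranking metric (see \code{\link{gsea}}).
#' @param sets Named list of gene sets; empty sets yield a flagged row.
#' @param ... Passed to \code{\link{gsea}}.
#' @param seed Integer seed; set i uses sub-seed seed + i.
#' @return data.frame with one row per set plus a q column (BH across the
#'   family; flagged rows excluded from the family).
#' @export
gsea_sets <- function(metric, sets, ..., seed = 1L) {
  rows <- lapply(seq_along(sets), function(i) {
    set <- intersect(sets[[i]], names(metric))
    if (!length(set))
      return(data.frame(set_name = names(sets)[i], n_set = 0L, ES = NA_real_,
                        NES = NA_real_, p_perm = NA_real_, n_perm = NA_integer_,
                        seed = as.integer(seed + i), flag = "empty_set",
                        stringsAsFactors = FALSE))
    r <- gsea(metric, set, ..., seed = seed + i, set_name = names(sets)[i])
    as.data.frame(r)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- out$flag == ""
  if (any(ok)) out$q[ok] <- adjust_bh(out$p_perm[ok])
  out
}

#' Stage-set enrichment in credible-interval genes at distance bins
#'
#' For each stage (and each flank), tests whether the genes assigned to the
#' stage are over-represented among genes captured by the credible intervals,
#' by the upper-tail hypergeometric test and a permutation null of random
#' same-size gene sets from the background universe.
#'
#' @param assignments \code{\link{assign_stages}} output.
#' @param annotation Gene annotation (capture recomputed per flank).
#' @param intervals Credible-interval data.frame.
#' @param universe Background gene ids (all genes tested for DE).
#' @param flanks_kb Numeric vector of flanks (kb), default 0.
#' @param n_perm Permutations per test.
#' @param seed Integer seed; each (stage, flank) uses a distinct sub-seed.
#' @param target_set_name Label for the target set.
#' @param exclude_genes,exclude_mode Optional exclusion list applied to each
#'   stage set via \code{\link{exclusion_filter}} (co-members resolved on the
#'   flank-0 capture map).
#' @return data.frame of EnrichmentResult rows: stage, target_set_name,
#'   flank_kb, n_universe, n_target, n_stage, n_overlap, p_hyper, p_perm,
#'   n_perm, seed.
#' @export
run_interval_enrichment <- function(assignments, annotation, intervals,
                                    universe, flanks_kb = 0, n_perm = 10000,
                                    seed = 1L, target_set_name = "t2d",
                                    exclude_genes = NULL,
                                    exclude_mode = "genes_and_comembers") {
  stages <- attr(assignments, "stages")
  capture0 <- genes_in_intervals(annotation, intervals, 0)
  rows <- list()
  i <- 0L
  for (flank in flanks_kb) {
    capture <- if (flank == 0) capture0 else
      genes_in_intervals(annotation, intervals, flank)
    target <- intersect(unique(capture$gene_id), universe)
    for (stage in stages) {
      i <- i + 1L
      gs <- intersect(stage_set(assignments, stage), universe)
      if (!is.null(exclude_genes))
        gs <- exclusion_filter(gs, exclude_genes, capture0, exclude_mode)
      ov <- length(intersect(gs, target))
      perm <- permutation_p(gs, target, universe, n_perm = n_perm,
                            seed = seed + i)
      rows[[i]] <- data.frame(
        stage = stage, target_set_name = target_set_name, flank_kb = flank,
        n_universe = length(universe), n_target = length(target),
        n_stage = length(gs), n_overlap = ov,
        p_hyper = hypergeom_p(length(universe), length(target), length(gs), ov),
        p_perm = perm$p_perm, n_perm = as.integer(n_perm),
        seed = as.integer(seed + i), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' The two directional gene-score / GSEA analyses
#'
#' Direction A ranks all scored genes by -log10(gene score p) and tests each
#' stage's DE gene set for enrichment near the top. Direction B ranks, per
#' stage, that stage's DE genes by -log10(q) of the stage's contrast (the
#' baseline stage uses each gene's minimum q across contrasts, as it has no
#' contrast of its own) and tests the set of significant gene scores
#' (score p < 0.05). Each direction is BH-adjusted across stages.
#'
#' @param de_table DE table with q set (see \code{\link{call_de}}).
#' @param assignments \code{\link{assign_stages}} output.
#' @param scores \code{\link{score_genes}} output.
#' @param weight_exponent,n_perm,baseline Passed to \code{\link{gsea}}.
#' @param seed Integer seed.
#' @return data.frame: direction (A/B), stage, n_set, ES, NES, p_perm, q,
#'   flag.
#' @export
run_directional_analyses <- function(de_table, assignments, scores,
                                     weight_exponent = 1, n_perm = 1000,
                                     seed = 1L, baseline = "complement") {
  stages <- attr(assignments, "stages")

  # Direction A: genes ranked by association score, stage sets tested
  metric_a <- stats::setNames(-log10(scores$score_p), scores$gene_id)
  sets_a <- stats::setNames(lapply(stages, function(s)
    stage_set(assignments, s)), stages)
  dir_a <- gsea_sets(metric_a, sets_a, weight_exponent = weight_exponent,
                     n_perm = n_perm, baseline = baseline, seed = seed)
  dir_a <- data.frame(direction = "A", stage = dir_a$set_name,
                      dir_a[, c("n_set", "ES", "NES", "p_perm", "q", "flag")],
                      stringsAsFactors = FALSE)

  # Direction B: per stage, that stage's DE genes ranked by q; tested set =
  # genes with significant scores
  sig <- scores$gene_id[scores$significant]
  min_q <- tapply(de_table$q, de_table$gene_id, min)
  rows_b <- lapply(seq_along(stages), function(i) {
    s <- stages[i]
    gs <- stage_set(assignments, s)
    if (s %in% unique(de_table$contrast)) {
      sub <- de_table[de_table$contrast == s & de_table$gene_id %in% gs, ]
      metric <- stats::setNames(-log10(sub$q), sub$gene_id)
    } else {
      metric <- stats::setNames(-log10(as.numeric(min_q[gs])), gs)
    }
    set <- intersect(sig, names(metric))
    if (!length(metric) || !length(set))
      return(data.frame(direction = "B", stage = s, n_set = 0L, ES = NA_real_,
                        NES = NA_real_, p_perm = NA_real_, q = NA_real_,
                        flag = "empty_set", stringsAsFactors = FALSE))
    r <- gsea(metric, set, weight_exponent = weight_exponent, n_perm = n_perm,
              seed = seed + 100L + i, baseline = baseline, set_name = s)
    data.frame(direction = "B", stage = s,
               r[, c("n_set", "ES", "NES", "p_perm")], q = NA_real_,
               flag = r$flag, stringsAsFactors = FALSE)
  })
  dir_b <- do.call(rbind, rows_b)
  ok <- dir_b$flag == "" & !is.na(dir_b$p_perm)
  if (any(ok)) dir_b$q[ok] <- adjust_bh(dir_b$p_perm[ok])

  out <- rbind(dir_a, dir_b)
  rownames(out) <- NULL
  out
}
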