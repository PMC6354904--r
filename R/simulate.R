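#' Configuration for the synthetic staged-differentiation study
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' list. The defaults describe the study design the package targets: iPSC
#' lines from three donors profiled at baseline plus seven differentiation
#' stages, negative-binomial counts with a gene-specific donor effect, a
#' disjoint block of upregulated marker genes per non-baseline stage, GWAS
#' credible intervals partly planted on marker genes of one stage, and SNP
#' p-values enriched inside the planted intervals.
#'
#' @param n_genes Number of genes to simulate.
#' @param stages Ordered stage names; the first entry is the baseline.
#' @param n_donors Number of donors (one sample per donor and stage).
#' @param lib_size_range Range of expected per-sample library sizes (counts).
#' @param nb_dispersion Negative-binomial dispersion; 0 gives Poisson counts.
#' @param marker_frac_per_stage Fraction of genes planted as markers of each
#'   non-baseline stage; the fractions must sum to below 1.
#' @param effect_log2fc_range Range of the true log2 fold change of planted
#'   markers at their stage.
#' @param donor_sd SD (log2 scale) of gene-specific donor effects, constant
#'   across stages.
#' @param baseline_meanlog,baseline_sdlog Parameters of the log-normal from
#'   which relative baseline expression is drawn.
#' @param n_loci Number of credible intervals to simulate.
#' @param planted_frac Fraction of loci planted on marker-gene bodies when
#'   \code{planted_locus_stage} is set.
#' @param interval_len_range Range of credible-interval lengths (bp).
#' @param snps_per_locus SNPs simulated inside each credible interval.
#' @param n_background_snps Genome-wide background SNPs with uniform p.
#' @param snp_p_exponent Exponent k of the enriched SNP p distribution
#'   (p = U^k) inside planted intervals; k = 1 is the null.
#' @param planted_locus_stage Stage whose markers anchor planted intervals,
#'   or \code{NULL} for none.
#' @param n_chroms Number of synthetic chromosomes.
#' @param gene_len_range,gene_gap_range Ranges of gene-body lengths and
#'   intergenic gaps (bp) used to lay out the synthetic genome.
#' @param lincrna_frac Fraction of genes labelled lincRNA (rest
#'   protein_coding).
#' @param seed Integer root seed; each generator derives its own sub-stream
#'   so adding loci never perturbs counts.
#'
#' @return A list of class \code{"sim_config"}.
#' @export
simulation_config <- function(n_genes = 2000L,
                              stages = c("iPSC", "DE", "GT", "PF",
                                         "PE", "EP", "EN", "BLC"),
                              n_donors = 3L,
                              lib_size_range = c(8e5, 1.2e6),
                              nb_dispersion = 0.1,
                              marker_frac_per_stage = 0.05,
                              effect_log2fc_range = c(2, 4),
                              donor_sd = 0.5,
                              baseline_meanlog = 4,
                              baseline_sdlog = 1.5,
                              n_loci = 40L,
                              planted_frac = 0.8,
                              interval_len_range = c(5e3, 2e5),
                              snps_per_locus = 50L,
                              n_background_snps = 2000L,
                              snp_p_exponent = 10,
                              planted_locus_stage = NULL,
                              n_chroms = 4L,
                              gene_len_range = c(2e3, 5e4),
                              gene_gap_range = c(5e4, 2e5),
                              lincrna_frac = 0.1,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), stages = as.character(stages),
    n_donors = as.integer(n_donors), lib_size_range = as.numeric(lib_size_range),
    nb_dispersion = as.numeric(nb_dispersion),
    marker_frac_per_stage = as.numeric(marker_frac_per_stage),
    effect_log2fc_range = as.numeric(effect_log2fc_range),
    donor_sd = as.numeric(donor_sd),
    baseline_meanlog = as.numeric(baseline_meanlog),
    baseline_sdlog = as.numeric(baseline_sdlog),
    n_loci = as.integer(n_loci), planted_frac = as.numeric(planted_frac),
    interval_len_range = as.numeric(interval_len_range),
    snps_per_locus = as.integer(snps_per_locus),
    n_background_snps = as.integer(n_background_snps),
    snp_p_exponent = as.numeric(snp_p_exponent),
    planted_locus_stage = if (is.null(planted_locus_stage)) NULL else
      as.character(planted_locus_stage),
    n_chroms = as.integer(n_chroms),
    gene_len_range = as.numeric(gene_len_range),
    gene_gap_range = as.numeric(gene_gap_range),
    lincrna_frac = as.numeric(lincrna_frac),
    seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

config_error <- function(field, msg) {
  stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_config <- function(cfg) {
  chk_pos_int <- function(field, x, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min)
      config_error(field, sprintf("must be a single integer >= %d", min))
  }
  chk_range <- function(field, x, lo_min = 0) {
    if (length(x) != 2L || any(is.na(x)) || x[1] > x[2] || x[1] < lo_min)
      config_error(field, "must be a (low, high) pair with low <= high")
  }
  chk_pos_int("n_genes", cfg$n_genes)
  if (length(cfg$stages) < 2L || anyDuplicated(cfg$stages))
    config_error("stages", "must list >= 2 distinct stage names (first = baseline)")
  chk_pos_int("n_donors", cfg$n_donors)
  chk_range("lib_size_range", cfg$lib_size_range, lo_min = 1)
  if (is.na(cfg$nb_dispersion) || cfg$nb_dispersion < 0)
    config_error("nb_dispersion", "must be >= 0")
  if (is.na(cfg$marker_frac_per_stage) || cfg$marker_frac_per_stage < 0 ||
      cfg$marker_frac_per_stage * (length(cfg$stages) - 1L) >= 1)
    config_error("marker_frac_per_stage",
                 "must satisfy 0 <= frac and frac * (n_stages - 1) < 1")
  chk_range("effect_log2fc_range", cfg$effect_log2fc_range, lo_min = 0)
  if (is.na(cfg$donor_sd) || cfg$donor_sd < 0)
    config_error("donor_sd", "must be >= 0")
  chk_pos_int("n_loci", cfg$n_loci, min = 0L)
  if (is.na(cfg$planted_frac) || cfg$planted_frac < 0 || cfg$planted_frac > 1)
    config_error("planted_frac", "must lie in [0, 1]")
  chk_range("interval_len_range", cfg$interval_len_range, lo_min = 1)
  chk_pos_int("snps_per_locus", cfg$snps_per_locus)
  chk_pos_int("n_background_snps", cfg$n_background_snps, min = 0L)
  if (is.na(cfg$snp_p_exponent) || cfg$snp_p_exponent < 1)
    config_error("snp_p_exponent", "must be >= 1")
  if (!is.null(cfg$planted_locus_stage) &&
      !(cfg$planted_locus_stage %in% cfg$stages[-1L]))
    config_error("planted_locus_stage", "must be a non-baseline stage name")
  chk_pos_int("n_chroms", cfg$n_chroms)
  chk_range("gene_len_range", cfg$gene_len_range, lo_min = 1)
  chk_range("gene_gap_range", cfg$gene_gap_range, lo_min = 1)
  if (is.na(cfg$lincrna_frac) || cfg$lincrna_frac < 0 || cfg$lincrna_frac > 1)
    config_error("lincrna_frac", "must lie in [0, 1]")
  if (is.na(cfg$seed)) config_error("seed", "must be an integer")
  invisible(cfg)
}

# Independent sub-streams: each generator seeds its own RNG state from the
# root seed plus a fixed offset, so e.g. adding loci never changes counts.
with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

#' Simulate staged RNA-seq counts with known ground truth
#'
#' One sample is produced per (donor, stage). Counts are negative-binomial
#' with mean proportional to a log-normal baseline abundance times
#' \code{2^(donor effect + true log2FC)}, rescaled so the expected column sum
#' equals the sample's library size. Each non-baseline stage receives a
#' disjoint block of marker genes whose true log2FC at that stage is drawn
#' from \code{effect_log2fc_range} (zero elsewhere).
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list with elements \code{counts} (a \code{\link{stage_counts}})
#'   and \code{truth}: \code{true_stage} (named vector, \code{NA} for
#'   non-markers), \code{true_log2fc} (genes x stages matrix),
#'   \code{donor_effects} (genes x donors matrix, log2 scale) and
#'   \code{planted_interval_genes} (filled by
#'   \code{\link{simulate_credible_sets}}).
#' @export
simulate_counts <- function(config) {
  validate_config(config)
  with_substream(config$seed, 101L, {
    ng <- config$n_genes
    stages <- config$stages
    donors <- sprintf("D%d", seq_len(config$n_donors))
    genes <- sprintf("G%05d", seq_len(ng))

    baseline <- stats::rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)

    lfc <- matrix(0, ng, length(stages), dimnames = list(genes, stages))
    true_stage <- stats::setNames(rep(NA_character_, ng), genes)
    n_mark <- floor(config$marker_frac_per_stage * ng)
    if (n_mark > 0L) {
      pool <- sample.int(ng)
      for (i in seq_along(stages[-1L])) {
        s <- stages[i + 1L]
        idx <- pool[seq.int((i - 1L) * n_mark + 1L, i * n_mark)]
        lfc[idx, s] <- stats::runif(n_mark, config$effect_log2fc_range[1],
                                    config$effect_log2fc_range[2])
        true_stage[idx] <- s
      }
    }

    donor_eff <- matrix(stats::rnorm(ng * config$n_donors, 0, config$donor_sd),
                        ng, config$n_donors, dimnames = list(genes, donors))

    samples <- expand.grid(donor = donors, stage = stages,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples <- samples[order(match(samples$stage, stages), samples$donor), ]
    samples <- data.frame(sample_id = paste(samples$donor, samples$stage, sep = "_"),
                          donor = samples$donor, stage = samples$stage,
                          stringsAsFactors = FALSE)
    rownames(samples) <- NULL

    lib <- stats::runif(nrow(samples), config$lib_size_range[1],
                        config$lib_size_range[2])
    counts <- matrix(0L, ng, nrow(samples),
                     dimnames = list(genes, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      rel <- baseline * 2^(donor_eff[, samples$donor[j]] + lfc[, samples$stage[j]])
      mu <- rel / sum(rel) * lib[j]
      counts[, j] <- if (config$nb_dispersion > 0)
        stats::rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
      else stats::rpois(ng, mu)
    }

    list(counts = stage_counts(counts, samples, stages = stages),
         truth = list(true_stage = true_stage, true_log2fc = lfc,
                      donor_effects = donor_eff,
                      planted_interval_genes = character(0)))
  })
}

#' Simulate non-overlapping gene annotation on synthetic chromosomes
#'
#' Genes are laid out sequentially per chromosome with random body lengths
#' and intergenic gaps, so gene bodies never overlap. Coordinates are
#' 0-based half-open.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A data.frame with columns gene_id, chrom, start, end, biotype,
#'   autosomal.
#' @export
simulate_annotation <- function(config) {
  validate_config(config)
  with_substream(config$seed, 202L, {
    ng <- config$n_genes
    genes <- sprintf("G%05d", seq_len(ng))
    chrom <- sprintf("chr%d", 1L + (seq_len(ng) - 1L) %% config$n_chroms)
    len <- round(stats::runif(ng, config$gene_len_range[1], config$gene_len_range[2]))
    gap <- round(stats::runif(ng, config$gene_gap_range[1], config$gene_gap_range[2]))
    start <- numeric(ng)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      start[i] <- cumsum(gap[i]) + c(0, cumsum(len[i]))[seq_along(i)]
    }
    biotype <- ifelse(stats::runif(ng) < config$lincrna_frac,
                      "lincRNA", "protein_coding")
    data.frame(gene_id = genes, chrom = chrom, start = start,
               end = start + len, biotype = biotype, autosomal = TRUE,
               stringsAsFactors = FALSE)
  })
}

#' Simulate GWAS credible intervals, optionally planted on marker genes
#'
#' When \code{planted_locus_stage} is set, \code{round(planted_frac * n_loci)}
#' intervals are anchored on gene bodies of that stage's markers (each
#' planted interval overlaps its anchor gene by construction); the remaining
#' intervals are placed uniformly, rejecting positions that touch a planted
#' gene.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param annotation Output of \code{\link{simulate_annotation}}.
#' @param truth Truth list from \code{\link{simulate_counts}}.
#' @param trait Trait label stored on every locus.
#' @return A list with \code{intervals} (data.frame: locus_id, trait, chrom,
#'   start, end, tags, planted) and \code{planted_genes} (gene ids anchoring
#'   planted intervals).
#' @export
simulate_credible_sets <- function(config, annotation, truth, trait = "t2d") {
  validate_config(config)
  with_substream(config$seed, 303L, {
    n_planted <- if (is.null(config$planted_locus_stage)) 0L else
      as.integer(round(config$planted_frac * config$n_loci))
    planted_genes <- character(0)
    rows <- vector("list", config$n_loci)
    chrom_len <- tapply(annotation$end, annotation$chrom, max) +
      mean(config$gene_gap_range)

    if (n_planted > 0L) {
      markers <- names(truth$true_stage)[!is.na(truth$true_stage) &
                                           truth$true_stage == config$planted_locus_stage]
      if (length(markers) < n_planted)
        stop(sprintf(paste0("cannot plant %d loci: only %d marker genes of ",
                            "stage '%s' available"),
                     n_planted, length(markers), config$planted_locus_stage),
             call. = FALSE)
      planted_genes <- sample(markers, n_planted)
      for (i in seq_len(n_planted)) {
        g <- annotation[annotation$gene_id == planted_genes[i], ]
        len <- round(stats::runif(1, config$interval_len_range[1],
                                  config$interval_len_range[2]))
        anchor <- round(stats::runif(1, g$start, g$end - 1))
        st <- max(0, anchor - round(len / 2))
        rows[[i]] <- data.frame(chrom = g$chrom, start = st, end = st + len,
                                planted = TRUE, stringsAsFactors = FALSE)
      }
    }

    avoid <- annotation[annotation$gene_id %in% planted_genes, ]
    i <- n_planted
    while (i < config$n_loci) {
      i <- i + 1L
      for (try in seq_len(200L)) {
        ch <- sample(names(chrom_len), 1L)
        len <- round(stats::runif(1, config$interval_len_range[1],
                                  config$interval_len_range[2]))
        st <- round(stats::runif(1, 0, max(1, chrom_len[[ch]] - len)))
        hit <- any(avoid$chrom == ch & avoid$start < st + len & st < avoid$end)
        if (!hit) break
      }
      rows[[i]] <- data.frame(chrom = ch, start = st, end = st + len,
                              planted = FALSE, stringsAsFactors = FALSE)
    }

    iv <- if (config$n_loci > 0L) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 planted = logical(0), stringsAsFactors = FALSE)
    iv <- data.frame(locus_id = sprintf("L%03d", seq_len(nrow(iv))),
                     trait = rep(trait, nrow(iv)), iv[, c("chrom", "start", "end")],
                     tags = rep("", nrow(iv)), planted = iv$planted,
                     stringsAsFactors = FALSE)
    list(intervals = iv, planted_genes = planted_genes)
  })
}

#' Simulate SNP summary statistics around credible intervals
#'
#' Places \code{snps_per_locus} SNPs uniformly inside each credible interval
#' plus uniform background SNPs genome-wide. Background (and unplanted-locus)
#' SNP p-values are Uniform(0,1); SNPs inside planted intervals draw
#' p = U^k with k = \code{snp_p_exponent}, so k = 1 recovers the null and the
#' expected planted p is 1/(k+1).
#'
#' @param config A \code{\link{simulation_config}}.
#' @param annotation Gene annotation (defines chromosome extents).
#' @param intervals Credible-interval data.frame from
#'   \code{\link{simulate_credible_sets}} (uses its \code{planted} column;
#'   absent column means no planted loci).
#' @return A data.frame with columns chrom, pos, p.
#' @export
simulate_snp_stats <- function(config, annotation, intervals) {
  validate_config(config)
  with_substream(config$seed, 404L, {
    k <- config$snp_p_exponent
    planted <- if ("planted" %in% names(intervals)) intervals$planted
      else rep(FALSE, nrow(intervals))
    parts <- list()
    if (nrow(intervals) > 0L) {
      m <- config$snps_per_locus
      pos <- unlist(lapply(seq_len(nrow(intervals)), function(i)
        round(stats::runif(m, intervals$start[i], intervals$end[i] - 1))))
      u <- stats::runif(nrow(intervals) * m)
      expo <- rep(ifelse(planted, k, 1), each = m)
      parts$locus <- data.frame(
        chrom = rep(intervals$chrom, each = m), pos = pos, p = u^expo,
        stringsAsFactors = FALSE)
    }
    if (config$n_background_snps > 0L) {
      chrom_len <- tapply(annotation$end, annotation$chrom, max)
      ch <- sample(names(chrom_len), config$n_background_snps, replace = TRUE,
                   prob = as.numeric(chrom_len) / sum(chrom_len))
      parts$bg <- data.frame(
        chrom = ch,
        pos = round(stats::runif(config$n_background_snps, 0, chrom_len[ch] - 1)),
        p = stats::runif(config$n_background_snps), stringsAsFactors = FALSE)
    }
    snps <- do.call(rbind, parts)
    rownames(snps) <- NULL
    # p = 0 would break -log10 scoring downstream; U^k is 0 with prob 0 but
    # guard against underflow anyway
    snps$p <- pmax(snps$p, .Machine$double.xmin)
    snps[order(snps$chrom, snps$pos), , drop = FALSE]
  })
}

#' Run all four generators and return one bundle
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list with counts, samples, truth, annotation, intervals, snps.
#' @export
simulate_study <- function(config) {
  cnt <- simulate_counts(config)
  ann <- simulate_annotation(config)
  cs <- simulate_credible_sets(config, ann, cnt$truth)
  cnt$truth$planted_interval_genes <- cs$planted_genes
  snps <- simulate_snp_stats(config, ann, cs$intervals)
  list(counts = cnt$counts, truth = cnt$truth, annotation = ann,
       intervals = cs$intervals, snps = snps)
}
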