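# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# Step-up BH: sort, walk from the largest p down, carry the running minimum.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- running
  }
  q
}

# Classic step-up rejection set at level alpha.
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  k <- max(c(0, which(ps <= (seq_len(m) / m) * alpha)))
  if (k == 0) rep(FALSE, m) else p <= ps[k]
}

# Term-by-term enumeration of the hypergeometric upper tail, in log space.
# Returns P(X >= k) for X ~ Hypergeometric(N, K, n).
hyper_tail_oracle <- function(N, K, n, k) {
  i <- seq.int(max(k, max(0, n - (N - K))), min(K, n))
  if (!length(i) || k > min(K, n)) return(if (k <= 0) 1 else 0)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

# All-pairs half-open overlap scan of gene bodies vs expanded intervals.
capture_oracle <- function(ann, iv, flank_kb) {
  f <- flank_kb * 1000
  out <- list()
  for (g in seq_len(nrow(ann))) for (l in seq_len(nrow(iv))) {
    s <- max(0, iv$start[l] - f); e <- iv$end[l] + f
    if (ann$chrom[g] == iv$chrom[l] && ann$start[g] < e && s < ann$end[g])
      out[[length(out) + 1L]] <- data.frame(gene_id = ann$gene_id[g],
                                            locus_id = iv$locus_id[l],
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(gene_id = character(0),
                                      locus_id = character(0)))
  do.call(rbind, out)
}

# Brute-force peak-stage assignment over an lfc matrix (genes x contrasts).
assign_oracle <- function(lfc, de, contrasts, baseline) {
  vapply(seq_len(nrow(lfc)), function(g) {
    best <- -Inf; best_s <- baseline
    for (j in seq_along(contrasts)) {
      if (lfc[g, j] > best) { best <- lfc[g, j]; best_s <- contrasts[j] }
    }
    if (best <= 0) baseline else best_s
  }, character(1))
}

# A small stage_counts fixture with controlled CPM patterns: a ballast gene
# fixes every library size at `lib`, so gene counts translate directly into
# CPM = count / lib * 1e6.
make_cpm_fixture <- function(gene_counts, lib = 1e6, donors = c("D1", "D2", "D3"),
                             stages = c("iPSC", "BLC")) {
  samples <- expand.grid(donor = donors, stage = stages,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste(samples$donor, samples$stage, sep = "_"),
                        samples, stringsAsFactors = FALSE)
  m <- do.call(rbind, gene_counts)
  rownames(m) <- names(gene_counts)
  colnames(m) <- samples$sample_id
  ballast <- lib - colSums(m)
  stopifnot(all(ballast > 0))
  m <- rbind(m, ballast = ballast)
  stage_counts(m, samples, stages)
}

# Random DE table (long format) over 7 contrasts for oracle tests.
random_de_table <- function(n_genes, contrasts, stages) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  tab <- expand.grid(gene_id = genes, contrast = contrasts,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$log2fc <- round(stats::rnorm(nrow(tab), 0, 2), 3)
  tab$p <- stats::runif(nrow(tab))
  tab$q <- tab$p
  tab$is_de <- stats::runif(nrow(tab)) < 0.3
  attr(tab, "stages") <- stages
  tab
}
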