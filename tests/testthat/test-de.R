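test_that("expression filter keeps a gene expressed in all donors of one stage", {
  # CPM 1.5 in all three BLC samples, 0 elsewhere -> retained
  # CPM 2 in two of three donors at every stage -> dropped
  x <- make_cpm_fixture(list(
    all_blc = c(0, 0, 0, 15, 15, 15),
    two_of_three = c(20, 20, 0, 20, 20, 0)), lib = 1e7)
  kept <- rownames(filter_expressed(x, 1)$counts)
  expect_true("all_blc" %in% kept)
  expect_false("two_of_three" %in% kept)
})

test_that("CPM threshold is strict: exactly 1 CPM everywhere is dropped", {
  x <- make_cpm_fixture(list(boundary = rep(10, 6)), lib = 1e7)
  expect_false("boundary" %in% rownames(filter_expressed(x, 1)$counts))
})

test_that("filter matches a brute-force scan over all (gene, stage) pairs", {
  set.seed(101)
  cfg <- simulation_config(n_genes = 1000, baseline_meanlog = 2,
                           baseline_sdlog = 2.5, seed = 101)
  x <- simulate_counts(cfg)$counts
  kept <- rownames(filter_expressed(x, 1)$counts)

  cc <- sweep(x$counts, 2, colSums(x$counts), "/") * 1e6
  expected <- character(0)
  for (g in rownames(cc)) {
    ok <- FALSE
    for (s in unique(x$samples$stage)) {
      if (all(cc[g, x$samples$stage == s] > 1)) ok <- TRUE
    }
    if (ok) expected <- c(expected, g)
  }
  expect_identical(kept, expected)
  expect_gt(length(kept), 0)
  expect_lt(length(kept), 1000)
})

test_that("log-CPM follows its definition and weights depend only on the data", {
  x <- make_cpm_fixture(list(g1 = rep(10, 6), g2 = rep(10, 6),
                             g3 = rep(4000, 6)))
  norm <- voom_normalize(x, prior_count = 0, simple_weights = TRUE)
  expect_equal(unname(norm$logcpm["g1", 1]), log2(10), tolerance = 1e-12)

  # identical count rows -> identical weight rows, with real weights
  cfg <- simulation_config(n_genes = 300, seed = 31)
  y <- simulate_counts(cfg)$counts
  y$counts[2, ] <- y$counts[1, ]
  norm2 <- voom_normalize(filter_expressed(stage_counts(y$counts, y$samples,
                                                        y$stages)))
  g12 <- rownames(y$counts)[1:2]
  expect_true(all(g12 %in% rownames(norm2$weights)))
  expect_equal(norm2$weights[g12[1], ], norm2$weights[g12[2], ])
})

test_that("homoscedastic data yield near-constant precision weights", {
  # counts built so log-CPM noise has the same SD at every abundance: no
  # mean-variance trend, hence the trend fit should be flat
  set.seed(7)
  n <- 2000
  donors <- c("D1", "D2", "D3")
  stages <- c("iPSC", "DE", "GT", "PF")
  samples <- expand.grid(donor = donors, stage = stages,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste(samples$donor, samples$stage, sep = "_"),
                        samples, stringsAsFactors = FALSE)
  mu <- stats::runif(n, 6, 14)  # log2 counts
  m <- matrix(round(2^(mu + stats::rnorm(n * nrow(samples), 0, 0.25))),
              n, nrow(samples), dimnames = list(sprintf("g%04d", 1:n),
                                                samples$sample_id))
  x <- stage_counts(m, samples, stages)
  w <- voom_normalize(x)$weights
  expect_lt(max(w) / stats::median(w), 1.1)
  expect_gt(min(w) / stats::median(w), 0.9)
})

test_that("with unit weights the stage coefficients solve generic least squares", {
  cfg <- simulation_config(n_genes = 50, seed = 41)
  x <- simulate_counts(cfg)$counts
  norm <- voom_normalize(x, simple_weights = TRUE)
  fit <- fit_contrasts(norm)
  X <- norm$design
  beta <- t(solve(t(X) %*% X, t(X) %*% t(norm$logcpm)))
  expect_lt(max(abs(fit$coef - beta)), 1e-10)

  # saturated 2 donor x 2 stage additive design interpolates exactly
  samples <- data.frame(sample_id = c("a", "b", "c", "d"),
                        donor = c("D1", "D2", "D1", "D2"),
                        stage = c("iPSC", "iPSC", "BLC", "BLC"),
                        stringsAsFactors = FALSE)
  m <- matrix(1, 2, 4, dimnames = list(c("g1", "g2"), samples$sample_id))
  x2 <- stage_counts(m, samples, c("iPSC", "BLC"))
  n2 <- voom_normalize(x2, simple_weights = TRUE)
  n2$logcpm[1, ] <- c(0, 1, 2, 3)  # stage effect 2, donor effect 1
  n2$logcpm[2, ] <- c(0, 1, 2, 3)
  f2 <- fit_contrasts(n2)
  expect_equal(unname(f2$coef[1, "BLC"]), 2, tolerance = 1e-12)
})

test_that("coefficients are invariant to sample order", {
  cfg <- simulation_config(n_genes = 80, seed = 43)
  x <- simulate_counts(cfg)$counts
  perm <- sample(ncol(x$counts))
  xp <- stage_counts(x$counts[, perm], x$samples[perm, ], x$stages)
  f1 <- fit_contrasts(voom_normalize(x))
  f2 <- fit_contrasts(voom_normalize(xp))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
})

test_that("design errors are informative", {
  cfg <- simulation_config(n_genes = 20, seed = 3)
  x <- simulate_counts(cfg)$counts
  keep <- x$samples$stage != "BLC"
  x_miss <- stage_counts(x$counts[, keep], x$samples[keep, ], x$stages)
  expect_error(voom_normalize(x_miss), "BLC")
  # fewer samples than coefficients
  one_donor <- x$samples$donor == "D1"
  x_small <- stage_counts(x$counts[, one_donor], x$samples[one_donor, ],
                          x$stages)
  expect_error(voom_normalize(x_small), "rank-deficient")
})

test_that("moderated t reduces to ordinary t at d0 = 0 and pools at d0 = Inf", {
  cfg <- simulation_config(n_genes = 100, seed = 47)
  x <- simulate_counts(cfg)$counts
  fit <- fit_contrasts(voom_normalize(filter_expressed(x)))

  de0 <- ebayes_moderate(fit, d0_override = 0)
  t_ord <- as.numeric(fit$coef[, fit$stage_coefs] /
                        (fit$stdev_unscaled[, fit$stage_coefs] * sqrt(fit$sigma2)))
  expect_equal(de0$t_mod, t_ord, tolerance = 1e-12)

  deI <- ebayes_moderate(fit, d0_override = Inf)
  expect_equal(stats::var(attr(deI, "s2_post")), 0, tolerance = 1e-20)
  expect_equal(attr(deI, "s2_post")[1], attr(deI, "s02"), tolerance = 1e-12)
})

test_that("the full weighted engine matches limma as an independent oracle", {
  skip_if_not_installed("limma")
  cfg <- simulation_config(n_genes = 500, seed = 53)
  x <- filter_expressed(simulate_counts(cfg)$counts)
  norm <- voom_normalize(x)
  v <- limma::voom(x$counts, norm$design, lib.size = colSums(x$counts),
                   span = 0.5)
  expect_equal(norm$logcpm, unname(v$E), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(norm$weights), unname(v$weights), tolerance = 1e-9)

  fit <- fit_contrasts(norm)
  lf <- limma::eBayes(limma::lmFit(v$E, norm$design, weights = v$weights))
  de <- ebayes_moderate(fit)
  expect_equal(attr(de, "d0"), unname(lf$df.prior), tolerance = 1e-6)
  expect_equal(attr(de, "s02"), unname(lf$s2.prior), tolerance = 1e-6)
  expect_equal(matrix(de$t_mod, ncol = 7),
               unname(lf$t[, fit$stage_coefs]), tolerance = 1e-8)
  expect_equal(matrix(de$p, ncol = 7),
               unname(lf$p.value[, fit$stage_coefs]), tolerance = 1e-8)
})

test_that("BH adjustment follows the step-up formula and preserves order", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_error(adjust_bh(c(0.1, 0)), "0, 1")
  expect_error(adjust_bh(c(0.1, 1.2)), "0, 1")

  set.seed(61)
  for (i in 1:20) {
    p <- stats::runif(stats::rpois(1, 50) + 2)^2
    q <- adjust_bh(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    for (alpha in c(0.01, 0.05, 0.2))
      expect_identical(q <= alpha, bh_reject_oracle(p, alpha))
    # order invariance
    perm <- sample(length(p))
    expect_equal(adjust_bh(p[perm]), q[perm], tolerance = 1e-15)
    # monotone in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("DE calling uses strict thresholds on q and |log2FC|", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    contrast = "BLC",
                    log2fc = c(3, -1.5, 1.0, 2),
                    p = c(0.1, 0.2, 0.3, 0.4) / 100,
                    stringsAsFactors = FALSE)
  # craft p so BH q values are known: q = (0.004, 0.004, 0.004, 0.004)
  out <- call_de(tab, q_max = 0.01, lfc_min = 1)
  expect_true(out$is_de[1])
  expect_true(out$is_de[2])   # negative log2FC counts via absolute value
  expect_false(out$is_de[3])  # |log2fc| = 1 exactly -> excluded
  # q exactly at the threshold is excluded
  out2 <- call_de(tab[1, ], q_max = tab$p[1])  # single p: q = p = q_max
  expect_false(out2$is_de)
})

test_that("median-ratio scaling removes composition-driven false discoveries", {
  # planting only upregulated markers shifts the CPM of null genes downward
  # at marker-rich stages; median-of-ratios effective library sizes restore
  # error control while keeping marker recall
  cfg <- simulation_config(n_genes = 5000, seed = 4002)
  sim <- simulate_counts(cfg)
  truth <- sim$truth
  fdp_of <- function(de) {
    asn <- assign_stages(de)
    called <- asn$gene_id[asn$qualifying]
    mean(is.na(truth$true_stage[called]))
  }
  de_mr <- run_de(sim$counts, lib_method = "median_ratio")
  expect_lte(fdp_of(de_mr), 0.05)
  asn <- assign_stages(de_mr)
  markers <- intersect(names(truth$true_stage)[!is.na(truth$true_stage)],
                       asn$gene_id)
  expect_gte(mean(asn$qualifying[match(markers, asn$gene_id)]), 0.9)
  de_cs <- run_de(sim$counts)
  expect_gt(fdp_of(de_cs), fdp_of(de_mr))
})
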