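#' Container for staged counts with sample metadata
#'
#' A thin wrapper around an integer gene x sample count matrix plus a sample
#' table mapping each sample to one donor and one stage. The design the
#' package targets has one differentiation per donor, so every (donor, stage)
#' pair may occur at most once.
#'
#' @param counts Non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param samples data.frame with columns sample_id, donor, stage; one row
#'   per column of \code{counts}, in the same order.
#' @param stages Ordered stage levels; defaults to order of first appearance
#'   in \code{samples$stage}. The first level is the baseline.
#' @return An object of class \code{"stage_counts"}.
#' @export
stage_counts <- function(counts, samples, stages = unique(samples$stage)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  req <- c("sample_id", "donor", "stage")
  if (!all(req %in% names(samples)))
    stop("samples must have columns sample_id, donor, stage")
  if (!identical(as.character(samples$sample_id), colnames(counts)))
    stop("samples$sample_id must match colnames(counts) in order")
  if (anyDuplicated(samples[, c("donor", "stage")]))
    stop("each (donor, stage) pair may occur at most once")
  if (!all(samples$stage %in% stages))
    stop("samples$stage contains levels missing from 'stages'")
  structure(list(counts = counts,
                 samples = data.frame(samples[req], stringsAsFactors = FALSE),
                 stages = as.character(stages)),
            class = "stage_counts")
}

#' @export
print.stage_counts <- function(x, ...) {
  cat(sprintf("stage_counts: %d genes x %d samples (%d donors, %d stages; baseline %s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$donor)),
              length(x$stages), x$stages[1]))
  invisible(x)
}

#' @export
dim.stage_counts <- function(x) dim(x$counts)

cpm <- function(counts, lib = colSums(counts)) {
  sweep(counts, 2, lib, "/") * 1e6
}

# Median-of-ratios size factors (relative to the per-gene geometric mean),
# rescaled to effective library sizes on the column-sum scale. Robust to
# composition shifts when many genes change in one direction.
median_ratio_lib <- function(counts) {
  lgm <- rowMeans(log(counts))
  use <- is.finite(lgm)
  if (sum(use) < 10)
    stop("too few all-positive genes for median-ratio scaling")
  sf <- apply(log(counts[use, , drop = FALSE]) - lgm[use], 2,
              stats::median)
  sf <- exp(sf - mean(sf))
  sf * exp(mean(log(colSums(counts))))
}

#' Filter to genes expressed above a CPM threshold in all donors of a stage
#'
#' A gene is retained when there is at least one stage at which its CPM
#' exceeds \code{cpm_threshold} in every donor's sample of that stage
#' (strict inequality). Library sizes are the column sums of the input
#' matrix; gene order is preserved.
#'
#' @param x A \code{\link{stage_counts}}.
#' @param cpm_threshold CPM cut-off (default 1).
#' @return A \code{\link{stage_counts}} restricted to the retained genes.
#' @export
filter_expressed <- function(x, cpm_threshold = 1) {
  stopifnot(inherits(x, "stage_counts"))
  cc <- cpm(x$counts)
  keep <- rep(FALSE, nrow(cc))
  for (s in unique(x$samples$stage)) {
    j <- x$samples$stage == s
    keep <- keep | apply(cc[, j, drop = FALSE] > cpm_threshold, 1, all)
  }
  if (!any(keep)) warning("no gene passes the expression filter")
  stage_counts(x$counts[keep, , drop = FALSE], x$samples, x$stages)
}

#' Stage + donor design matrix with the baseline stage as reference
#' @noRd
stage_design <- function(samples, stages, baseline = stages[1]) {
  if (!(baseline %in% samples$stage))
    stop(sprintf("baseline stage '%s' has no samples", baseline))
  miss <- setdiff(stages, unique(samples$stage))
  if (length(miss))
    stop(sprintf("stage(s) with no samples: %s", paste(miss, collapse = ", ")))
  stage <- factor(samples$stage, levels = c(baseline, setdiff(stages, baseline)))
  donor <- factor(samples$donor)
  if (nlevels(donor) > 1L)
    design <- stats::model.matrix(~ stage + donor)
  else
    design <- stats::model.matrix(~ stage)
  colnames(design) <- sub("^stage", "", colnames(design))
  rownames(design) <- samples$sample_id
  design
}

#' Log-CPM normalisation with mean-variance precision weights
#'
#' Computes \code{log2((count + prior_count) / (lib + 2 * prior_count) * 1e6)}
#' and, unless \code{simple_weights} is set, estimates inverse-variance
#' observation weights from the mean-variance trend: a preliminary unweighted
#' fit of the stage + donor design gives per-gene residual SDs, the square
#' root of SD is smoothed against average log2 count by \code{lowess}, and
#' each observation's weight is the inverse of the trend-predicted variance
#' at its fitted log2 count.
#'
#' @param x A \code{\link{stage_counts}} (normally already filtered).
#' @param baseline Baseline stage for the design (default first stage level).
#' @param prior_count Prior count added to each observation (default 0.5).
#' @param span \code{lowess} smoother span for the trend (default 0.5).
#' @param simple_weights If TRUE, all weights are 1 (useful for oracle
#'   comparisons against unweighted least squares).
#' @param lib_method \code{"colsums"} (default): library size is the column
#'   sum of the filtered matrix; \code{"median_ratio"}: effective library
#'   sizes from median-of-ratios size factors, which are robust to
#'   composition shifts when expression changes are predominantly
#'   one-directional.
#' @return A list of class \code{"stage_norm"}: logcpm and weights matrices,
#'   lib_sizes, design, samples, stages, baseline.
#' @export
voom_normalize <- function(x, baseline = x$stages[1], prior_count = 0.5,
                           span = 0.5, simple_weights = FALSE,
                           lib_method = c("colsums", "median_ratio")) {
  stopifnot(inherits(x, "stage_counts"))
  lib_method <- match.arg(lib_method)
  lib <- if (lib_method == "median_ratio") median_ratio_lib(x$counts) else
    colSums(x$counts)
  if (any(lib <= 0)) stop("all library sizes must be > 0")
  design <- stage_design(x$samples, x$stages, baseline)
  if (nrow(design) <= ncol(design))
    stop(sprintf("rank-deficient design: %d samples for %d coefficients",
                 nrow(design), ncol(design)))
  logcpm <- log2(sweep(x$counts + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)

  if (simple_weights) {
    w <- matrix(1, nrow(logcpm), ncol(logcpm), dimnames = dimnames(logcpm))
  } else {
    fit <- ls_fit(logcpm, design)
    # trend of sqrt(residual SD) on average log2 count
    avelog2count <- rowMeans(logcpm) + mean(log2(lib + 1)) - log2(1e6)
    sd_qrt <- sqrt(sqrt(fit$sigma2))
    ok <- fit$df > 0 & is.finite(sd_qrt)
    lo <- stats::lowess(avelog2count[ok], sd_qrt[ok], f = span)
    trend <- stats::approxfun(lo, rule = 2, ties = list("ordered", mean))
    fitted_logcpm <- fit$coef %*% t(design)
    fitted_log2count <- sweep(fitted_logcpm, 2, log2(lib + 1) - log2(1e6), "+")
    w <- trend(fitted_log2count)^-4
    dim(w) <- dim(logcpm)
    dimnames(w) <- dimnames(logcpm)
  }
  if (any(!is.finite(w)) || any(w <= 0))
    stop("internal error: non-finite or non-positive precision weights")
  structure(list(logcpm = logcpm, weights = w, lib_sizes = lib,
                 design = design, samples = x$samples, stages = x$stages,
                 baseline = baseline),
            class = "stage_norm")
}

# Unweighted multi-response least squares: one shared design for all genes.
ls_fit <- function(y, design) {
  qr_ <- qr(design)
  coef <- t(qr.coef(qr_, t(y)))
  res <- t(qr.resid(qr_, t(y)))
  df <- nrow(design) - qr_$rank
  sigma2 <- rowSums(res^2) / df
  list(coef = coef, sigma2 = sigma2, df = rep(df, nrow(y)))
}

#' Per-gene weighted linear fits of every stage against the baseline
#'
#' Fits, for each gene, weighted least squares of log-CPM on stage indicators
#' (baseline as reference) plus donor indicators. The coefficient of stage s
#' is the log2 fold change of s versus the baseline, adjusted for donor.
#'
#' @param norm A \code{\link{voom_normalize}} result.
#' @return A list of class \code{"stage_fit"}: coef and stdev_unscaled
#'   (genes x coefficients), sigma2, df, design, stage coefficient names.
#' @export
fit_contrasts <- function(norm) {
  stopifnot(inherits(norm, "stage_norm"))
  X <- norm$design
  y <- norm$logcpm
  w <- norm$weights
  ng <- nrow(y)
  p <- ncol(X)
  coef <- matrix(NA_real_, ng, p, dimnames = list(rownames(y), colnames(X)))
  unscaled <- coef
  sigma2 <- numeric(ng)
  df <- integer(ng)
  for (g in seq_len(ng)) {
    sw <- sqrt(w[g, ])
    Xw <- X * sw
    fit <- stats::lm.fit(Xw, y[g, ] * sw)
    coef[g, ] <- fit$coefficients
    df[g] <- fit$df.residual
    sigma2[g] <- sum(fit$residuals^2) / fit$df.residual
    xtx_inv <- chol2inv(chol(crossprod(Xw)))
    unscaled[g, ] <- sqrt(diag(xtx_inv))
  }
  stage_names <- setdiff(norm$stages, norm$baseline)
  structure(list(coef = coef, stdev_unscaled = unscaled, sigma2 = sigma2,
                 df = df, design = X, stage_coefs = stage_names,
                 baseline = norm$baseline, stages = norm$stages),
            class = "stage_fit")
}

#' Invert the trigamma function (Newton iteration)
#' @noRd
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-gene variances and t-statistics
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 by
#' moment matching on log residual variances (digamma/trigamma inversion),
#' shrinks each gene's variance to the posterior
#' \code{(d0 s0^2 + d_g s_g^2) / (d0 + d_g)}, and returns moderated
#' t-statistics with d0 + d_g degrees of freedom for every stage contrast.
#' When the log-variances are underdispersed relative to their sampling
#' spread, d0 is infinite and all genes share the pooled variance s0^2.
#'
#' @param fit A \code{\link{fit_contrasts}} result.
#' @param d0_override Optional forced prior df: 0 gives ordinary t-statistics,
#'   \code{Inf} the pooled-variance limit.
#' @return data.frame of class \code{"de_table"} with one row per
#'   (gene, stage contrast): gene_id, contrast, log2fc, t_mod, p, df_residual;
#'   attributes d0, s02, s2_post.
#' @export
ebayes_moderate <- function(fit, d0_override = NULL) {
  stopifnot(inherits(fit, "stage_fit"))
  ok <- fit$df > 0 & is.finite(fit$sigma2) & fit$sigma2 > 0
  if (sum(ok) < 2L) stop("need >= 2 genes with positive residual df")

  z <- log(fit$sigma2[ok])
  d <- fit$df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # log-variances underdispersed relative to their sampling spread:
    # infinite prior df, variances pooled to their mean
    d0 <- Inf
    s02 <- mean(fit$sigma2[ok])
  }
  if (!is.null(d0_override)) {
    d0 <- d0_override
    if (is.infinite(d0)) s02 <- mean(fit$sigma2[ok])
  }

  s2_post <- if (is.infinite(d0)) rep(s02, length(fit$sigma2)) else
    (d0 * s02 + fit$df * fit$sigma2) / (d0 + fit$df)

  idx <- match(fit$stage_coefs, colnames(fit$coef))
  gene_ids <- rownames(fit$coef)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(nrow(fit$coef)))
  # total df capped at the pooled residual df, the information actually
  # available across genes
  df_pooled <- sum(fit$df[ok])
  out <- do.call(rbind, lapply(seq_along(idx), function(i) {
    j <- idx[i]
    t_mod <- fit$coef[, j] / (fit$stdev_unscaled[, j] * sqrt(s2_post))
    df_total <- pmin(d0 + fit$df, df_pooled)
    p <- 2 * stats::pt(-abs(t_mod), df = df_total)
    data.frame(gene_id = gene_ids, contrast = fit$stage_coefs[i],
               log2fc = fit$coef[, j], t_mod = t_mod, p = p,
               df_residual = fit$df, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  # exact zeros only arise from degenerate fits; keep p in (0, 1]
  out$p <- pmax(out$p, .Machine$double.xmin)
  structure(out, d0 = d0, s02 = s02, s2_post = s2_post,
            stages = fit$stages, baseline = fit$baseline,
            class = c("de_table", "data.frame"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \code{q_i = min_{p_(j) >= p_i} m p_(j) / j},
#' capped at 1, in the input order.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as \code{p}.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed (gene, contrast) pairs
#'
#' Adds (or recomputes) q-values per contrast family by Benjamini-Hochberg
#' and sets \code{is_de = (q < q_max) & (|log2fc| > lfc_min)}; both
#' inequalities are strict, so boundary genes are excluded.
#'
#' @param table A \code{\link{ebayes_moderate}} result (or any data.frame
#'   with gene_id, contrast, log2fc, p).
#' @param q_max q-value threshold (default 0.01).
#' @param lfc_min absolute log2FC threshold (default 1).
#' @return The table with columns q and is_de added.
#' @export
call_de <- function(table, q_max = 0.01, lfc_min = 1) {
  stopifnot(all(c("gene_id", "contrast", "log2fc", "p") %in% names(table)))
  table$q <- stats::ave(table$p, table$contrast, FUN = adjust_bh)
  table$is_de <- table$q < q_max & abs(table$log2fc) > lfc_min
  table
}

#' Full differential-expression pipeline
#'
#' Expression filter, log-CPM normalisation with precision weights, per-gene
#' weighted fits of stage contrasts with donor blocking, empirical-Bayes
#' moderation, per-contrast BH adjustment and DE calling.
#'
#' @param x A \code{\link{stage_counts}}.
#' @param baseline Baseline stage.
#' @param cpm_threshold Expression filter threshold (CPM, strict).
#' @param q_max,lfc_min DE thresholds (strict).
#' @param simple_weights Bypass precision weights (all 1).
#' @param prior_count,span,lib_method Passed to \code{\link{voom_normalize}}.
#' @return A \code{"de_table"} data.frame (see \code{\link{ebayes_moderate}}
#'   and \code{\link{call_de}}).
#' @export
run_de <- function(x, baseline = x$stages[1], cpm_threshold = 1,
                   q_max = 0.01, lfc_min = 1, simple_weights = FALSE,
                   prior_count = 0.5, span = 0.5,
                   lib_method = c("colsums", "median_ratio")) {
  kept <- filter_expressed(x, cpm_threshold)
  norm <- voom_normalize(kept, baseline = baseline, prior_count = prior_count,
                         span = span, simple_weights = simple_weights,
                         lib_method = lib_method)
  fit <- fit_contrasts(norm)
  call_de(ebayes_moderate(fit), q_max = q_max, lfc_min = lfc_min)
}
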