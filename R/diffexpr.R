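## Negative-binomial differential expression: median-of-ratios size factors,
## method-of-moments dispersion with trend shrinkage, per-gene NB Wald test,
## BH step-up FDR, and the twofold / FDR-0.01 call rule.

#' Median-of-ratios size factors
#'
#' The reference is the per-gene geometric mean over samples, computed on
#' genes with all-nonzero counts; each sample's size factor is the median over
#' those genes of count / reference.
#'
#' @param counts gene x sample count matrix.
#' @param fallback `"none"` errors when no gene is nonzero in every sample;
#'   `"poscounts"` uses, per sample, the genes nonzero in that sample against
#'   a geometric mean taken over nonzero entries (pseudo-reference fallback).
#' @return named positive numeric vector, one size factor per sample.
#' @export
estimate_size_factors <- function(counts, fallback = c("none", "poscounts")) {
  fallback <- match.arg(fallback)
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    if (fallback == "none")
      stop("no gene has nonzero counts in every sample; ",
           "rerun with fallback = \"poscounts\"")
    loggeo <- rowSums(ifelse(is.finite(logc), logc, 0)) /
      pmax(rowSums(is.finite(logc)), 1)
    sf <- apply(logc, 2, function(lc) {
      use <- is.finite(lc) & is.finite(loggeo)
      exp(median((lc - loggeo)[use]))
    })
    return(sf)
  }
  sf <- apply(logc, 2, function(lc) exp(median((lc - loggeo)[ok])))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factor estimate")
  sf
}

#' Per-gene NB dispersion by method of moments with trend shrinkage
#'
#' Raw per-gene dispersion is `max(0, (v - mu) / mu^2)` pooled over conditions
#' (within-condition variance of size-factor-normalized counts, weighted by
#' residual degrees of freedom). Raw values are then shrunk toward a fitted
#' mean-dispersion trend `a0 + a1 / mu` by a weighted average, stabilizing
#' two-replicate designs.
#'
#' @param counts gene x sample count matrix.
#' @param size_factors per-sample size factors.
#' @param design sample design (conditions = line x tissue).
#' @param shrink_weight weight of the trend in the average (0 = raw
#'   method-of-moments, 1 = pure trend); default 0.5.
#' @return named per-gene dispersion vector (>= 0).
#' @export
estimate_dispersion <- function(counts, size_factors, design,
                                shrink_weight = 0.5) {
  check_design(design)
  design <- design[match(colnames(counts), design$sample_id), ]
  norm <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  cond <- condition_label(design$line, design$tissue)
  num <- rep(0, nrow(counts)); den <- 0
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    if (length(idx) < 2) next
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- row_vars(norm[, idx, drop = FALSE])
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + (length(idx) - 1) * a
    den <- den + (length(idx) - 1)
  }
  if (den == 0)
    stop("dispersion estimation needs at least one condition with >= 2 replicates")
  raw <- pmax(num / den, 0)
  mu_bar <- rowMeans(norm)
  use <- mu_bar > 0
  trend <- rep(1e-8, nrow(counts))
  if (sum(use) >= 10) {
    fit <- lm(raw[use] ~ I(1 / mu_bar[use]))
    a0 <- max(coef(fit)[1], 0)
    a1 <- max(coef(fit)[2], 0)
    trend[use] <- pmax(a0 + a1 / mu_bar[use], 1e-8)
  }
  out <- (1 - shrink_weight) * raw + shrink_weight * trend
  names(out) <- rownames(counts)
  out
}

## Fisher scoring for the NB group mean q with offsets log(s): solves
## sum_j (y_j - s_j q) / (1 + alpha s_j q) = 0. Monotone score, so a few
## scoring steps converge; vectorized across genes.
nb_fit_group <- function(y, s, alpha, maxit = 60L, tol = 1e-12) {
  tot <- rowSums(y)
  q <- tot / sum(s)                      # Poisson / starting estimate
  zero <- tot == 0
  logq <- log(pmax(q, 1e-10))
  for (it in seq_len(maxit)) {
    qv <- exp(logq)
    mu <- outer(qv, s)
    den <- 1 + alpha * mu
    score <- rowSums((y - mu) / den)
    info <- rowSums(mu / den)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    logq <- pmin(pmax(logq + step, -30), 30)
    if (max(abs(step)) < tol) break
  }
  q <- exp(logq)
  q[zero] <- 0
  q
}

#' Negative-binomial Wald test for a two-condition contrast
#'
#' Fits a per-gene NB mean for each condition by maximum likelihood with
#' log-link size-factor offsets and fixed gene-wise dispersion, then tests
#' `log2fc = log2(mu_num / mu_den)` against zero with a Wald statistic whose
#' standard error comes from the Fisher information. Zero-count groups are
#' floored at `pseudo_floor` normalized counts so fold changes stay finite;
#' genes with no reads in either condition are flagged and given p = 1.
#'
#' @param counts gene x sample count matrix.
#' @param size_factors per-sample size factors.
#' @param dispersion per-gene dispersion (scalar recycled).
#' @param design sample design.
#' @param contrast character vector `c(numerator, denominator)` of condition
#'   labels `"line.tissue"` (numerator over denominator).
#' @param pseudo_floor normalized-count floor for zero groups (default 0.5).
#' @return data.frame: gene_id, base_mean, log2fc, se, stat, pvalue, all_zero.
#' @export
nb_wald_test <- function(counts, size_factors, dispersion, design, contrast,
                         pseudo_floor = 0.5) {
  check_design(design)
  stopifnot(length(contrast) == 2)
  cond <- setNames(condition_label(design$line, design$tissue), design$sample_id)
  num_s <- names(cond)[cond == contrast[[1]]]
  den_s <- names(cond)[cond == contrast[[2]]]
  if (!length(num_s) || !length(den_s))
    stop("contrast condition(s) absent from design: ",
         paste(setdiff(contrast, cond), collapse = ", "))
  if (length(num_s) < 2 || length(den_s) < 2)
    warning("a contrast condition has a single replicate; ",
            "inference relies entirely on the pooled dispersion")
  alpha <- rep_len(dispersion, nrow(counts))
  sn <- size_factors[num_s]; sd_ <- size_factors[den_s]
  yn <- counts[, num_s, drop = FALSE]; yd <- counts[, den_s, drop = FALSE]
  qn <- nb_fit_group(yn, sn, alpha)
  qd <- nb_fit_group(yd, sd_, alpha)
  all_zero <- qn == 0 & qd == 0
  qn_f <- ifelse(qn == 0, pseudo_floor, qn)
  qd_f <- ifelse(qd == 0, pseudo_floor, qd)
  info <- function(q, s) {
    mu <- outer(q, s)
    rowSums(mu / (1 + alpha * mu))
  }
  se <- sqrt(1 / info(qn_f, sn) + 1 / info(qd_f, sd_)) / log(2)
  log2fc <- log2(qn_f / qd_f)
  stat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * pnorm(-abs(stat))
  log2fc[all_zero] <- 0; stat[all_zero] <- 0; pvalue[all_zero] <- 1
  norm <- sweep(counts[, c(num_s, den_s), drop = FALSE], 2,
                size_factors[c(num_s, den_s)], "/")
  data.frame(gene_id = rownames(counts),
             base_mean = rowMeans(norm),
             log2fc = log2fc, se = se, stat = stat, pvalue = pvalue,
             all_zero = all_zero,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort p ascending, multiply by n/rank, enforce monotonicity
#' from the largest p downward, cap at 1. Ties keep their stable order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
adjust_fdr <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  idx <- which(!is.na(pvalues))
  p <- pvalues[idx]
  if (any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    out[idx] <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  out
}

#' Apply the twofold / FDR call rule
#'
#' `over` iff padj < alpha and log2fc > lfc_threshold; `under` iff padj <
#' alpha and log2fc < -lfc_threshold; `ns` otherwise.
#'
#' @param table result of [nb_wald_test()] with a `padj` column (see
#'   [adjust_fdr()]).
#' @param lfc_threshold log2 fold-change gate (default 1, i.e. twofold).
#' @param alpha FDR level (default 0.01).
#' @return `table` with a `call` column (`"over"`, `"under"`, `"ns"`).
#' @export
call_deg <- function(table, lfc_threshold = 1, alpha = 0.01) {
  if (is.null(table$padj))
    stop("table lacks 'padj'; run adjust_fdr on pvalue first")
  call <- rep("ns", nrow(table))
  sig <- !is.na(table$padj) & table$padj < alpha
  call[sig & table$log2fc > lfc_threshold] <- "over"
  call[sig & table$log2fc < -lfc_threshold] <- "under"
  table$call <- call
  table
}

#' Run one contrast end to end
#'
#' Convenience wrapper: Wald test, BH adjustment, call rule.
#'
#' @inheritParams nb_wald_test
#' @inheritParams call_deg
#' @return DE result data.frame with pvalue, padj and call columns.
#' @export
run_contrast <- function(counts, size_factors, dispersion, design, contrast,
                         lfc_threshold = 1, alpha = 0.01, pseudo_floor = 0.5) {
  res <- nb_wald_test(counts, size_factors, dispersion, design, contrast,
                      pseudo_floor = pseudo_floor)
  res$padj <- adjust_fdr(res$pvalue)
  call_deg(res, lfc_threshold = lfc_threshold, alpha = alpha)
}

#' Write a DE result table as TSV
#' @param table DE result data.frame.
#' @param path output path.
#' @export
write_de_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
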