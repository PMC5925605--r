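#' Per-probe linear regression of M-values on tumor cellularity
#'
#' Ordinary least squares of each probe's M-values on an intercept plus a
#' single continuous covariate, the level of tumor involvement (normals
#' enter at cellularity 0, tumors at their recorded fraction). Fully
#' vectorized across probes.
#'
#' @param M probe x sample M-value matrix.
#' @param x cellularity vector aligned with the columns of `M` (>= 3
#'   distinct values).
#' @return data.frame per probe: `probe_id`, `slope` (M-units per unit
#'   cellularity), `sigma2` (residual variance, RSS / df), `df_resid`
#'   (n - 2), `se_unit` (unscaled standard error `1/sqrt(Sxx)`, so
#'   `se = sqrt(sigma2) * se_unit`).
#' @export
fit_probe_regressions <- function(M, x) {
  if (ncol(M) != length(x)) stop("columns of M must align with x")
  if (length(unique(x)) < 3) {
    stop("cellularity must take >= 3 distinct values (design not estimable)")
  }
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.vector(M %*% xc) / sxx
  fitted_dev <- outer(slope, xc)                   # deviation from probe mean
  Mc <- M - rowMeans(M)
  rss <- rowSums((Mc - fitted_dev)^2)
  df <- n - 2L
  data.frame(
    probe_id = rownames(M) %||% sprintf("p%d", seq_len(nrow(M))),
    slope = slope,
    sigma2 = rss / df,
    df_resid = df,
    se_unit = 1 / sqrt(sxx),
    stringsAsFactors = FALSE
  )
}

# Inverse of the trigamma function by Newton iteration on the convex
# transform (Smyth 2004); vectorized.
trigamma_inverse <- function(y) {
  out <- y
  lo <- !is.na(y) & y < 1e-6
  hi <- !is.na(y) & y > 1e7
  out[lo] <- 1 / y[lo]
  out[hi] <- 1 / sqrt(y[hi])
  mid <- !is.na(y) & !lo & !hi
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior to the observed residual
#' variances by moment matching on the log scale: the excess variance of
#' `log(sigma2)` over the sampling component `trigamma(df/2)` identifies
#' the prior degrees of freedom `d0` through a trigamma inversion, and the
#' matched mean identifies the prior variance `s0_sq`. When the empirical
#' spread of `log(sigma2)` does not exceed the sampling component, `d0` is
#' infinite (complete shrinkage). Variances of zero are floored at the 1st
#' percentile of the positive values before taking logs.
#'
#' @param sigma2 per-probe residual variances (>= 10 values).
#' @param df_resid residual degrees of freedom (scalar).
#' @return list with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
estimate_prior <- function(sigma2, df_resid) {
  if (length(sigma2) < 10) stop("need >= 10 probes to estimate the prior")
  pos <- sigma2[sigma2 > 0]
  if (length(pos) == 0) stop("all residual variances are zero")
  floor_val <- as.numeric(quantile(pos, 0.01))
  s2 <- pmax(sigma2, floor_val)
  z <- log(s2)
  if (var(z) < 1e-15) {
    return(list(d0 = Inf, s0_sq = s2[1]))
  }
  df2 <- df_resid / 2
  e <- z - digamma(df2) + log(df2)
  evar <- var(e)
  excess <- evar - trigamma(df2)
  if (excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics from a fitted variance prior
#'
#' Shrinks each probe's residual variance toward the prior:
#' `s2_post = (d0 * s0_sq + df * sigma2) / (d0 + df)`; the moderated t is
#' the slope over its posterior standard error, referred to a t
#' distribution on `d0 + df` degrees of freedom (normal limit when `d0` is
#' infinite). `d0 = 0` reproduces the ordinary t-test.
#'
#' @param fit output of [fit_probe_regressions()].
#' @param prior list with `d0`, `s0_sq` (from [estimate_prior()], or a
#'   manual override).
#' @return `fit` with added columns `s2_post`, `t_mod`, `p_raw`, `df_total`.
#' @export
moderated_t <- function(fit, prior) {
  d0 <- prior$d0
  df <- fit$df_resid
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s0_sq, nrow(fit))
  } else {
    (d0 * prior$s0_sq + df * fit$sigma2) / (d0 + df)
  }
  t_mod <- fit$slope / (sqrt(s2_post) * fit$se_unit)
  df_total <- d0 + df
  p <- 2 * pt(-abs(t_mod), df = df_total)
  fit$s2_post <- s2_post
  fit$t_mod <- t_mod
  fit$p_raw <- p
  fit$df_total <- df_total
  fit
}

#' Call differentially methylated positions
#'
#' Applies the study's call rule: Bonferroni correction over the tested
#' probes and a minimum absolute group methylation difference. The effect
#' size is the difference of group mean beta values (mean tumor - mean
#' normal), not the regression slope.
#'
#' @param stats output of [moderated_t()].
#' @param beta probe x sample beta matrix (same probes, for delta-beta).
#' @param groups per-sample `"normal"`/`"tumor"` labels.
#' @param alpha adjusted p-value threshold (default 0.01).
#' @param delta minimum `|delta_beta|` (default 0.2, i.e. 20%).
#' @return DMP table sorted by `p_adj`, then decreasing `|delta_beta|`,
#'   ties broken by `probe_id`; columns include `p_adj` (Bonferroni),
#'   `delta_beta`, and `significant`.
#' @export
call_dmps <- function(stats, beta, groups, alpha = 0.01, delta = 0.2) {
  if (!all(c("normal", "tumor") %in% groups)) {
    stop("both normal and tumor samples are required")
  }
  if (alpha <= 0 || alpha >= 1 || delta <= 0 || delta >= 1) {
    stop("alpha and delta must lie in (0, 1)")
  }
  beta <- beta[match(stats$probe_id, rownames(beta)), , drop = FALSE]
  db <- rowMeans(beta[, groups == "tumor", drop = FALSE]) -
    rowMeans(beta[, groups == "normal", drop = FALSE])
  n_tested <- nrow(stats)
  stats$p_adj <- pmin(1, stats$p_raw * n_tested)
  stats$delta_beta <- as.numeric(db)
  stats$significant <- stats$p_adj < alpha & abs(stats$delta_beta) > delta
  ord <- order(stats$p_adj, -abs(stats$delta_beta), stats$probe_id)
  stats <- stats[ord, ]
  rownames(stats) <- NULL
  attr(stats, "n_tested") <- n_tested
  stats
}

#' Correlation of profile-wide methylation with cellularity
#'
#' Pearson correlation between each sample's mean beta over a probe set
#' (typically the significant DMPs) and tumor cellularity.
#'
#' @param beta probe x sample beta matrix.
#' @param dmp_ids probe identifiers defining the profile (>= 1).
#' @param x per-sample cellularity.
#' @return Pearson r, or `NA` (with a warning) when either vector has zero
#'   variance.
#' @export
profile_correlation <- function(beta, dmp_ids, x) {
  if (length(dmp_ids) < 1) stop("need >= 1 profile probe")
  if (length(x) < 3) stop("need >= 3 samples")
  prof <- colMeans(beta[rownames(beta) %in% dmp_ids, , drop = FALSE])
  if (sd(prof) == 0 || sd(x) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(prof, x)
}

#' Unsupervised 2-group clustering of samples on a probe set
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance on beta values restricted to the given probes), cut at two
#' clusters; agreement with the true labels is the adjusted Rand index.
#'
#' @param beta probe x sample beta matrix restricted to significant probes
#'   (>= 2 probes).
#' @param groups true per-sample labels (>= 2 samples per group).
#' @return list with `cluster` (integer partition) and `agreement`
#'   (adjusted Rand index in `[-1, 1]`, 1 = perfect).
#' @export
cluster_samples <- function(beta, groups) {
  if (nrow(beta) < 2) stop("need >= 2 probes for clustering")
  if (min(table(groups)) < 2) stop("need >= 2 samples per group")
  hc <- hclust(dist(t(beta)), method = "complete")
  part <- cutree(hc, k = 2)
  list(cluster = part,
       agreement = mclust::adjustedRandIndex(part, groups))
}
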