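test_that("per-probe OLS matches the closed-form slope", {
  x <- c(0, 0, 0, 0.5, 0.7, 0.9)
  M <- rbind(
    line = 1 + 2 * x,
    const = rep(3, 6)
  )
  colnames(M) <- paste0("S", 1:6)
  fit <- fit_probe_regressions(M, x)
  expect_equal(fit$slope[1], 2)
  expect_lt(fit$sigma2[1], 1e-24)
  expect_equal(fit$slope[2], 0)
  expect_equal(fit$df_resid, c(4L, 4L))

  # closed-form oracle on random probes: slope = cov(x, M) / var(x)
  set.seed(4)
  R <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, colnames(M)))
  fr <- fit_probe_regressions(R, x)
  oracle <- apply(R, 1, function(m) cov(x, m) / var(x))
  expect_equal(fr$slope, unname(oracle), tolerance = 1e-12)
  # sigma2 equals RSS / (n - 2) from lm on a few probes
  for (i in c(1, 17, 42)) {
    lmf <- lm(R[i, ] ~ x)
    expect_equal(fr$sigma2[i], sum(residuals(lmf)^2) / 4, tolerance = 1e-12)
    expect_equal(fr$slope[i], unname(coef(lmf)[2]), tolerance = 1e-12)
  }

  expect_error(fit_probe_regressions(M, rep(0.5, 6)), "distinct")
})

test_that("variance prior estimation recovers known hyperparameters", {
  # degenerate: identical variances give a point-mass prior
  pr <- estimate_prior(rep(4, 100), 10)
  expect_equal(pr$d0, Inf)
  expect_equal(pr$s0_sq, 4)

  # recovery of a scaled inverse-chi-square prior (d0 = 4, s0^2 = 2)
  set.seed(11)
  d0 <- 4; s0 <- 2; df <- 20; n <- 20000
  sigma2_true <- s0 * d0 / rchisq(n, d0)
  s2_obs <- sigma2_true * rchisq(n, df) / df
  est <- estimate_prior(s2_obs, df)
  expect_lt(abs(est$d0 - d0) / d0, 0.10)
  expect_lt(abs(est$s0_sq - s0) / s0, 0.05)

  # scale equivariance: d0 invariant, s0_sq scales
  est3 <- estimate_prior(3 * s2_obs, df)
  expect_equal(est3$d0, est$d0, tolerance = 1e-8)
  expect_equal(est3$s0_sq, 3 * est$s0_sq, tolerance = 1e-8)

  expect_error(estimate_prior(rep(1, 5), 10), ">= 10")
})

test_that("prior estimation agrees with the limma moment estimator", {
  skip_if_not_installed("limma")
  set.seed(12)
  s2 <- 1.5 * 6 / rchisq(5000, 6) * rchisq(5000, 15) / 15
  ours <- estimate_prior(s2, 15)
  ref <- limma::fitFDist(s2, df1 = 15)
  expect_equal(ours$d0, ref$df2, tolerance = 0.02)
  expect_equal(ours$s0_sq, ref$scale, tolerance = 0.02)
})

test_that("moderated t interpolates between no and full shrinkage", {
  set.seed(13)
  x <- c(rep(0, 8), runif(10, 0.5, 0.9))
  M <- matrix(rnorm(200 * 18), 200, 18, dimnames = list(NULL, paste0("S", 1:18)))
  fit <- fit_probe_regressions(M, x)

  # d0 = 0: ordinary t, p matches the textbook OLS t-test
  plain <- moderated_t(fit, list(d0 = 0, s0_sq = 1))
  t_ref <- fit$slope / (sqrt(fit$sigma2) * fit$se_unit)
  expect_equal(plain$t_mod, t_ref, tolerance = 1e-12)
  for (i in c(3, 50, 111)) {
    lmp <- summary(lm(M[i, ] ~ x))$coefficients[2, 4]
    expect_equal(plain$p_raw[i], lmp, tolerance = 1e-10)
  }

  # d0 = Inf: posterior variance pinned at s0_sq
  full <- moderated_t(fit, list(d0 = Inf, s0_sq = 0.8))
  expect_true(all(full$s2_post == 0.8))

  # fixed point: sigma2 exactly s0_sq is unchanged for any d0
  fp <- fit[1, ]
  fp$sigma2 <- 0.7
  out <- moderated_t(fp, list(d0 = 3, s0_sq = 0.7))
  expect_equal(out$s2_post, 0.7)

  # interpolation: s2_post between sigma2 and s0_sq for finite d0
  mid <- moderated_t(fit, list(d0 = 4, s0_sq = median(fit$sigma2)))
  lo <- pmin(fit$sigma2, median(fit$sigma2))
  hi <- pmax(fit$sigma2, median(fit$sigma2))
  expect_true(all(mid$s2_post >= lo - 1e-12 & mid$s2_post <= hi + 1e-12))
})

test_that("moderation matches limma's squeezeVar/eBayes machinery", {
  skip_if_not_installed("limma")
  set.seed(14)
  x <- c(rep(0, 6), runif(9, 0.5, 0.9))
  M <- matrix(rnorm(300 * 15, sd = rep(runif(300, 0.5, 2), 15)), 300, 15,
              dimnames = list(paste0("cg", 1:300), paste0("S", 1:15)))
  fit <- fit_probe_regressions(M, x)
  prior <- estimate_prior(fit$sigma2, fit$df_resid[1])
  ours <- moderated_t(fit, prior)

  lfit <- limma::lmFit(M, cbind(1, x))
  leb <- limma::eBayes(lfit)
  # same posterior variances given the same prior inputs
  sq <- limma::squeezeVar(fit$sigma2, fit$df_resid[1])
  expect_equal(ours$s2_post, sq$var.post, tolerance = 0.02)
  # moderated t and p agree with limma's own pipeline
  expect_equal(ours$t_mod, leb$t[, 2], tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(ours$p_raw, leb$p.value[, 2], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("DMP calling enforces both the p and effect-size rules", {
  stats <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    slope = c(2, 2, 0.1, 2),
    sigma2 = 1, df_resid = 10, se_unit = 0.3,
    s2_post = 1, t_mod = c(9, 9, 0.5, 9),
    p_raw = c(1e-9, 1e-6, 0.5, 2e-3),
    df_total = 14,
    stringsAsFactors = FALSE
  )
  beta <- rbind(
    a = c(0.1, 0.1, 0.5, 0.5),
    b = c(0.1, 0.1, 0.18, 0.18),   # strong p but |delta beta| = 0.08
    c = c(0.5, 0.5, 0.52, 0.48),
    d = c(0.2, 0.2, 0.55, 0.55)
  )
  colnames(beta) <- paste0("S", 1:4)
  groups <- group_labels(2, 2)
  out <- call_dmps(stats, beta, groups, alpha = 0.01, delta = 0.2)

  expect_equal(out$p_adj, pmin(1, out$p_raw * 4))
  expect_equal(out$p_adj[out$probe_id == "a"], 4e-9)
  a <- out[out$probe_id == "a", ]
  expect_equal(a$delta_beta, 0.4)
  expect_true(a$significant)
  expect_false(out$significant[out$probe_id == "b"])   # fails delta rule
  expect_false(out$significant[out$probe_id == "c"])
  # d: p_adj = 8e-3 < 0.01 and delta = 0.35 > 0.2 -> significant
  expect_true(out$significant[out$probe_id == "d"])
  # sorted by p_adj then |delta_beta|
  expect_equal(out$probe_id, c("a", "b", "d", "c"))

  expect_error(call_dmps(stats, beta, rep("tumor", 4)), "normal")
  expect_error(call_dmps(stats, beta, groups, alpha = 0), "alpha")
})

test_that("p_adj is monotone in p_raw and bounded", {
  set.seed(15)
  stats <- data.frame(
    probe_id = sprintf("p%03d", 1:50),
    slope = 0, sigma2 = 1, df_resid = 10, se_unit = 1,
    s2_post = 1, t_mod = 0, p_raw = runif(50), df_total = 12,
    stringsAsFactors = FALSE
  )
  beta <- matrix(runif(50 * 6), 50, 6,
                 dimnames = list(stats$probe_id, paste0("S", 1:6)))
  out <- call_dmps(stats, beta, group_labels(3, 3))
  expect_true(all(out$p_adj >= out$p_raw))
  expect_true(all(out$p_adj <= 1))
  expect_true(all(diff(out$p_adj) >= 0))
})

test_that("profile correlation behaves under linear and degenerate input", {
  x <- c(0, 0, 0.5, 0.6, 0.8)
  beta <- matrix(rep(0.1 + 0.3 * x, each = 4), 4, byrow = FALSE)
  rownames(beta) <- paste0("p", 1:4)
  colnames(beta) <- paste0("S", 1:5)
  expect_equal(profile_correlation(beta, rownames(beta), x), 1)
  # flipping the direction of association flips the sign exactly
  expect_equal(profile_correlation(beta, rownames(beta), -x), -1)
  const <- matrix(0.4, 4, 5, dimnames = dimnames(beta))
  expect_warning(r <- profile_correlation(const, rownames(const), x), "zero")
  expect_true(is.na(r))
})

test_that("hierarchical clustering separates well-spiked groups", {
  set.seed(16)
  n_probe <- 60
  normal <- matrix(rnorm(n_probe * 8, 0.2, 0.02), n_probe, 8)
  tumor <- matrix(rnorm(n_probe * 8, 0.6, 0.02), n_probe, 8)
  beta <- cbind(normal, tumor)
  colnames(beta) <- paste0("S", 1:16)
  groups <- group_labels(8, 8)
  res <- cluster_samples(beta, groups)
  expect_equal(res$agreement, 1)

  # cloning every sample leaves a clean 2-cluster structure
  dup <- cbind(beta, beta)
  res2 <- cluster_samples(dup, c(groups, groups))
  expect_equal(res2$agreement, 1)

  # no signal: agreement near zero
  null <- matrix(rnorm(n_probe * 16, 0.4, 0.05), n_probe, 16,
                 dimnames = dimnames(beta))
  res3 <- cluster_samples(null, groups)
  expect_lt(abs(res3$agreement), 0.3)

  expect_error(cluster_samples(beta[1, , drop = FALSE], groups), ">= 2")
})
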