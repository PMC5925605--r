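#' Beta value from methylated/unmethylated intensities
#'
#' beta = meth / (meth + unmeth + offset). The offset (default 100) is a
#' conventional stabilizer against near-zero total intensities. Works
#' elementwise on scalars, vectors or matrices.
#'
#' @param meth,unmeth non-negative intensities (same shape).
#' @param offset non-negative stabilizer added to the denominator.
#' @return beta values in `[0, 1]`, same shape as the inputs. A zero
#'   denominator yields beta 0 with a warning.
#' @export
compute_beta <- function(meth, unmeth, offset = 100) {
  if (any(meth < 0) || any(unmeth < 0) || offset < 0) {
    stop("intensities and offset must be non-negative")
  }
  den <- meth + unmeth + offset
  zero <- den == 0
  if (any(zero)) {
    warning(sum(zero), " zero-signal entries set to beta = 0")
    den[zero] <- 1
  }
  b <- meth / den
  b[zero] <- 0
  b
}

#' M-value (logit2) transform of beta values
#'
#' M = log2(beta / (1 - beta)) after clipping beta into
#' `[eps, 1 - eps]`, which guarantees finite values. Strictly increasing in
#' beta; [m_to_beta()] inverts it on the clipped range.
#'
#' @param beta values in `[0, 1]`.
#' @param eps clipping bound (default 1e-6).
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  assert_prob(beta, "beta")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Inverse of the M-value transform
#' @param m M-values.
#' @return beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Probe-level quality filtering
#'
#' Removes probes failing the detection p-value rule and probes flagged as
#' overlapping a SNP at the interrogated site. Under the default `"any"`
#' policy a probe is dropped when its detection p exceeds the threshold in
#' one or more samples (the strictest reading); `det_policy = "fraction"`
#' drops a probe when more than `det_fraction` of its samples fail.
#'
#' @param signal list with `meth`, `unmeth`, `detection_p` matrices sharing
#'   dimnames (probes x samples).
#' @param manifest probe manifest covering all probes in `signal`.
#' @param det_threshold detection p-value threshold (default 0.01).
#' @param det_policy `"any"` (default) or `"fraction"`.
#' @param det_fraction failing-sample fraction for the `"fraction"` policy.
#' @return list with `signal` (filtered matrices), `manifest` (filtered),
#'   and `dropped` (data.frame of `probe_id`, `reason` in
#'   `{"detection", "snp"}`; detection takes precedence when both apply).
#' @export
filter_probes <- function(signal, manifest, det_threshold = 0.01,
                          det_policy = c("any", "fraction"),
                          det_fraction = 0.5) {
  det_policy <- match.arg(det_policy)
  probes <- rownames(signal$meth)
  if (!all(probes %in% manifest$probe_id)) {
    stop("manifest does not cover all probes in the signal matrices")
  }
  m <- manifest[match(probes, manifest$probe_id), ]
  fail_frac <- rowMeans(signal$detection_p > det_threshold)
  det_fail <- if (det_policy == "any") fail_frac > 0 else fail_frac > det_fraction
  snp_fail <- m$snp_flag & !det_fail
  drop <- det_fail | m$snp_flag
  if (all(drop)) stop("all probes removed by QC filtering")
  dropped <- data.frame(
    probe_id = probes[drop],
    reason = ifelse(det_fail[drop], "detection", "snp"),
    stringsAsFactors = FALSE
  )
  keep <- !drop
  list(
    signal = lapply(signal, function(x) x[keep, , drop = FALSE]),
    manifest = m[keep, ],
    dropped = dropped
  )
}

#' Quantile normalization across columns
#'
#' Forces every column to share the same empirical distribution: the
#' row-wise mean of the column-sorted values. Ties within a column receive
#' the mean of their rank range (average ranks, linearly interpolated into
#' the reference distribution). Row and column names are preserved.
#'
#' @param x numeric matrix with >= 2 columns and no missing values.
#' @return normalized matrix, same shape.
#' @export
quantile_normalize <- function(x) {
  if (any(is.na(x))) stop("missing values not allowed")
  if (ncol(x) < 2) {
    warning("single-column input returned unchanged")
    return(x)
  }
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    approx(seq_along(ref), ref, xout = rank(col, ties.method = "average"))$y
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Sample-level quality control
#'
#' Two per-sample screens mirroring standard array QC: (1) a genome-wide
#' methylation density check -- a good sample's beta distribution is
#' bimodal, so samples whose fraction of betas in the mid-band
#' `[0.3, 0.7]` exceeds `midband_max` fail the bimodality screen; (2)
#' multidimensional scaling of 1 - Pearson correlation distances into two
#' dimensions, flagging samples whose distance from the centroid is more
#' than `mds_k` median absolute deviations above the median distance.
#'
#' @param beta probe x sample beta matrix (>= 3 samples).
#' @param midband_max maximum tolerated mid-band fraction (default 0.35).
#' @param mds_k robust z threshold for MDS outliers (default 5).
#' @return data.frame per sample: `sample_id`, `midband_fraction`,
#'   `bimodality_pass`, `mds_x`, `mds_y`, `mds_outlier`.
#' @export
sample_qc <- function(beta, midband_max = 0.35, mds_k = 5) {
  if (ncol(beta) < 3) stop("sample QC needs >= 3 samples")
  midband <- colMeans(beta >= 0.3 & beta <= 0.7)
  sds <- apply(beta, 2, sd)
  if (any(sds == 0) || all(apply(beta, 1, sd) == 0)) {
    warning("constant beta values; MDS coordinates set to 0, no outliers")
    xy <- matrix(0, ncol(beta), 2)
    out <- rep(FALSE, ncol(beta))
  } else {
    d <- as.dist(1 - cor(beta))
    xy <- cmdscale(d, k = 2)
    cen <- colMeans(xy)
    dc <- sqrt(rowSums(sweep(xy, 2, cen)^2))
    s <- mad(dc)
    out <- if (s == 0) rep(FALSE, length(dc)) else (dc - median(dc)) / s > mds_k
  }
  data.frame(
    sample_id = colnames(beta),
    midband_fraction = as.numeric(midband),
    bimodality_pass = as.numeric(midband) <= midband_max,
    mds_x = xy[, 1], mds_y = xy[, 2],
    mds_outlier = out,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
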