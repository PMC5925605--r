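#' Cluster probes by genomic proximity
#'
#' Greedy chaining: a new cluster starts whenever the chromosome changes or
#' the gap to the previous probe exceeds `maxgap`. Every probe belongs to
#' exactly one cluster and clusters are maximal.
#'
#' @param manifest ordered probe manifest.
#' @param maxgap maximum within-cluster gap in bp (default 500).
#' @return data.frame `probe_id`, `chrom`, `pos`, `cluster` (integer id,
#'   increasing along the genome).
#' @export
cluster_probes <- function(manifest, maxgap = 500) {
  gap <- c(Inf, diff(manifest$pos))
  new_chrom <- c(TRUE, manifest$chrom[-1] != manifest$chrom[-nrow(manifest)])
  brk <- new_chrom | gap > maxgap
  data.frame(
    probe_id = manifest$probe_id,
    chrom = manifest$chrom,
    pos = manifest$pos,
    cluster = cumsum(brk),
    stringsAsFactors = FALSE
  )
}

#' Per-probe group methylation difference
#'
#' @param beta probe x sample beta matrix.
#' @param groups per-sample `"normal"`/`"tumor"` labels.
#' @return named vector of delta-beta (mean tumor - mean normal) per probe.
#' @export
probe_level_values <- function(beta, groups) {
  if (!all(c("normal", "tumor") %in% groups)) {
    stop("both groups must be present")
  }
  rowMeans(beta[, groups == "tumor", drop = FALSE]) -
    rowMeans(beta[, groups == "normal", drop = FALSE])
}

#' Running-mean smoothing within probe clusters
#'
#' Truncated running mean of half-width `(window - 1) / 2`: near cluster
#' edges the window shrinks to the available neighbors; clusters smaller
#' than the window average whatever is available. `window = 1` is the
#' identity.
#'
#' @param values per-probe numeric vector (manifest order).
#' @param clusters integer cluster ids from [cluster_probes()].
#' @param window odd positive window size (default 3).
#' @return smoothed vector, same length.
#' @export
smooth_in_clusters <- function(values, clusters, window = 3L) {
  if (window < 1 || window %% 2 == 0) stop("window must be a positive odd integer")
  if (window == 1) return(values)
  n <- length(values)
  brk <- c(TRUE, clusters[-1] != clusters[-n])
  if (anyDuplicated(clusters[brk])) stop("cluster ids must form contiguous runs")
  h <- (window - 1L) %/% 2L
  first <- which(brk)
  last <- c(first[-1] - 1L, n)
  ci <- cumsum(brk)
  i <- seq_len(n)
  lo <- pmax(i - h, first[ci])
  hi <- pmin(i + h, last[ci])
  cs <- cumsum(c(0, values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Find candidate bump regions
#'
#' Maximal runs of consecutive probes within one cluster whose smoothed
#' value exceeds `cutoff` in absolute value with a common sign. Runs with
#' fewer than `min_probes` probes are discarded.
#'
#' @param smoothed smoothed per-probe values (manifest order).
#' @param clusters cluster ids from [cluster_probes()].
#' @param manifest the probe manifest (for coordinates).
#' @param cutoff minimum `|smoothed|` (default 0.2).
#' @param min_probes minimum run length (default 3).
#' @return data.frame of candidate regions: `chrom`, `start`, `end`
#'   (1-based inclusive probe coordinates), `n_probes`, `value` (mean
#'   smoothed delta-beta over the run), `area` (sum of `|smoothed|`), plus
#'   `idx_start`/`idx_end` row indices into the manifest.
#' @export
find_bumps <- function(smoothed, clusters, manifest, cutoff = 0.2,
                       min_probes = 3L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  state <- ifelse(abs(smoothed) > cutoff, sign(smoothed), 0)
  brk <- c(TRUE, state[-1] != state[-length(state)] |
             clusters[-1] != clusters[-length(clusters)])
  run <- cumsum(brk)
  keep <- which(state != 0)
  if (length(keep) == 0) return(.empty_regions())
  regs <- lapply(split(keep, run[keep]), function(idx) {
    if (length(idx) < min_probes) return(NULL)
    data.frame(
      chrom = manifest$chrom[idx[1]],
      start = manifest$pos[idx[1]],
      end = manifest$pos[idx[length(idx)]],
      n_probes = length(idx),
      value = mean(smoothed[idx]),
      area = sum(abs(smoothed[idx])),
      idx_start = idx[1],
      idx_end = idx[length(idx)],
      stringsAsFactors = FALSE
    )
  })
  regs <- do.call(rbind, regs)
  if (is.null(regs)) return(.empty_regions())
  regs <- regs[order(regs$idx_start), ]
  rownames(regs) <- NULL
  regs
}

.empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             n_probes = integer(), value = numeric(), area = numeric(),
             idx_start = integer(), idx_end = integer(),
             stringsAsFactors = FALSE)
}

# One bump-hunting pass: delta-beta -> smooth -> candidate regions.
.bump_pass <- function(beta, groups, clusters, manifest, cutoff, min_probes,
                       window) {
  vals <- probe_level_values(beta, groups)
  sm <- smooth_in_clusters(vals, clusters, window)
  find_bumps(sm, clusters, manifest, cutoff, min_probes)
}

#' Resampling family-wise error rates for candidate regions
#'
#' Builds null datasets (by default permuting the sample group labels,
#' which is exact under two-group exchangeability; a residual-bootstrap
#' alternative resamples group-centered residuals and adds them to the
#' pooled probe means) and, in each of `B` iterations, records the maximum
#' candidate `|value|` produced by the identical bump-hunting machinery.
#' The FWER of an observed region is `(1 + #{null max >= |value|}) / (B + 1)`.
#'
#' @param beta probe x sample beta matrix (manifest order).
#' @param groups per-sample labels.
#' @param manifest probe manifest.
#' @param maxgap clustering gap (default 500 bp).
#' @param cutoff,min_probes,window bump parameters (see [find_bumps()],
#'   [smooth_in_clusters()]).
#' @param B number of resampling iterations (default 1000).
#' @param seed RNG seed.
#' @param null `"permute"` (default) or `"bootstrap-residual"`.
#' @return the observed candidate table with an `fwer` column.
#' @export
resampling_fwer <- function(beta, groups, manifest, maxgap = 500,
                            cutoff = 0.2, min_probes = 3L, window = 3L,
                            B = 1000L, seed = 1L,
                            null = c("permute", "bootstrap-residual")) {
  null <- match.arg(null)
  if (B < 1) stop("B must be >= 1")
  cl <- cluster_probes(manifest, maxgap)$cluster
  obs <- .bump_pass(beta, groups, cl, manifest, cutoff, min_probes, window)
  if (nrow(obs) == 0) {
    obs$fwer <- numeric(0)
    return(obs)
  }
  # canonical sample order (by name) so that shuffling the input columns
  # leaves the resampled nulls, and hence the FWERs, bit-identical
  canon <- order(colnames(beta) %||% seq_len(ncol(beta)))
  null_max <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      if (null == "permute") {
        ng <- groups
        ng[canon] <- groups[canon][sample(length(canon))]
        cand <- .bump_pass(beta, ng, cl, manifest, cutoff, min_probes, window)
      } else {
        gm <- rowMeans(beta)
        resid <- beta - cbind(
          rowMeans(beta[, groups == "normal", drop = FALSE]),
          rowMeans(beta[, groups == "tumor", drop = FALSE])
        )[, as.integer(groups == "tumor") + 1L]
        pick <- sample(length(canon), replace = TRUE)
        nb <- beta
        nb[, canon] <- pmin(pmax(gm + resid[, canon[pick]], 0), 1)
        cand <- .bump_pass(nb, groups, cl, manifest, cutoff, min_probes, window)
      }
      if (nrow(cand) == 0) 0 else max(abs(cand$value))
    }, numeric(1))
  })
  obs$fwer <- vapply(abs(obs$value), function(v) {
    (1 + sum(null_max >= v)) / (B + 1)
  }, numeric(1))
  if (1 / (B + 1) > 0.01) {
    warning("B = ", B, " gives an FWER floor of ", signif(1 / (B + 1), 3),
            "; increase B to resolve FWER < 0.01")
  }
  obs
}

#' End-to-end DMR detection
#'
#' Convenience wrapper: cluster probes, compute group delta-beta, smooth,
#' find candidate bumps, and attach resampling FWERs.
#'
#' @inheritParams resampling_fwer
#' @param fwer_threshold regions at or above this FWER get `reported =
#'   FALSE` (default 0.01); all candidates are returned.
#' @return candidate region table with `fwer` and `reported` columns.
#' @export
find_dmrs <- function(beta, groups, manifest, maxgap = 500, cutoff = 0.2,
                      min_probes = 3L, window = 3L, B = 1000L, seed = 1L,
                      null = "permute", fwer_threshold = 0.01) {
  out <- resampling_fwer(beta, groups, manifest, maxgap, cutoff, min_probes,
                         window, B, seed, null)
  out$reported <- out$fwer < fwer_threshold
  out
}
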