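#' Total probe intensity
#'
#' @param signal list with `meth` and `unmeth` matrices.
#' @return elementwise sum, probe x sample.
#' @export
total_intensity <- function(signal) {
  signal$meth + signal$unmeth
}

#' Copy-number log ratios against the median of normals
#'
#' Columns are quantile normalized, each probe is divided by its median
#' over the normal samples, and the ratio is log10 transformed; 0 is
#' diploid, log10(CN/2) the expected value of a CN-copy segment at
#' purity 1. Zero medians are floored to the smallest positive median with
#' a warning; probes with all-zero intensity are returned as `NA` rows and
#' listed in the `excluded` attribute.
#'
#' @param T probe x sample total-intensity matrix (from
#'   [total_intensity()]).
#' @param normal_ids column names of the normal samples (>= 2).
#' @param normalize quantile normalize the columns first (default TRUE).
#' @return log10 ratio matrix, probe x sample.
#' @export
log_ratio <- function(T, normal_ids, normalize = TRUE) {
  if (length(normal_ids) < 2) stop("need >= 2 normal samples")
  if (!all(normal_ids %in% colnames(T))) stop("unknown normal sample ids")
  all_zero <- rowSums(T) == 0
  Tn <- if (normalize) quantile_normalize(T) else T
  med <- apply(Tn[, normal_ids, drop = FALSE], 1, median)
  zero_med <- med <= 0 & !all_zero
  if (any(zero_med)) {
    warning(sum(zero_med), " zero normal medians floored to smallest positive")
    med[zero_med] <- min(med[med > 0])
  }
  med[all_zero] <- 1
  L <- log10(Tn / med)
  L[all_zero, ] <- NA_real_
  attr(L, "excluded") <- rownames(T)[all_zero]
  L
}

#' Shrink single-probe outliers toward their local median
#'
#' For each sample and chromosome (in genomic order), a probe whose value
#' deviates from the median of its +/-2-probe neighborhood (self excluded)
#' by more than `k_sd` sample standard deviations is shrunk to that median
#' plus/minus `k_sd * sd`, preserving the sign of the deviation.
#' Chromosomes with fewer than 5 probes pass through unchanged.
#'
#' @param L log-ratio matrix (manifest order).
#' @param manifest probe manifest aligned with the rows of `L`.
#' @param k_sd deviation threshold in sample SDs (default 4).
#' @return smoothed matrix, same shape.
#' @export
smooth_outliers <- function(L, manifest, k_sd = 4) {
  out <- L
  chrom_idx <- split(seq_len(nrow(L)), manifest$chrom)
  for (s in seq_len(ncol(L))) {
    x <- L[, s]
    sdev <- sd(x, na.rm = TRUE)
    if (is.na(sdev) || sdev == 0) next
    for (idx in chrom_idx) {
      n <- length(idx)
      if (n < 5) next
      v <- x[idx]
      med <- vapply(seq_len(n), function(i) {
        nb <- v[setdiff(max(1L, i - 2L):min(n, i + 2L), i)]
        median(nb, na.rm = TRUE)
      }, numeric(1))
      dev <- v - med
      far <- !is.na(dev) & abs(dev) > k_sd * sdev
      v[far] <- med[far] + sign(dev[far]) * k_sd * sdev
      out[idx, s] <- v
    }
  }
  out
}

# Best mean-shift split of a numeric vector: for every split point i
# (left = 1..i), the pooled two-sample t statistic between left and right
# means, computed in O(n) via cumulative sums. Returns the argmax split and
# its |t|; splits leave at least `min_width` points on each side.
best_split <- function(x, min_width = 2L) {
  n <- length(x)
  if (n < 2 * min_width) return(NULL)
  cs <- cumsum(x)
  css <- cumsum(x^2)
  i <- min_width:(n - min_width)
  nl <- i
  nr <- n - i
  ml <- cs[i] / nl
  mr <- (cs[n] - cs[i]) / nr
  ssl <- css[i] - nl * ml^2
  ssr <- (css[n] - css[i]) - nr * mr^2
  sp2 <- pmax(ssl + ssr, 0) / (n - 2)
  denom <- sqrt(sp2 * (1 / nl + 1 / nr))
  t <- ifelse(denom == 0, ifelse(ml == mr, 0, Inf), abs(ml - mr) / denom)
  k <- which.max(t)
  list(split = i[k], t = t[k])
}

# Permutation p-value for the best split of `x`, with early stopping once
# the exceedance count makes acceptance (p < alpha) impossible.
split_p_value <- function(x, t_obs, n_perm, alpha, min_width = 2L) {
  count <- 0L
  limit <- alpha * (n_perm + 1)
  for (b in seq_len(n_perm)) {
    bs <- best_split(sample(x), min_width)
    if (!is.null(bs) && bs$t >= t_obs) {
      count <- count + 1L
      if (count + 1 >= limit) return((count + 1) / (n_perm + 1))
    }
  }
  (count + 1) / (n_perm + 1)
}

#' Recursive binary segmentation with permutation testing
#'
#' At each interval the split maximizing the two-sample t statistic between
#' left and right means is found; it is accepted when its permutation
#' p-value (random shuffles of the interval's values, re-maximizing each
#' time) is below `alpha`, and the procedure recurses on both halves.
#'
#' @param x ordered numeric vector (one sample, one chromosome).
#' @param alpha change-point significance level (default 0.01).
#' @param n_perm permutations per tested split (default 10000; reduce for
#'   desk-scale runs).
#' @param seed RNG seed.
#' @param min_width minimum points on each side of a split (default 2).
#' @return sorted integer change points: indices of the last element of
#'   each left-hand segment (empty when no split is accepted).
#' @export
binary_segment <- function(x, alpha = 0.01, n_perm = 10000L, seed = 1L,
                           min_width = 2L) {
  if (length(x) < 2) return(integer(0))
  if (n_perm < 1 / alpha) {
    warning("n_perm = ", n_perm, " cannot resolve p < ", alpha,
            " (permutation floor ", signif(1 / (n_perm + 1), 3), ")")
  }
  recurse <- function(x, offset) {
    bs <- best_split(x, min_width)
    if (is.null(bs)) return(integer(0))
    p <- split_p_value(x, bs$t, n_perm, alpha, min_width)
    if (p >= alpha) return(integer(0))
    i <- bs$split
    c(recurse(x[seq_len(i)], offset),
      offset + i,
      recurse(x[(i + 1):length(x)], offset + i))
  }
  with_seed(seed, sort(recurse(x, 0L)))
}

#' Segment every sample's genome
#'
#' Runs [binary_segment()] per sample per chromosome and returns the full
#' partition (all segments, qualifying or not) with per-segment means.
#'
#' @param L log-ratio matrix (manifest order); `NA` probes are skipped.
#' @param manifest probe manifest aligned with `L`.
#' @param alpha,n_perm,min_width see [binary_segment()].
#' @param seed base seed; each sample/chromosome gets a deterministic
#'   sub-seed.
#' @return data.frame: `sample_id`, `chrom`, `start`, `end` (1-based
#'   inclusive probe coordinates), `idx_start`, `idx_end`, `n_markers`,
#'   `mean_log_ratio`.
#' @export
segment_genome <- function(L, manifest, alpha = 0.01, n_perm = 1000L,
                           seed = 1L, min_width = 2L) {
  chroms <- unique(manifest$chrom)
  res <- list()
  for (s in seq_len(ncol(L))) {
    sid <- colnames(L)[s]
    for (ci in seq_along(chroms)) {
      idx <- which(manifest$chrom == chroms[ci] & !is.na(L[, s]))
      if (length(idx) < 2) next
      x <- L[idx, s]
      sub_seed <- (as.integer(seed) %% 1000000L) * 1000L + s * 29L + ci
      cps <- binary_segment(x, alpha, n_perm, sub_seed, min_width)
      bounds <- c(0L, cps, length(x))
      for (k in seq_len(length(bounds) - 1L)) {
        span <- (bounds[k] + 1L):bounds[k + 1L]
        res[[length(res) + 1L]] <- data.frame(
          sample_id = sid, chrom = chroms[ci],
          start = manifest$pos[idx[span[1]]],
          end = manifest$pos[idx[span[length(span)]]],
          idx_start = idx[span[1]], idx_end = idx[span[length(span)]],
          n_markers = length(span),
          mean_log_ratio = mean(x[span]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call copy-number segments from a genome partition
#'
#' Keeps segments with at least `min_markers` probes whose mean log ratio
#' exceeds `gain_cut` (gain) or falls below `loss_cut` (loss) -- the
#' asymmetric thresholds corresponding to at least one copy gained or
#' lost.
#'
#' @param segments output of [segment_genome()].
#' @param min_markers minimum probes per segment (default 5).
#' @param gain_cut,loss_cut mean log-ratio thresholds (defaults 0.2 and
#'   -0.3).
#' @return qualifying segments with a `direction` column (`gain`/`loss`).
#' @export
call_segments <- function(segments, min_markers = 5L, gain_cut = 0.2,
                          loss_cut = -0.3) {
  keep <- segments$n_markers >= min_markers &
    (segments$mean_log_ratio > gain_cut | segments$mean_log_ratio < loss_cut)
  out <- segments[keep, , drop = FALSE]
  out$direction <- ifelse(out$mean_log_ratio > gain_cut, "gain", "loss")
  rownames(out) <- NULL
  out
}

.seg_granges <- function(df, seqlevels = unique(df$chrom)) {
  GenomicRanges::GRanges(factor(df$chrom, levels = seqlevels),
                         IRanges::IRanges(df$start, df$end))
}

# Build two interval sets on a shared seqlevel universe for overlap queries.
.pair_granges <- function(a, b) {
  lv <- union(unique(a$chrom), unique(b$chrom))
  list(a = .seg_granges(a, lv), b = .seg_granges(b, lv))
}

#' Remove tumor segments shared with normals or overlapping a blacklist
#'
#' A tumor segment is dropped when any normal-sample segment of the same
#' direction covers at least `shared_frac` of the tumor segment's length,
#' or when it overlaps a blacklist interval by at least 1 bp (e.g. the
#' HLA-region exclusion).
#'
#' @param tumor_segs,normal_segs called segment tables (see
#'   [call_segments()]); `normal_segs` may be empty or NULL.
#' @param blacklist optional data.frame with `chrom`, `start`, `end`.
#' @param shared_frac minimum tumor-side overlap fraction (default 0.5).
#' @return filtered tumor segment table.
#' @export
filter_shared_and_blacklist <- function(tumor_segs, normal_segs = NULL,
                                        blacklist = NULL, shared_frac = 0.5) {
  if (nrow(tumor_segs) == 0) return(tumor_segs)
  keep <- rep(TRUE, nrow(tumor_segs))
  if (!is.null(normal_segs) && nrow(normal_segs) > 0) {
    pg <- .pair_granges(tumor_segs, normal_segs)
    tg <- pg$a
    ng <- pg$b
    hits <- GenomicRanges::findOverlaps(tg, ng)
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ow <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(tg)[qi], IRanges::ranges(ng)[si]))
      same_dir <- tumor_segs$direction[qi] == normal_segs$direction[si]
      frac <- ow / IRanges::width(IRanges::ranges(tg)[qi])
      keep[unique(qi[same_dir & frac >= shared_frac])] <- FALSE
    }
  }
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    pg <- .pair_granges(tumor_segs, blacklist)
    keep[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(pg$a, pg$b)))] <- FALSE
  }
  out <- tumor_segs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recurrent copy-number intervals across tumors
#'
#' Per direction, intervals are first reduced within each sample, then a
#' breakpoint sweep counts how many distinct samples cover each genomic
#' position; maximal sub-intervals covered by at least `min_samples`
#' samples are reported with their peak support.
#'
#' @param segs called (and filtered) tumor segment table.
#' @param min_samples minimum distinct supporting samples (default 2).
#' @return data.frame `chrom`, `start`, `end`, `direction`, `n_samples`.
#' @export
recurrent_segments <- function(segs, min_samples = 2L) {
  if (min_samples < 2) stop("min_samples must be >= 2")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_samples = integer(), stringsAsFactors = FALSE)
  if (is.null(segs) || nrow(segs) == 0) return(empty)
  out <- empty
  for (dir in unique(segs$direction)) {
    d <- segs[segs$direction == dir, ]
    per_sample <- lapply(split(d, d$sample_id), function(s) {
      as.data.frame(GenomicRanges::reduce(.seg_granges(s)))
    })
    merged <- do.call(rbind, unname(per_sample))
    cov <- GenomicRanges::coverage(GenomicRanges::GRanges(
      merged$seqnames, IRanges::IRanges(merged$start, merged$end)))
    sl <- IRanges::slice(cov, lower = min_samples)
    for (chrom in names(sl)) {
      v <- sl[[chrom]]
      if (length(v) == 0) next
      out <- rbind(out, data.frame(
        chrom = chrom,
        start = IRanges::start(v), end = IRanges::end(v),
        direction = dir,
        n_samples = as.integer(IRanges::viewMaxs(v)),
        stringsAsFactors = FALSE
      ))
    }
  }
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Overlap recurrent CNVs with DMRs
#'
#' Joins recurrent copy-number intervals with differentially methylated
#' regions on >= 1 bp overlap (1-based inclusive coordinates) and flags
#' hypermethylation concordance (copy gain together with a positive
#' regional delta-beta).
#'
#' @param cnvs recurrent segment table (see [recurrent_segments()]).
#' @param dmrs DMR table with `chrom`, `start`, `end`, `value`.
#' @return one row per overlapping pair with both intervals, the shared
#'   width in bp, and `concordant_hyper`.
#' @export
overlap_dmrs <- function(cnvs, dmrs) {
  empty <- data.frame(chrom = character(), cnv_start = integer(),
                      cnv_end = integer(), direction = character(),
                      dmr_start = integer(), dmr_end = integer(),
                      dmr_value = numeric(), overlap_bp = integer(),
                      concordant_hyper = logical(), stringsAsFactors = FALSE)
  if (nrow(cnvs) == 0 || nrow(dmrs) == 0) return(empty)
  pg <- .pair_granges(cnvs, dmrs)
  cg <- pg$a
  dg <- pg$b
  hits <- GenomicRanges::findOverlaps(cg, dg)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ow <- IRanges::width(IRanges::pintersect(IRanges::ranges(cg)[qi],
                                           IRanges::ranges(dg)[si]))
  data.frame(
    chrom = cnvs$chrom[qi],
    cnv_start = cnvs$start[qi], cnv_end = cnvs$end[qi],
    direction = cnvs$direction[qi],
    dmr_start = dmrs$start[si], dmr_end = dmrs$end[si],
    dmr_value = dmrs$value[si],
    overlap_bp = as.integer(ow),
    concordant_hyper = cnvs$direction[qi] == "gain" & dmrs$value[si] > 0,
    stringsAsFactors = FALSE
  )
}
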