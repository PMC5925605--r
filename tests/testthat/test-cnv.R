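test_that("total intensity is the elementwise sum and symmetric", {
  s <- list(meth = matrix(c(300, 0), 1), unmeth = matrix(c(200, 0), 1))
  expect_equal(total_intensity(s), matrix(c(500, 0), 1))
  s2 <- list(meth = s$unmeth, unmeth = s$meth)
  expect_equal(total_intensity(s2), total_intensity(s))
})

test_that("log ratios reference the median of normals", {
  # without normalization the arithmetic is exact
  T <- cbind(N1 = c(100, 200), N2 = c(100, 200), N3 = c(100, 200),
             T1 = c(200, 100))
  rownames(T) <- c("p1", "p2")
  L <- log_ratio(T, c("N1", "N2", "N3"), normalize = FALSE)
  expect_equal(unname(L[, "N1"]), c(0, 0))
  expect_equal(L["p1", "T1"], log10(2), tolerance = 1e-12)
  expect_equal(L["p2", "T1"], log10(0.5), tolerance = 1e-12)

  # quantile-normalized path still centers normals near zero
  set.seed(2)
  Tn <- matrix(rlnorm(500 * 6, log(3000), 0.5), 500, 6)
  Tn <- Tn[, c(1, 1, 1, 2, 3, 4)] * exp(matrix(rnorm(3000, 0, 0.05), 500))
  colnames(Tn) <- c(paste0("N", 1:3), paste0("T", 1:3))
  rownames(Tn) <- paste0("p", 1:500)
  Ln <- log_ratio(Tn, paste0("N", 1:3))
  expect_lt(abs(median(Ln[, 1:3])), 0.01)

  expect_error(log_ratio(T, "N1"), ">= 2")
})

test_that("single-probe outliers are shrunk toward the local median", {
  man <- manual_manifest(seq(1000, 20000, by = 1000))
  x <- rep(0, 20)
  x[10] <- 1
  L <- matrix(x, dimnames = list(man$probe_id, NULL))
  sm <- smooth_outliers(L, man, k_sd = 2)
  sdx <- sd(x)
  expect_equal(unname(sm[10, 1]), 0 + 2 * sdx)  # shrunk to median + k * sd
  expect_equal(unname(sm[-10, 1]), x[-10])      # neighbors untouched

  # no outliers: identity
  L2 <- matrix(rep(c(0, 0.01), 10), 20, dimnames = dimnames(L))
  expect_equal(smooth_outliers(L2, man, k_sd = 4), L2)

  # short chromosomes pass through unchanged
  man3 <- manual_manifest(c(1, 2, 3, 4), chrom = rep("chrS", 4))
  L3 <- matrix(c(0, 5, 0, 0), dimnames = list(man3$probe_id, NULL))
  expect_equal(smooth_outliers(L3, man3, k_sd = 1), L3)
})

test_that("the best split matches an exhaustive max-t oracle", {
  exhaustive <- function(x, min_width = 2) {
    n <- length(x)
    best <- NULL
    for (i in min_width:(n - min_width)) {
      l <- x[1:i]; r <- x[(i + 1):n]
      sp <- (sum((l - mean(l))^2) + sum((r - mean(r))^2)) / (n - 2)
      tt <- if (sp == 0) {
        if (mean(l) == mean(r)) 0 else Inf
      } else abs(mean(l) - mean(r)) / sqrt(sp * (1 / i + 1 / (n - i)))
      if (is.null(best) || tt > best$t) best <- list(split = i, t = tt)
    }
    best
  }
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(6:50, 1)
    x <- rnorm(n) + rep(c(0, sample(c(0, 1, 2), 1)), c(n %/% 2, n - n %/% 2))
    got <- methylforge:::best_split(x)
    ref <- exhaustive(x)
    expect_equal(got$split, ref$split)
    expect_equal(got$t, ref$t, tolerance = 1e-9)
  }
})

test_that("binary segmentation finds a clean step and nothing in constants", {
  x <- c(rep(0, 25), rep(0.5, 25))
  cp <- binary_segment(x, alpha = 0.01, n_perm = 300, seed = 3)
  expect_equal(cp, 25)
  expect_equal(binary_segment(rep(0.3, 40), alpha = 0.01, n_perm = 300,
                              seed = 3), integer(0))
  expect_warning(binary_segment(x, alpha = 0.01, n_perm = 50, seed = 1),
                 "floor")

  # noisy step still splits within a couple of probes
  set.seed(4)
  xn <- c(rnorm(30, 0, 0.05), rnorm(30, 0.4, 0.05))
  cpn <- binary_segment(xn, alpha = 0.01, n_perm = 300, seed = 5)
  expect_true(any(abs(cpn - 30) <= 2))
})

test_that("segment partitioning and calling respect the thresholds", {
  segs <- data.frame(
    sample_id = "T1", chrom = "chr1",
    start = c(1, 100, 200), end = c(99, 199, 400),
    idx_start = 1, idx_end = 2,
    n_markers = c(4, 6, 6),
    mean_log_ratio = c(0.5, 0.25, -0.25),
    stringsAsFactors = FALSE
  )
  out <- call_segments(segs, min_markers = 5, gain_cut = 0.2, loss_cut = -0.3)
  # 4 markers rejected; 0.25 gain kept; -0.25 not a loss (asymmetric cut)
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_log_ratio, 0.25)
  expect_equal(out$direction, "gain")

  segs$mean_log_ratio[3] <- -0.35
  out2 <- call_segments(segs, 5, 0.2, -0.3)
  expect_setequal(out2$direction, c("gain", "loss"))
})

test_that("segments partition each chromosome", {
  fx <- noiseless_cohort()
  co <- fx$cohort
  man <- fx$manifest
  T <- total_intensity(co$signal)
  nid <- co$samples$sample_id[co$samples$group == "normal"]
  L <- log_ratio(T, nid, normalize = FALSE)
  segs <- segment_genome(L[, 1:4], man, alpha = 0.01, n_perm = 200, seed = 7)
  for (sid in colnames(L)[1:4]) {
    for (ch in unique(man$chrom)) {
      s <- segs[segs$sample_id == sid & segs$chrom == ch, ]
      s <- s[order(s$idx_start), ]
      idx <- which(man$chrom == ch)
      expect_equal(s$idx_start[1], idx[1])
      expect_equal(s$idx_end[nrow(s)], idx[length(idx)])
      if (nrow(s) > 1) {
        expect_true(all(s$idx_start[-1] == s$idx_end[-nrow(s)] + 1))
      }
    }
  }
})

test_that("shared-with-normal and blacklisted segments are removed", {
  tum <- data.frame(sample_id = "T1", chrom = "chr1",
                    start = c(100, 1000, 5000), end = c(200, 1200, 5100),
                    n_markers = 6, mean_log_ratio = c(0.4, 0.4, -0.5),
                    direction = c("gain", "gain", "loss"),
                    stringsAsFactors = FALSE)
  nor <- data.frame(sample_id = "N1", chrom = "chr1",
                    start = c(50, 4990), end = c(250, 5150),
                    n_markers = 6, mean_log_ratio = c(0.4, 0.4),
                    direction = c("gain", "gain"),
                    stringsAsFactors = FALSE)
  out <- filter_shared_and_blacklist(tum, nor)
  # first gain fully inside a normal gain -> dropped;
  # loss overlapping a normal gain -> kept (directions differ)
  expect_setequal(out$start, c(1000, 5000))

  bl <- data.frame(chrom = "chr1", start = 1200, end = 1200)
  out2 <- filter_shared_and_blacklist(tum, NULL, blacklist = bl)
  expect_setequal(out2$start, c(100, 5000))   # 1 bp overlap drops it
})

test_that("recurrent segments are breakpoint intersections across samples", {
  segs <- data.frame(
    sample_id = c("T1", "T2"), chrom = "chr1",
    start = c(100, 150), end = c(200, 250),
    n_markers = 6, mean_log_ratio = 0.4, direction = "gain",
    stringsAsFactors = FALSE
  )
  out <- recurrent_segments(segs, 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 150)
  expect_equal(out$end, 200)
  expect_equal(out$n_samples, 2)

  # identical interval in two samples
  segs2 <- segs
  segs2$start <- c(100, 100); segs2$end <- c(200, 200)
  out2 <- recurrent_segments(segs2, 2)
  expect_equal(c(out2$start, out2$end, out2$n_samples), c(100, 200, 2))

  # single-sample events never appear
  expect_equal(nrow(recurrent_segments(segs[1, ], 2)), 0)

  # duplicated segments within one sample count once
  segs3 <- rbind(segs[1, ], segs[1, ])
  expect_equal(nrow(recurrent_segments(segs3, 2)), 0)
  expect_error(recurrent_segments(segs, 1), ">= 2")
})

test_that("CNV/DMR overlap joins on >= 1 bp with a concordance flag", {
  cnvs <- data.frame(chrom = "chr1", start = 100, end = 200,
                     direction = "gain", n_samples = 3,
                     stringsAsFactors = FALSE)
  dmrs <- data.frame(chrom = "chr1", start = c(150, 500), end = c(300, 600),
                     value = c(0.3, 0.3), stringsAsFactors = FALSE)
  out <- overlap_dmrs(cnvs, dmrs)
  expect_equal(nrow(out), 1)
  expect_equal(out$overlap_bp, 51)     # 1-based inclusive: 150..200
  expect_true(out$concordant_hyper)

  cnvs$direction <- "loss"
  expect_false(overlap_dmrs(cnvs, dmrs)$concordant_hyper)
  expect_equal(nrow(overlap_dmrs(cnvs, dmrs[2, , drop = FALSE])), 0)
})
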