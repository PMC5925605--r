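#' Generate a synthetic array probe manifest
#'
#' Builds an ordered probe manifest emulating the layout of a genome-wide
#' CpG methylation array: probes are scattered over chromosomes with a
#' mixture of short (island-like) and long inter-probe gaps, so that probe
#' clustering at a 500 bp gap threshold yields multi-probe clusters as well
#' as singletons.
#'
#' @param n_probes total number of probes (>= `n_chrom`).
#' @param n_chrom number of chromosomes, named `chr1..chrN`.
#' @param island_fraction fraction of probes annotated as CpG island.
#' @param close_fraction fraction of adjacent probe pairs drawn with a gap
#'   <= 300 bp (well under the 500 bp clustering threshold); the remainder
#'   get gaps of 1-20 kb.
#' @param snp_fraction fraction of probes flagged as overlapping a SNP.
#' @param seed integer RNG seed; fixed seed gives bit-identical manifests.
#' @return a `data.frame` with columns `probe_id`, `chrom`, `pos`, `gene`,
#'   `island_relation` (island/shore/shelf/open_sea), `enhancer`,
#'   `snp_flag`; positions strictly increasing within each chromosome.
#' @export
generate_manifest <- function(n_probes, n_chrom = 1L, island_fraction = 0.8,
                              close_fraction = 0.7, snp_fraction = 0.01,
                              seed = 1L) {
  if (n_probes < 1 || n_chrom < 1) stop("n_probes and n_chrom must be positive")
  if (n_probes < n_chrom) stop("n_probes must be >= n_chrom")
  assert_prob(island_fraction, "island_fraction")
  with_seed(seed, {
    sizes <- rep(n_probes %/% n_chrom, n_chrom)
    extra <- n_probes %% n_chrom
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    chrom <- rep(paste0("chr", seq_len(n_chrom)), times = sizes)
    pos <- unlist(lapply(sizes, function(m) {
      close <- runif(m - 1) < close_fraction
      gaps <- ifelse(close, sample(30:300, m - 1, replace = TRUE),
                     sample(1000:20000, m - 1, replace = TRUE))
      cumsum(c(sample(1000:5000, 1), gaps))
    }), use.names = FALSE)
    rel <- ifelse(runif(n_probes) < island_fraction, "island",
                  sample(c("shore", "shelf", "open_sea"), n_probes,
                         replace = TRUE))
    gene <- unlist(lapply(seq_len(n_chrom), function(k) {
      paste0("GENE", k, "_", ceiling(seq_len(sizes[k]) / 15))
    }), use.names = FALSE)
    gene[rel == "open_sea" & runif(n_probes) < 0.6] <- ""
    data.frame(
      probe_id = sprintf("cg%08d", seq_len(n_probes)),
      chrom = chrom,
      pos = as.integer(pos),
      gene = gene,
      island_relation = rel,
      enhancer = runif(n_probes) < 0.3,
      snp_flag = runif(n_probes) < snp_fraction,
      stringsAsFactors = FALSE
    )
  })
}

# Probe-level baseline methylation mode: CpG islands are mostly
# unmethylated (low mode), open-sea probes mostly methylated (high mode).
.baseline_low_prob <- c(island = 0.9, shore = 0.6, shelf = 0.35, open_sea = 0.2)

#' Default ground-truth design parameters for a synthetic cohort
#'
#' The defaults define the study conditions emulated throughout: 500 spiked
#' differentially methylated positions at a full-cellularity effect of
#' +0.30 beta (99% hypermethylated), eight 10-probe regional bumps placed on
#' whole probe clusters (island-wide hypermethylation), and five recurrent
#' copy-number intervals (two CN=4 gains, one CN=3 gain, two CN=1 losses),
#' each carried by eight tumor samples, with ten spiked DMPs placed inside
#' each CNV interval so that the classifier's CNV-exclusion rule is
#' exercised.
#'
#' @param n_dmp number of spiked DMP probes (0 for a null cohort).
#' @param delta signed beta difference at full cellularity for spiked DMPs.
#' @param hyper_fraction fraction of spiked DMPs with positive delta.
#' @param n_dmr number of spiked regions; each occupies one whole probe
#'   cluster of `dmr_probes` to `dmr_probes + 5` probes.
#' @param dmr_probes minimum probe count of a spiked region's cluster.
#' @param dmr_delta full-cellularity beta shift inside spiked regions.
#' @param cnv_cn integer copy numbers of the recurrent CNV intervals
#'   (all != 2); one interval per entry. The defaults (two-copy gains and
#'   homozygous deletions) are events that clear the calling thresholds
#'   (log ratio > 0.2 / < -0.3) with margin; single-copy events sit at or
#'   below those cuts by construction and are represented separately (see
#'   `recovery_cn`).
#' @param cnv_probes probes spanned by each CNV interval. The default of
#'   120 consecutive probes emulates a large (megabase-scale) event, the
#'   regime in which intensity-based copy-number calling from methylation
#'   arrays is reliable.
#' @param cnv_carriers tumor samples carrying each CNV interval.
#' @param cnv_dmp_overlap spiked DMPs placed inside each recurrent CNV
#'   interval.
#' @param recovery_cn copy numbers of additional single-copy truth
#'   segments (`role = "recovery"`) used to measure segmentation boundary
#'   and level accuracy; they carry no spiked DMPs.
#' @param recovery_carriers tumor samples carrying each recovery segment.
#' @return a list of parameters consumed by [generate_cohort()].
#' @export
truth_params <- function(n_dmp = 500L, delta = 0.3, hyper_fraction = 0.99,
                         n_dmr = 8L, dmr_probes = 10L, dmr_delta = 0.3,
                         cnv_cn = c(4L, 4L, 4L, 0L, 0L), cnv_probes = 120L,
                         cnv_carriers = 8L, cnv_dmp_overlap = 10L,
                         recovery_cn = c(3L, 1L), recovery_carriers = 3L) {
  list(n_dmp = n_dmp, delta = delta, hyper_fraction = hyper_fraction,
       n_dmr = n_dmr, dmr_probes = dmr_probes, dmr_delta = dmr_delta,
       cnv_cn = cnv_cn, cnv_probes = cnv_probes,
       cnv_carriers = cnv_carriers, cnv_dmp_overlap = cnv_dmp_overlap,
       recovery_cn = recovery_cn, recovery_carriers = recovery_carriers)
}

# Lay out ground truth over a manifest. `low_mode` is the logical vector of
# probes whose baseline sits at the low (unmethylated) mode; hypermethylation
# spikes are placed on low-baseline, SNP-free probes so the full effect is
# observable, mirroring island hypermethylation in tumors.
design_truth <- function(manifest, params, low_mode, tumor_ids) {
  n <- nrow(manifest)
  taken <- rep(FALSE, n)

  ## --- CNV intervals: runs of consecutive probes, shared across carriers.
  ## Recurrent intervals host spiked DMPs; recovery intervals (single-copy
  ## events) exist to measure segmentation accuracy.
  cnv <- NULL
  cnv_probe_idx <- integer(0)   # probes inside recurrent intervals only
  cn_all <- c(params$cnv_cn, params$recovery_cn %||% integer(0))
  roles <- rep(c("recurrent", "recovery"),
               c(length(params$cnv_cn), length(params$recovery_cn %||% integer(0))))
  n_carr <- ifelse(roles == "recurrent", params$cnv_carriers,
                   params$recovery_carriers %||% 1L)
  if (length(cn_all) > 0 && length(tumor_ids) >= 2) {
    for (k in seq_along(cn_all)) {
      ok <- FALSE
      for (try in 1:200) {
        s <- sample(n - params$cnv_probes, 1)
        idx <- s:(s + params$cnv_probes - 1)
        if (!any(taken[idx]) &&
            length(unique(manifest$chrom[idx])) == 1) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place CNV interval ", k, "; manifest too small")
      taken[idx] <- TRUE
      # only copy-gain intervals can host spiked DMPs: in a homozygous
      # deletion there is no DNA left to carry a methylation mark
      if (roles[k] == "recurrent" && cn_all[k] > 0) {
        cnv_probe_idx <- c(cnv_probe_idx, idx)
      }
      carriers <- sample(tumor_ids, min(n_carr[k], length(tumor_ids)))
      cnv <- rbind(cnv, data.frame(
        segment_id = paste0("cnv", k),
        chrom = manifest$chrom[s],
        start = manifest$pos[s],
        end = manifest$pos[s + params$cnv_probes - 1],
        sample_id = carriers,
        cn = cn_all[k],
        role = roles[k],
        stringsAsFactors = FALSE
      ))
    }
  }

  ## --- DMR intervals: whole probe clusters of >= dmr_probes probes
  dmr <- NULL
  dmr_probe_idx <- integer(0)
  if (params$n_dmr > 0) {
    cl <- cluster_probes(manifest, maxgap = 500)
    sizes <- table(cl$cluster)
    eligible <- as.integer(names(sizes)[sizes >= params$dmr_probes &
                                          sizes <= params$dmr_probes + 5])
    # only fully low-baseline (unmethylated-island) clusters: a spiked
    # region must be able to express the full shift on every probe
    eligible <- eligible[vapply(eligible, function(g) {
      idx <- which(cl$cluster == g)
      !any(taken[idx]) && all(low_mode[idx])
    }, logical(1))]
    if (length(eligible) < params$n_dmr) {
      stop("not enough free probe clusters of size >= ", params$dmr_probes,
           " for the requested DMR truth; enlarge the manifest")
    }
    chosen <- sample(eligible, params$n_dmr)
    dmr <- do.call(rbind, lapply(seq_along(chosen), function(k) {
      idx <- which(cl$cluster == chosen[k])
      dmr_probe_idx <<- c(dmr_probe_idx, idx)
      taken[idx] <<- TRUE
      data.frame(region_id = paste0("dmr", k),
                 chrom = manifest$chrom[idx[1]],
                 start = manifest$pos[idx[1]],
                 end = manifest$pos[idx[length(idx)]],
                 delta = params$dmr_delta, n_probes = length(idx),
                 stringsAsFactors = FALSE)
    }))
  }

  ## --- scattered DMPs: hyper spikes on low-baseline SNP-free probes
  dmp <- NULL
  if (params$n_dmp > 0) {
    n_rec <- sum(roles == "recurrent")
    n_inside <- if (n_rec > 0 && length(cnv_probe_idx) > 0) {
      min(params$cnv_dmp_overlap * n_rec, params$n_dmp)
    } else 0L
    inside <- integer(0)
    if (n_inside > 0) {
      pool <- cnv_probe_idx[low_mode[cnv_probe_idx] &
                              !manifest$snp_flag[cnv_probe_idx]]
      inside <- sample(pool, min(n_inside, length(pool)))
    }
    n_hyper <- round(params$n_dmp * params$hyper_fraction)
    pool_hyper <- which(low_mode & !taken & !manifest$snp_flag)
    pool_hypo <- which(!low_mode & !taken & !manifest$snp_flag)
    outside_hyper <- sample(pool_hyper, n_hyper - length(inside))
    hypo <- sample(pool_hypo, params$n_dmp - n_hyper)
    dmp <- data.frame(
      probe_id = manifest$probe_id[c(inside, outside_hyper, hypo)],
      delta = c(rep(params$delta, length(inside) + length(outside_hyper)),
                rep(-params$delta, length(hypo))),
      in_cnv = c(rep(TRUE, length(inside)),
                 rep(FALSE, length(outside_hyper) + length(hypo))),
      stringsAsFactors = FALSE
    )
  }

  list(dmp = dmp, dmr = dmr, cnv = cnv)
}

#' Generate a synthetic tumor/normal methylation cohort with known truth
#'
#' Emulates the statistical structure of paired methylated/unmethylated
#' signal-intensity matrices from a 450k-style array: per-probe baseline
#' beta values drawn from a bimodal mixture (low mode near `base_low`, high
#' mode near `base_high`); tumor samples observe, at spiked probes, the
#' cellularity-diluted mixture `c * clip(base + delta, 0, 1) + (1 - c) * base`;
#' multiplicative log-normal total intensities scaled by CN/2 inside a
#' sample's copy-number truth segments; and small detection p-values with a
#' configurable rate of probe-by-sample detection failures. Measurement
#' noise is additive Gaussian on the logit scale, back-transformed, so beta
#' stays inside (0, 1) without clipping.
#'
#' @param manifest probe manifest from [generate_manifest()].
#' @param n_normal number of normal samples (>= 2; cellularity 0).
#' @param n_tumor number of tumor samples.
#' @param truth_design parameter list from [truth_params()], or an already
#'   materialized truth set (list with `dmp`/`dmr`/`cnv`) to reuse across
#'   cohorts (e.g. an independent validation cohort with identical truth).
#' @param intensity_scale median total intensity of a diploid probe.
#' @param noise_sd beta measurement noise: sd of an additive Gaussian on
#'   the M-value (log2 logit) scale, back-transformed to beta
#'   (0 disables noise). The default of 0.3 M-units matches typical
#'   technical-replicate variability of 450k arrays.
#' @param probe_sdlog,sample_sdlog log-normal sd of per-probe baseline
#'   intensity and per-probe-per-sample intensity noise (0 disables).
#' @param base_low,base_high means of the two baseline beta modes.
#' @param base_conc concentration of the baseline Beta draws (higher =
#'   tighter modes).
#' @param cellularity_range tumor cellularity drawn uniformly from this
#'   interval (normals are 0); upper bound capped at 0.9.
#' @param detection_fail_rate probe-by-sample probability of a detection
#'   failure (detection p drawn above 0.02 instead of below 0.005).
#' @param n_replicates number of tumor samples to duplicate as technical
#'   replicates (only the noise terms are re-drawn).
#' @param baseline optional baseline from a previous cohort on the same
#'   manifest (list with `base`, `low_mode`, `lam`): per-probe baseline
#'   methylation and intensity are probe biology, so an independent
#'   validation cohort must share them with the training cohort while
#'   re-drawing samples and noise.
#' @param seed integer RNG seed.
#' @return a list with elements `signal` (list of `meth`, `unmeth`,
#'   `detection_p` probe x sample matrices), `samples` (sample sheet with
#'   `sample_id`, `group`, `cellularity`, `replicate_of`), `truth`, and
#'   `baseline` (pass to a validation cohort).
#' @export
generate_cohort <- function(manifest, n_normal = 16L, n_tumor = 31L,
                            truth_design = truth_params(),
                            intensity_scale = 3000, noise_sd = 0.3,
                            probe_sdlog = 0.5, sample_sdlog = 0.1,
                            base_low = 0.1, base_high = 0.85,
                            base_conc = 50, cellularity_range = c(0.6, 0.9),
                            detection_fail_rate = 5e-4, n_replicates = 0L,
                            baseline = NULL, seed = 1L) {
  if (n_normal < 2) stop("n_normal must be >= 2 (median of normals undefined)")
  if (n_tumor < 1) stop("n_tumor must be >= 1")
  if (max(cellularity_range) > 0.9) stop("tumor cellularity must be <= 0.9")
  n <- nrow(manifest)

  with_seed(seed, {
    samples <- data.frame(
      sample_id = c(sprintf("NORM%03d", seq_len(n_normal)),
                    sprintf("TUM%03d", seq_len(n_tumor))),
      group = rep(c("normal", "tumor"), c(n_normal, n_tumor)),
      cellularity = c(rep(0, n_normal),
                      runif(n_tumor, cellularity_range[1], cellularity_range[2])),
      replicate_of = NA_character_,
      stringsAsFactors = FALSE
    )
    tumor_ids <- samples$sample_id[samples$group == "tumor"]

    if (is.null(baseline)) {
      low_mode <- runif(n) < .baseline_low_prob[manifest$island_relation]
      base <- ifelse(low_mode,
                     rbeta(n, base_low * base_conc, (1 - base_low) * base_conc),
                     rbeta(n, base_high * base_conc, (1 - base_high) * base_conc))
      lam <- intensity_scale * exp(rnorm(n, 0, probe_sdlog))
    } else {
      low_mode <- baseline$low_mode
      base <- baseline$base
      lam <- baseline$lam
    }
    truth <- if (is.null(truth_design$n_dmp)) {
      truth_design                       # pre-materialized truth, reused
    } else {
      design_truth(manifest, truth_design, low_mode, tumor_ids)
    }

    effect <- rep(0, n)
    if (!is.null(truth$dmp)) {
      effect[match(truth$dmp$probe_id, manifest$probe_id)] <- truth$dmp$delta
    }
    if (!is.null(truth$dmr)) {
      for (k in seq_len(nrow(truth$dmr))) {
        idx <- which(manifest$chrom == truth$dmr$chrom[k] &
                       manifest$pos >= truth$dmr$start[k] &
                       manifest$pos <= truth$dmr$end[k])
        effect[idx] <- effect[idx] + truth$dmr$delta[k]
      }
    }

    shifted <- pmin(pmax(base + effect, 0), 1)
    n_samp <- nrow(samples)
    cvec <- samples$cellularity
    # mixture: columns are samples; normals (c = 0) stay at baseline
    beta_mix <- outer(base, 1 - cvec) + outer(shifted, cvec)

    draw_noise <- function(mix) {
      if (noise_sd > 0) {
        # additive Gaussian on the M-value (log2 logit) scale, then
        # back-transformed: keeps beta inside (0, 1) without clipping
        plogis(qlogis(pmin(pmax(mix, 1e-9), 1 - 1e-9)) +
                 matrix(rnorm(length(mix), 0, noise_sd * log(2)), nrow(mix)))
      } else mix
    }
    beta_obs <- draw_noise(beta_mix)

    cnscale <- matrix(1, n, n_samp)
    if (!is.null(truth$cnv)) {
      for (k in seq_len(nrow(truth$cnv))) {
        j <- match(truth$cnv$sample_id[k], samples$sample_id)
        if (is.na(j)) next
        idx <- which(manifest$chrom == truth$cnv$chrom[k] &
                       manifest$pos >= truth$cnv$start[k] &
                       manifest$pos <= truth$cnv$end[k])
        cnscale[idx, j] <- truth$cnv$cn[k] / 2
      }
    }
    draw_intensity_noise <- function(cols) {
      if (sample_sdlog > 0) {
        exp(matrix(rnorm(n * cols, 0, sample_sdlog), n))
      } else matrix(1, n, cols)
    }
    T <- lam * cnscale * draw_intensity_noise(n_samp)

    draw_detp <- function(cols) {
      d <- matrix(runif(n * cols, 0, 0.005), n)
      fail <- matrix(runif(n * cols) < detection_fail_rate, n)
      d[fail] <- runif(sum(fail), 0.02, 1)
      d
    }
    detection_p <- draw_detp(n_samp)

    meth <- beta_obs * T
    unmeth <- (1 - beta_obs) * T
    dimnames(meth) <- dimnames(unmeth) <- dimnames(detection_p) <-
      list(manifest$probe_id, samples$sample_id)

    if (n_replicates > 0) {
      rep_of <- sample(tumor_ids, min(n_replicates, length(tumor_ids)))
      for (sid in rep_of) {
        j <- match(sid, samples$sample_id)
        rid <- paste0(sid, "_REP")
        # same mixture signal and CN state; only noise terms re-drawn
        b <- draw_noise(beta_mix[, j, drop = FALSE])
        Tr <- lam * cnscale[, j] * draw_intensity_noise(1)[, 1]
        meth <- cbind(meth, b[, 1] * Tr)
        unmeth <- cbind(unmeth, (1 - b[, 1]) * Tr)
        detection_p <- cbind(detection_p, draw_detp(1))
        colnames(meth)[ncol(meth)] <- rid
        colnames(unmeth)[ncol(unmeth)] <- rid
        colnames(detection_p)[ncol(detection_p)] <- rid
        samples <- rbind(samples, data.frame(
          sample_id = rid, group = samples$group[j],
          cellularity = samples$cellularity[j], replicate_of = sid,
          stringsAsFactors = FALSE))
      }
    }

    list(signal = list(meth = meth, unmeth = unmeth, detection_p = detection_p),
         samples = samples, truth = truth,
         baseline = list(base = base, low_mode = low_mode, lam = lam))
  })
}
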