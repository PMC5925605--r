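# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small but complete cohort: 3000 probes, 4 chromosomes, modest truth.
small_cohort <- function() {
  fixture("small_cohort", function() {
    man <- generate_manifest(3000, 4, seed = 101)
    co <- generate_cohort(
      man, n_normal = 10, n_tumor = 14,
      truth_design = truth_params(n_dmp = 80, n_dmr = 3, dmr_probes = 8,
                                  cnv_probes = 60,
                                  cnv_carriers = 5, cnv_dmp_overlap = 4,
                                  recovery_carriers = 2),
      seed = 202
    )
    list(manifest = man, cohort = co)
  })
}

# Noise-free cohort for exact-arithmetic checks.
noiseless_cohort <- function() {
  fixture("noiseless_cohort", function() {
    man <- generate_manifest(800, 2, seed = 55)
    co <- generate_cohort(
      man, n_normal = 4, n_tumor = 6,
      truth_design = truth_params(n_dmp = 40, n_dmr = 2, dmr_probes = 6,
                                  cnv_cn = c(4L, 0L),
                                  cnv_probes = 30, cnv_carriers = 3,
                                  cnv_dmp_overlap = 2, recovery_cn = 1L,
                                  recovery_carriers = 2),
      noise_sd = 0, probe_sdlog = 0, sample_sdlog = 0,
      detection_fail_rate = 0,
      cellularity_range = c(0.9, 0.9),
      seed = 77
    )
    list(manifest = man, cohort = co)
  })
}

# Manual probe manifest with explicit positions, single chromosome.
manual_manifest <- function(pos, chrom = rep("chr1", length(pos))) {
  data.frame(
    probe_id = sprintf("p%03d", seq_along(pos)),
    chrom = chrom,
    pos = as.integer(pos),
    gene = "",
    island_relation = "island",
    enhancer = FALSE,
    snp_flag = FALSE,
    stringsAsFactors = FALSE
  )
}

# Beta matrix with named groups: first n_normal columns normal.
manual_beta <- function(values, n_normal, prefix = "S") {
  colnames(values) <- sprintf("%s%02d", prefix, seq_len(ncol(values)))
  values
}

group_labels <- function(n_normal, n_tumor) {
  rep(c("normal", "tumor"), c(n_normal, n_tumor))
}

# Probe ids of a manifest falling inside truth region intervals.
probes_in_intervals <- function(man, intervals) {
  if (is.null(intervals)) return(character(0))
  unlist(lapply(seq_len(nrow(intervals)), function(k) {
    man$probe_id[man$chrom == intervals$chrom[k] &
                   man$pos >= intervals$start[k] &
                   man$pos <= intervals$end[k]]
  }))
}
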