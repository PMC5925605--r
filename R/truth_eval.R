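#' Recovery metrics against a synthetic ground truth
#'
#' Helpers that score pipeline output against the generator's truth set;
#' used by the analysis drivers and the acceptance checks.
#'
#' @name truth_eval
NULL

#' @rdname truth_eval
#' @param dmps DMP table from [call_dmps()].
#' @param truth truth set from [generate_cohort()].
#' @param manifest the (full) probe manifest.
#' @return `dmp_recovery`: list with `recall` (fraction of spiked probes
#'   called significant), `n_true`, `n_called`, and `false_positives`
#'   (significant calls outside every truth probe/region).
#' @export
dmp_recovery <- function(dmps, truth, manifest) {
  sig <- dmps$probe_id[dmps$significant]
  true_ids <- truth$dmp$probe_id
  region_ids <- character(0)
  if (!is.null(truth$dmr)) {
    region_ids <- .interval_probes(manifest, truth$dmr)
  }
  list(
    recall = mean(true_ids %in% sig),
    n_true = length(true_ids),
    n_called = length(sig),
    false_positives = length(setdiff(sig, c(true_ids, region_ids)))
  )
}

.interval_probes <- function(manifest, intervals) {
  unlist(lapply(seq_len(nrow(intervals)), function(k) {
    manifest$probe_id[manifest$chrom == intervals$chrom[k] &
                        manifest$pos >= intervals$start[k] &
                        manifest$pos <= intervals$end[k]]
  }))
}

#' @rdname truth_eval
#' @param dmrs candidate/region table from [find_dmrs()]; only rows with
#'   `reported = TRUE` are scored.
#' @param eval_manifest the manifest the regions were computed on (after
#'   probe filtering).
#' @return `dmr_recovery`: per truth region, the probe-level Jaccard index
#'   between the region's probes and the probes of all reported regions
#'   overlapping it.
#' @export
dmr_recovery <- function(dmrs, truth, eval_manifest) {
  hits <- dmrs[dmrs$reported, , drop = FALSE]
  vapply(seq_len(nrow(truth$dmr)), function(k) {
    ch <- truth$dmr$chrom[k]
    truth_idx <- which(eval_manifest$chrom == ch &
                         eval_manifest$pos >= truth$dmr$start[k] &
                         eval_manifest$pos <= truth$dmr$end[k])
    ov <- hits[hits$chrom == ch & hits$end >= truth$dmr$start[k] &
                 hits$start <= truth$dmr$end[k], , drop = FALSE]
    got <- integer(0)
    for (j in seq_len(nrow(ov))) {
      got <- union(got, which(eval_manifest$chrom == ch &
                                eval_manifest$pos >= ov$start[j] &
                                eval_manifest$pos <= ov$end[j]))
    }
    length(intersect(truth_idx, got)) / length(union(truth_idx, got))
  }, numeric(1))
}

#' @rdname truth_eval
#' @param segments full genome partition from [segment_genome()].
#' @param roles which truth CNV roles to score (default `"recovery"`).
#' @return `cnv_recovery`: data.frame per truth (segment, carrier) pair
#'   with `boundary_error` (probes, the worse of the two edges against the
#'   best-overlapping called segment) and `mean_error`
#'   (`|mean_log_ratio - log10(cn/2)|`; `NA` for homozygous deletions).
#' @export
cnv_recovery <- function(segments, truth, eval_manifest,
                         roles = "recovery") {
  tr <- truth$cnv
  if (!is.null(tr$role)) tr <- tr[tr$role %in% roles, , drop = FALSE]
  out <- lapply(seq_len(nrow(tr)), function(k) {
    ch <- tr$chrom[k]
    truth_idx <- which(eval_manifest$chrom == ch &
                         eval_manifest$pos >= tr$start[k] &
                         eval_manifest$pos <= tr$end[k])
    segs <- segments[segments$sample_id == tr$sample_id[k] &
                       segments$chrom == ch, , drop = FALSE]
    if (nrow(segs) == 0 || length(truth_idx) == 0) {
      return(data.frame(segment_id = tr$segment_id[k],
                        sample_id = tr$sample_id[k], cn = tr$cn[k],
                        boundary_error = NA_real_, mean_error = NA_real_))
    }
    ov <- pmin(segs$idx_end, max(truth_idx)) -
      pmax(segs$idx_start, min(truth_idx)) + 1
    best <- segs[which.max(ov), ]
    expected <- if (tr$cn[k] > 0) log10(tr$cn[k] / 2) else NA_real_
    data.frame(
      segment_id = tr$segment_id[k],
      sample_id = tr$sample_id[k],
      cn = tr$cn[k],
      boundary_error = max(abs(best$idx_start - min(truth_idx)),
                           abs(best$idx_end - max(truth_idx))),
      mean_error = abs(best$mean_log_ratio - expected),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
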