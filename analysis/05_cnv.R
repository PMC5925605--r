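#!/usr/bin/env Rscript
# Stage 5 -- copy-number inference from total intensities.
#
# Sums methylated and unmethylated intensities, quantile normalizes,
# references each probe to the median of the normals, log10 transforms,
# smooths single-probe outliers, segments every sample per chromosome by
# recursive binary segmentation with permutation-tested change points, and
# reports recurrent tumor segments after removing those shared with
# normals, finally intersecting them with the reported DMRs.

library(methylforge)

seed <- 1L
manifest <- read_table_tsv("results/cohort/manifest.tsv")
samples <- read_table_tsv("results/cohort/samples.tsv")
truth <- read_truth("results/cohort/truth.json")
signal <- read_signal("results/cohort")
flt <- filter_probes(signal, manifest)
dmrs <- read_regions_bed("results/dmr/dmr_table.bed.tsv")

T <- total_intensity(flt$signal)
normal_ids <- samples$sample_id[samples$group == "normal"]
L <- log_ratio(T, normal_ids)
L <- smooth_outliers(L, flt$manifest)
segs <- segment_genome(L, flt$manifest, alpha = 0.01, n_perm = 500,
                       seed = stage_seed(seed, "cnv"))
called <- call_segments(segs, min_markers = 5, gain_cut = 0.2,
                        loss_cut = -0.3)
tumor_segs <- called[called$sample_id %in%
                       samples$sample_id[samples$group == "tumor"], ]
normal_segs <- called[called$sample_id %in% normal_ids, ]
filtered <- filter_shared_and_blacklist(tumor_segs, normal_segs)
recurrent <- recurrent_segments(filtered, min_samples = 2)
joint <- overlap_dmrs(recurrent, dmrs[dmrs$reported, ])

dir.create("results/cnv", showWarnings = FALSE, recursive = TRUE)
write_regions_bed(called, "results/cnv/segments.bed.tsv")
if (nrow(recurrent) > 0) {
  write_regions_bed(recurrent, "results/cnv/recurrent.bed.tsv")
}
if (nrow(joint) > 0) write_table_tsv(joint, "results/cnv/cnv_dmr_overlap.tsv")

rec <- cnv_recovery(segs, truth, flt$manifest)
cat(sprintf("%d called segments -> %d after normal/blacklist filtering -> %d recurrent intervals\n",
            nrow(called), nrow(filtered), nrow(recurrent)))
cat(sprintf("single-copy recovery: max boundary error %.0f probes, max level error %.3f\n",
            max(rec$boundary_error), max(rec$mean_error)))
cat(sprintf("%d recurrent CNVs overlap a reported DMR (concordant hypermethylation: %d)\n",
            nrow(joint), sum(joint$concordant_hyper)))
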