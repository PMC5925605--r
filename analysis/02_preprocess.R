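#!/usr/bin/env Rscript
# Stage 2 -- quality control and normalization.
#
# Drops probes failing detection (p > 0.01 in any sample) or overlapping a
# SNP, computes beta values (offset 100), and screens samples for
# non-bimodal methylation density and multidimensional-scaling outliers.

library(methylforge)

manifest <- read_table_tsv("results/cohort/manifest.tsv")
signal <- read_signal("results/cohort")

flt <- filter_probes(signal, manifest, det_threshold = 0.01)
beta <- compute_beta(flt$signal$meth, flt$signal$unmeth, offset = 100)
qc <- sample_qc(beta)

dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)
write_table_tsv(flt$dropped, "results/preprocess/dropped_probes.tsv")
write_table_tsv(qc, "results/preprocess/sample_qc.tsv")
write_matrix_tsv(beta, "results/preprocess/beta.tsv")

cat(sprintf("kept %d of %d probes (%d detection, %d snp); %d/%d samples pass bimodality, %d MDS outliers\n",
            nrow(beta), nrow(manifest),
            sum(flt$dropped$reason == "detection"),
            sum(flt$dropped$reason == "snp"),
            sum(qc$bimodality_pass), nrow(qc), sum(qc$mds_outlier)))
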