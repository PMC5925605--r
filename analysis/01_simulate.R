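#!/usr/bin/env Rscript
# Stage 1 -- simulate the study cohort.
#
# Generates the synthetic 450k-style cohort used throughout the analysis:
# a 20,000-probe manifest over 8 chromosomes, 16 normal and 31 tumor
# samples (tumor cellularity 60-90%), with known ground truth: 500 spiked
# DMPs (delta = 0.3 at full cellularity, 99% hypermethylated), eight
# island-wide regional bumps, three recurrent CN=4 gains and two CN=0
# deletions (8 carriers each, 50 DMPs inside the gains), and CN=3/CN=1
# segments for segmentation-accuracy measurement.

library(methylforge)

seed <- 1L
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

manifest <- generate_manifest(20000, 8, seed = stage_seed(seed, "simulate"))
cohort <- generate_cohort(manifest, n_normal = 16, n_tumor = 31,
                          seed = stage_seed(seed, "simulate"))

write_table_tsv(manifest, "results/cohort/manifest.tsv")
write_table_tsv(cohort$samples, "results/cohort/samples.tsv")
write_truth(cohort$truth, "results/cohort/truth.json")
write_signal(cohort$signal, "results/cohort")
# per-probe baselines are probe biology: persisted so the validation
# cohort in stage 06 shares them
write_table_tsv(data.frame(probe_id = manifest$probe_id,
                           base = cohort$baseline$base,
                           low_mode = cohort$baseline$low_mode,
                           lam = cohort$baseline$lam),
                "results/cohort/baseline.tsv")

cat(sprintf("cohort: %d probes x %d samples; truth: %d DMPs, %d DMRs, %d CNV carrier segments\n",
            nrow(manifest), nrow(cohort$samples),
            nrow(cohort$truth$dmp), nrow(cohort$truth$dmr),
            nrow(cohort$truth$cnv)))
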