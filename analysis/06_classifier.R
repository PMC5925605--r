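#!/usr/bin/env Rscript
# Stage 6 -- minimal CpG diagnostic panel.
#
# From the significant probes: excludes those inside recurrent CNV
# intervals, keeps only fully differentiating probes (rank AUC exactly 1
# in either direction), prunes redundant probes (r^2 > 0.9), chooses the
# L1 penalty by repeated stratified 5-fold cross-validation, fits the
# final L1-regularized logistic model, and evaluates on the training
# cohort plus an independently generated 100-sample validation cohort
# sharing the same ground truth and probe baselines.

library(methylforge)

seed <- 1L
manifest <- read_table_tsv("results/cohort/manifest.tsv")
samples <- read_table_tsv("results/cohort/samples.tsv")
truth <- read_truth("results/cohort/truth.json")
beta <- read_matrix_tsv("results/preprocess/beta.tsv")
dmps <- read_table_tsv("results/diffmeth/dmp_table.tsv")
recurrent <- read_regions_bed("results/cnv/recurrent.bed.tsv")

model <- train_panel(dmps, recurrent, manifest, beta, samples$group,
                     n_rep = 25, seed = stage_seed(seed, "train"))

dir.create("results/classifier", showWarnings = FALSE, recursive = TRUE)
write_panel(model, "results/classifier/panel_model.json",
            provenance = list(seed = seed))

sc_train <- predict_scores(model, beta)
ev_train <- evaluate_panel(sc_train$score, samples$group)
write_table_tsv(sc_train, "results/classifier/scores_training.tsv")

# independent validation cohort: same manifest, truth and probe baselines
bl <- read_table_tsv("results/cohort/baseline.tsv")
val <- generate_cohort(manifest, 50, 50,
                       truth_design = truth,
                       baseline = list(base = bl$base,
                                       low_mode = bl$low_mode,
                                       lam = bl$lam),
                       seed = stage_seed(seed, "validate"))
beta_val <- compute_beta(val$signal$meth, val$signal$unmeth)
sc_val <- predict_scores(model, beta_val)
ev_val <- evaluate_panel(sc_val$score, val$samples$group)
write_table_tsv(sc_val, "results/classifier/scores_validation.tsv")

cat(sprintf("%d candidates after selection -> %d active probes at lambda = %.3g\n",
            length(model$selected_features), model$n_active, model$lambda))
cat(sprintf("training: accuracy %.2f, AUC %.2f\n",
            ev_train$accuracy, ev_train$auc))
cat(sprintf("validation (n = 100): sensitivity %.2f, specificity %.2f, accuracy %.2f, AUC %.2f\n",
            ev_val$sensitivity, ev_val$specificity, ev_val$accuracy,
            ev_val$auc))
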