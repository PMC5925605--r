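#' Default pipeline configuration
#'
#' All stage parameters in one validated list. `scale = "desk"` keeps the
#' resampling sizes small enough for interactive runs (the full-scale
#' settings match the published protocol: 1000 bootstrap iterations for
#' region FWERs, 10000 segmentation permutations, 1000 cross-validation
#' repetitions).
#'
#' @param seed integer master seed; each stage derives its own sub-seed.
#' @param out_dir where artifacts are written.
#' @param scale `"desk"` or `"full"`.
#' @param ... overrides for any default parameter.
#' @return named list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("methylforge_run_"),
                           scale = c("desk", "full"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    scale = scale,
    # synth
    n_probes = 20000L, n_chrom = 8L, n_normal = 16L, n_tumor = 31L,
    truth = truth_params(),
    intensity_scale = 3000, noise_sd = 0.3,
    # preprocess
    det_threshold = 0.01, det_policy = "any", beta_offset = 100,
    # dmp
    alpha = 0.01, delta = 0.2,
    # dmr
    maxgap = 500, dmr_cutoff = 0.2, min_probes = 3L, smooth_window = 3L,
    dmr_B = if (scale == "desk") 200L else 1000L, fwer_threshold = 0.01,
    # cnv
    seg_alpha = 0.01,
    seg_n_perm = if (scale == "desk") 500L else 10000L,
    min_markers = 5L, gain_cut = 0.2, loss_cut = -0.3,
    cnv_k_sd = 4, min_cnv_samples = 2L,
    # classify
    auc_keep = 1.0, r2_cut = 0.9,
    cv_n_rep = if (scale == "desk") 25L else 1000L, cv_n_folds = 5L,
    # validation cohort
    n_validation = 100L
  )
  override <- list(...)
  cfg[names(override)] <- override
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented domain before any
#' computation runs.
#'
#' @param cfg configuration list.
#' @return the configuration, invisibly; errors on the first violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(
    "alpha must be in (0,1)" = cfg$alpha > 0 && cfg$alpha < 1,
    "delta must be in (0,1)" = cfg$delta > 0 && cfg$delta < 1,
    "seg_alpha must be in (0,1)" = cfg$seg_alpha > 0 && cfg$seg_alpha < 1,
    "det_threshold must be in (0,1)" = cfg$det_threshold > 0 && cfg$det_threshold < 1,
    "dmr_cutoff must be positive" = cfg$dmr_cutoff > 0,
    "gain_cut must be positive" = cfg$gain_cut > 0,
    "loss_cut must be negative" = cfg$loss_cut < 0,
    "min_probes must be >= 1" = cfg$min_probes >= 1,
    "min_markers must be >= 1" = cfg$min_markers >= 1,
    "smooth_window must be odd" = cfg$smooth_window %% 2 == 1,
    "n_normal must be >= 2" = cfg$n_normal >= 2,
    "beta_offset must be >= 0" = cfg$beta_offset >= 0
  )
  invisible(cfg)
}

# Canonical hash of a configuration: stable across sessions, stamped into
# every artifact so reruns are attributable.
config_hash <- function(cfg) {
  cfg <- cfg[sort(setdiff(names(cfg), "out_dir"))]
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> differential methylation -> DMRs ->
#' CNVs -> panel training -> evaluation (training cohort, plus an
#' independently generated validation cohort sharing the same ground
#' truth). Every artifact is written under `cfg$out_dir` and stamped with
#' the seed and configuration hash; a rerun with the same configuration is
#' bit-identical.
#'
#' @param cfg configuration from [default_config()].
#' @param quiet suppress per-stage log lines.
#' @return invisible list with all in-memory artifacts: `cohort`, `qc`,
#'   `beta`, `dmps`, `dmrs`, `cnv` (per-sample and recurrent tables),
#'   `model`, `eval_train`, `eval_validation`, and `truth`.
#' @export
run_pipeline <- function(cfg = default_config(), quiet = FALSE) {
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(seed = cfg$seed, config_hash = config_hash(cfg))
  log_line <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  }

  ## simulate
  manifest <- generate_manifest(cfg$n_probes, cfg$n_chrom,
                                seed = stage_seed(cfg$seed, "simulate"))
  cohort <- generate_cohort(manifest, cfg$n_normal, cfg$n_tumor,
                            truth_design = cfg$truth,
                            intensity_scale = cfg$intensity_scale,
                            noise_sd = cfg$noise_sd,
                            seed = stage_seed(cfg$seed, "simulate"))
  write_table_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  write_table_tsv(cohort$samples, file.path(cfg$out_dir, "samples.tsv"))
  write_truth(cohort$truth, file.path(cfg$out_dir, "truth.json"))
  log_line("simulate", nrow(manifest), " probes, ",
           nrow(cohort$samples), " samples")

  ## preprocess
  flt <- filter_probes(cohort$signal, manifest, cfg$det_threshold,
                       cfg$det_policy)
  beta <- compute_beta(flt$signal$meth, flt$signal$unmeth, cfg$beta_offset)
  qc <- sample_qc(beta)
  write_table_tsv(flt$dropped, file.path(cfg$out_dir, "qc_dropped_probes.tsv"))
  write_table_tsv(qc, file.path(cfg$out_dir, "qc_samples.tsv"))
  log_line("preprocess", nrow(beta), " probes kept (",
           nrow(flt$dropped), " dropped); ",
           sum(!qc$bimodality_pass | qc$mds_outlier), " sample flags")

  ## differential methylation
  M <- beta_to_m(beta)
  groups <- cohort$samples$group
  x <- cohort$samples$cellularity
  fit <- fit_probe_regressions(M, x)
  prior <- estimate_prior(fit$sigma2, fit$df_resid[1])
  stats <- moderated_t(fit, prior)
  dmps <- call_dmps(stats, beta, groups, cfg$alpha, cfg$delta)
  write_table_tsv(dmps, file.path(cfg$out_dir, "dmp_table.tsv"))
  log_line("dmp", sum(dmps$significant), " significant probes of ",
           nrow(dmps), " tested")

  ## DMRs
  dmrs <- find_dmrs(beta, groups, flt$manifest, cfg$maxgap, cfg$dmr_cutoff,
                    cfg$min_probes, cfg$smooth_window, cfg$dmr_B,
                    stage_seed(cfg$seed, "dmr"), "permute",
                    cfg$fwer_threshold)
  write_regions_bed(dmrs, file.path(cfg$out_dir, "dmr_table.bed.tsv"))
  log_line("dmr", sum(dmrs$reported), " regions at FWER < ",
           cfg$fwer_threshold, " (", nrow(dmrs), " candidates)")

  ## CNVs
  T <- total_intensity(flt$signal)
  normal_ids <- cohort$samples$sample_id[groups == "normal"]
  L <- log_ratio(T, normal_ids)
  L <- smooth_outliers(L, flt$manifest, cfg$cnv_k_sd)
  segs <- segment_genome(L, flt$manifest, cfg$seg_alpha, cfg$seg_n_perm,
                         stage_seed(cfg$seed, "cnv"))
  called <- call_segments(segs, cfg$min_markers, cfg$gain_cut, cfg$loss_cut)
  tumor_ids <- cohort$samples$sample_id[groups == "tumor"]
  tumor_segs <- called[called$sample_id %in% tumor_ids, , drop = FALSE]
  normal_segs <- called[called$sample_id %in% normal_ids, , drop = FALSE]
  filtered <- filter_shared_and_blacklist(tumor_segs, normal_segs)
  recurrent <- recurrent_segments(filtered, cfg$min_cnv_samples)
  cnv_dmr <- overlap_dmrs(recurrent, dmrs[dmrs$reported, , drop = FALSE])
  write_regions_bed(called, file.path(cfg$out_dir, "cnv_segments.bed.tsv"))
  if (nrow(recurrent) > 0) {
    write_regions_bed(recurrent, file.path(cfg$out_dir, "cnv_recurrent.bed.tsv"))
  }
  log_line("cnv", nrow(called), " called segments, ",
           nrow(recurrent), " recurrent intervals")

  ## panel training
  model <- train_panel(dmps, recurrent, flt$manifest, beta, groups,
                       cfg$auc_keep, cfg$r2_cut, cfg$cv_n_rep,
                       cfg$cv_n_folds, stage_seed(cfg$seed, "train"))
  write_panel(model, file.path(cfg$out_dir, "panel_model.json"), stamp)
  log_line("train", length(model$selected_features), " candidates -> ",
           model$n_active, " active probes (lambda = ",
           signif(model$lambda, 3), ")")

  ## evaluation: training cohort
  sc_train <- predict_scores(model, beta)
  eval_train <- evaluate_panel(sc_train$score, groups)
  write_table_tsv(sc_train, file.path(cfg$out_dir, "scores_training.tsv"))

  ## evaluation: independent validation cohort, same manifest + truth
  val <- generate_cohort(manifest,
                         n_normal = cfg$n_validation %/% 2,
                         n_tumor = cfg$n_validation - cfg$n_validation %/% 2,
                         truth_design = cohort$truth,
                         intensity_scale = cfg$intensity_scale,
                         noise_sd = cfg$noise_sd,
                         baseline = cohort$baseline,
                         seed = stage_seed(cfg$seed, "validate"))
  beta_val <- compute_beta(val$signal$meth, val$signal$unmeth, cfg$beta_offset)
  sc_val <- predict_scores(model, beta_val)
  eval_val <- evaluate_panel(sc_val$score, val$samples$group)
  write_table_tsv(sc_val, file.path(cfg$out_dir, "scores_validation.tsv"))
  ev <- data.frame(
    cohort = c("training", "validation"),
    sensitivity = c(eval_train$sensitivity, eval_val$sensitivity),
    specificity = c(eval_train$specificity, eval_val$specificity),
    accuracy = c(eval_train$accuracy, eval_val$accuracy),
    auc = c(eval_train$auc, eval_val$auc),
    seed = stamp$seed, config_hash = stamp$config_hash
  )
  write_table_tsv(ev, file.path(cfg$out_dir, "evaluation.tsv"))
  log_line("evaluate", "training acc ", round(eval_train$accuracy, 3),
           "; validation sens ", round(eval_val$sensitivity, 3),
           " spec ", round(eval_val$specificity, 3))

  invisible(list(cohort = cohort, manifest = manifest, qc = qc,
                 dropped = flt$dropped, beta = beta, dmps = dmps,
                 dmrs = dmrs, cnv = list(partition = segs,
                                         segments = called,
                                         filtered = filtered,
                                         recurrent = recurrent,
                                         dmr_overlap = cnv_dmr),
                 model = model, eval_train = eval_train,
                 eval_validation = eval_val, truth = cohort$truth,
                 stamp = stamp))
}
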