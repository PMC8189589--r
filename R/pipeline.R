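#' Default pipeline configuration
#'
#' Reduced-scale settings that exercise every stage end-to-end on a desktop
#' CPU: a 51-scan cohort (23 paired + 5 unpaired subjects) on 150 ROI /
#' 400 brain voxels, 30 train/test splits over K = 2..10, 200 permutations,
#' 100 surrogates and 500 VIP bootstraps.
#'
#' @param seed Master seed; per-stage streams are derived from it.
#' @param outdir Output directory (NULL = no files written).
#' @param ... Overrides for any listed setting.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL, ...) {
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              n_paired = 23L, n_unpaired = 5L,
              n_roi_vox = 150L, n_brain_vox = 400L,
              planted_rho = 0.8, drug_shift = 1, noise_sd = 0.2,
              K_set = 2:10, K_full = 8L,
              n_splits = 30L, n_perm = 200L,
              scheme_kind = "block", pair_preserving_split = FALSE,
              n_rounds = 100L, n_match_perm = 50L,
              n_surrogates = 100L,
              n_samples = 153L, n_genes = 400L, n_signal = 40L,
              effect_beta = 1, expr_noise_sd = 0.3,
              pls_components = 2:10, pls_folds = 5L, pls_repeats = 5L,
              n_pls_perm = 200L, n_boot = 500L, vip_components = 6L,
              n_random_sets = 1000L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full covariation pipeline on a synthetic cohort
#'
#' Generates a cohort with planted ground truth, then runs every stage in
#' dependency order: relative maps, the cross-validated mode test, the
#' full-sample mode and covariation influence maps, the surrogate-based
#' network overlap test, the drug-challenge analyses, the expression
#' preparation and PLS stage, bootstrap VIP ranking and median-rank
#' enrichment.  All randomness derives from the master seed, so reruns with
#' the same config are bit-identical.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file of
#'   overrides).
#' @return A list of class `result_bundle` with per-stage results, the
#'   planted truth, and provenance (seed and config hash).
#' @export
run_full <- function(config = pipeline_config()) {
  if (is.character(config)) {
    overrides <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, overrides)
  }
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  log_stage <- function(fmt, ...) message(sprintf(paste0("[crossmode] ", fmt), ...))

  log_stage("generating cohort: %d paired + %d unpaired subjects",
            cfg$n_paired, cfg$n_unpaired)
  sim <- generate_paired_cohort(
    n_paired = cfg$n_paired, n_unpaired = cfg$n_unpaired,
    n_roi_vox = cfg$n_roi_vox, n_brain_vox = cfg$n_brain_vox,
    planted_rho = cfg$planted_rho, drug_shift = cfg$drug_shift,
    noise_sd = cfg$noise_sd, seed = .child_seed(cfg$seed, "cohort"))
  sim <- add_synthetic_expression(
    sim, n_samples = cfg$n_samples, n_genes = cfg$n_genes,
    n_signal = cfg$n_signal, effect_beta = cfg$effect_beta,
    noise_sd = cfg$expr_noise_sd, seed = .child_seed(cfg$seed, "expression"))
  cohort <- sim$cohort
  mats <- cohort_matrices(cohort)
  log_stage("cohort ready: %d scans, %d ROI voxels, %d brain voxels",
            nrow(cohort$scans), ncol(mats$P), ncol(mats$C))

  log_stage("cross-validated mode test (%d splits, %d permutations)",
            cfg$n_splits, cfg$n_perm)
  mode_test <- cross_validated_mode_test(
    mats$P, mats$C, cohort$scans, K_set = cfg$K_set,
    n_splits = cfg$n_splits, n_perm = cfg$n_perm,
    scheme_kind = cfg$scheme_kind,
    pair_preserving_split = cfg$pair_preserving_split,
    seed = .child_seed(cfg$seed, "mode_test"))

  log_stage("matching accuracy test (%d rounds)", cfg$n_rounds)
  matching <- matching_accuracy_test(
    mats$P, mats$C, cohort$scans, K = cfg$K_full, n_rounds = cfg$n_rounds,
    n_perm = cfg$n_match_perm, scheme_kind = cfg$scheme_kind,
    seed = .child_seed(cfg$seed, "matching"))

  log_stage("full-sample mode (K = %d) and influence maps", cfg$K_full)
  mode <- fit_cca_mode(mats$P, mats$C, cfg$K_full)
  influence_roi <- covariation_influence(mats$P, mode$variates[, "striatal"])
  influence_brain <- covariation_influence(mats$C, mode$variates[, "cbf"])

  log_stage("surrogate maps and network overlap (%d surrogates)",
            cfg$n_surrogates)
  surr <- generate_surrogates(influence_brain, cohort$brain_coords,
                              n_surrogates = cfg$n_surrogates,
                              seed = .child_seed(cfg$seed, "surrogates"))
  overlap <- network_overlap_test(influence_brain, cohort$parcellation, surr)

  log_stage("drug-challenge analyses")
  scores <- data.frame(striatal = mode$variates[, "striatal"],
                       cbf = mode$variates[, "cbf"])
  challenge <- list(
    delta = delta_score_correlation(scores, cohort$scans),
    placebo_trained = local({
      pt <- placebo_trained_scores(mats$P, mats$C, cohort$scans, cfg$K_full)
      delta_score_correlation(pt$scores, cohort$scans)
    }),
    subjective_all = subjective_effect_correlation(
      scores, rowSums(cohort$subjective), cohort$scans, "all"),
    subjective_drug = subjective_effect_correlation(
      scores, rowSums(cohort$subjective), cohort$scans, "drug_only"))

  log_stage("expression preparation and PLS")
  set.seed(.child_seed(cfg$seed, "pls"))
  prep <- prepare_expression(cohort$probes, cohort$roi_coords)
  y <- influence_roi[prep$voxel]
  pls_cv <- cv_pls_accuracy(prep$X, y, components = cfg$pls_components,
                            folds = cfg$pls_folds, repeats = cfg$pls_repeats)
  surr_roi <- generate_surrogates(influence_roi, cohort$roi_coords,
                                  n_surrogates = cfg$n_surrogates,
                                  seed = .child_seed(cfg$seed, "roi_surrogates"))
  set.seed(.child_seed(cfg$seed, "pls_perm"))
  pls_sig <- pls_significance(prep$X, y, n_perm = cfg$n_pls_perm,
                              surrogate_y = surr_roi$maps[, prep$voxel,
                                                          drop = FALSE],
                              components = cfg$pls_components,
                              folds = cfg$pls_folds, repeats = 1L)

  log_stage("bootstrap VIP ranking (%d resamples)", cfg$n_boot)
  set.seed(.child_seed(cfg$seed, "vip"))
  ranking <- bootstrap_vip_ranking(prep$X, y,
                                   n_components = cfg$vip_components,
                                   n_boot = cfg$n_boot)

  log_stage("median-rank enrichment (%d random sets per gene set)",
            cfg$n_random_sets)
  set.seed(.child_seed(cfg$seed, "enrichment"))
  enrichment <- enrichment_table(ranking, cohort$gene_sets,
                                 n_random = cfg$n_random_sets)

  hashed <- unclass(cfg)
  hashed$outdir <- NULL  # provenance reflects the analysis, not file paths
  cfg_json <- jsonlite::toJSON(hashed, auto_unbox = TRUE, null = "null")
  bundle <- structure(list(
    config = cfg, truth = sim$truth, scans = cohort$scans,
    mode_test = mode_test, matching = matching, mode = mode,
    influence = list(roi = influence_roi, brain = influence_brain),
    overlap = overlap, challenge = challenge,
    expression_prep = list(n_matched = nrow(prep$X), dropped = prep$dropped),
    pls = list(cv = pls_cv, significance = pls_sig),
    ranking = ranking, enrichment = enrichment,
    provenance = list(seed = cfg$seed, config_hash = .str_hash(cfg_json),
                      package_version = as.character(utils::packageVersion("crossmode")))),
    class = "result_bundle")

  if (!is.null(cfg$outdir)) write_result_bundle(bundle, cohort, cfg$outdir)
  bundle
}

#' Persist a result bundle
#'
#' Writes summary JSON, the gene ranking and enrichment tables as TSV, and
#' the influence maps as NIfTI volumes.
#'
#' @param bundle A [run_full()] result.
#' @param cohort The cohort the bundle was computed on (for masks).
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_result_bundle <- function(bundle, cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    seed = bundle$provenance$seed,
    config_hash = bundle$provenance$config_hash,
    mean_oos_r = bundle$mode_test$mean_oos_r,
    per_K_r = as.list(bundle$mode_test$per_K_r),
    mode_p = bundle$mode_test$p_value,
    matching_accuracy = bundle$matching$accuracy,
    matching_null_mean = bundle$matching$null_mean,
    delta_rho = bundle$challenge$delta$rho,
    delta_p = bundle$challenge$delta$p,
    pls_cv_r = bundle$pls$cv$overall,
    pls_best_ncomp = bundle$pls$cv$best_n_components,
    pls_p_perm = bundle$pls$significance$p_perm,
    pls_p_surrogate = bundle$pls$significance$p_surrogate)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(bundle$ranking, file.path(outdir, "gene_ranking.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(bundle$enrichment, file.path(outdir, "enrichment.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_ranked_list(bundle$ranking,
                    file.path(outdir, "ranked_genes_desc.tsv"),
                    file.path(outdir, "ranked_genes_asc.tsv"))
  roi_mask <- cm_mask(cohort$roi_coords, cohort$spacing)
  brain_mask <- cm_mask(cohort$brain_coords, cohort$spacing)
  write_map_nifti(bundle$influence$roi, roi_mask,
                  file.path(outdir, "influence_roi.nii.gz"))
  write_map_nifti(bundle$influence$brain, brain_mask,
                  file.path(outdir, "influence_brain.nii.gz"))
  invisible(outdir)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("crossmode result bundle\n")
  cat(sprintf("  mode test: mean out-of-sample r = %.3f, p = %.4g\n",
              x$mode_test$mean_oos_r, x$mode_test$p_value))
  cat(sprintf("  matching accuracy = %.0f%% (null %.0f%%)\n",
              100 * x$matching$accuracy, 100 * x$matching$null_mean))
  cat(sprintf("  delta-score Spearman rho = %.2f (p = %.3g)\n",
              x$challenge$delta$rho, x$challenge$delta$p))
  cat(sprintf("  gene PLS: cv r = %.2f, p_perm = %.4g, p_surrogate = %.4g\n",
              x$pls$cv$overall, x$pls$significance$p_perm,
              x$pls$significance$p_surrogate))
  cat(sprintf("  planted enrichment p = %.4g\n",
              x$enrichment$p[x$enrichment$set == "planted"]))
  invisible(x)
}
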