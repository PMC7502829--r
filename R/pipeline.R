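#' Pipeline configuration
#'
#' Bundles every stage setting of the end-to-end analysis: the cohort
#' source (a [simulation_config()] or a directory of NIfTI/CSV inputs),
#' the EZ voxel threshold, the cluster-extent null mode and alpha, the
#' group pooling fraction, the normative bootstrap count, permutation
#' settings, the predictor domains and the master seed (fanned out to
#' per-stage seeds by fixed offsets).
#'
#' @param cohort a [simulation_config()] or a directory path.
#' @param replicate optional replicate-cohort source (same forms).
#' @param u EZ voxel threshold (strict |EZ| > u; default 1.96).
#' @param alpha family-wise cluster alpha (default 0.05).
#' @param cluster_null `"mc"` (Monte-Carlo on the skeleton, default) or
#'   `"grf"` (analytic 3D).
#' @param optimize run the ROC threshold sweep instead of fixing (u,
#'   alpha).
#' @param frequency_fraction group pooling fraction (default 0.25).
#' @param B normative bootstrap replicates.
#' @param n_fields Monte-Carlo null fields for the extent threshold.
#' @param n_perm permutations for the significance test.
#' @param perm_mode `"fast"` (fixed subset) or `"full"` (RFE refit per
#'   permutation).
#' @param domains predictor domains to fit (`"fa"`, `"cytokine"`).
#' @param subsample_reps repeated-subsampling repetitions per test size
#'   (0 disables the profile).
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = simulation_config(),
                            replicate = NULL,
                            u = 1.96, alpha = 0.05,
                            cluster_null = c("mc", "grf"),
                            optimize = FALSE,
                            frequency_fraction = 0.25,
                            B = 200L, n_fields = 500L,
                            n_perm = 500L,
                            perm_mode = c("fast", "full"),
                            domains = c("fa", "cytokine"),
                            subsample_reps = 0L,
                            seed = 1L) {
  structure(list(cohort = cohort, replicate = replicate, u = u,
                 alpha = alpha, cluster_null = match.arg(cluster_null),
                 optimize = optimize,
                 frequency_fraction = frequency_fraction,
                 B = as.integer(B), n_fields = as.integer(n_fields),
                 n_perm = as.integer(n_perm),
                 perm_mode = match.arg(perm_mode),
                 domains = match.arg(domains, several.ok = TRUE),
                 subsample_reps = as.integer(subsample_reps),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_cohort <- function(source) {
  if (inherits(source, "cohort_bundle")) return(source)
  if (inherits(source, "simulation_config")) return(generate_cohort(source))
  if (is.character(source)) {
    x <- read_skeleton_cohort(source)
    x$covariates <- read.csv(file.path(source, "covariates.csv"))
    x$cytokines <- read.csv(file.path(source, "cytokines.csv"))
    x$outcomes <- read.csv(file.path(source, "outcomes.csv"))
    class(x) <- "cohort_bundle"
    return(x)
  }
  stop("unsupported cohort source")
}

# Features of one cohort cut against a (possibly foreign) normative model
# and catalogue: covariate-adjusted patient FA means per catalogue cluster,
# plus cytokine columns.
cohort_features <- function(bundle, model, catalogue,
                            domains = c("fa", "cytokine"),
                            who = c("patient", "control")) {
  ids <- bundle$covariates$id[bundle$covariates$group %in% who]
  fa_adj <- adjust_fa(bundle$fa[ids, , drop = FALSE], model,
                      bundle$covariates)
  out <- list()
  if ("fa" %in% domains && length(catalogue) > 0)
    out$fa <- extract_features(fa_adj, catalogue)
  if ("cytokine" %in% domains)
    out$cytokine <- cytokine_features(bundle$cytokines, ids)
  out
}

#' Run the full lesion-load prognostic pipeline
#'
#' Executes, in order: cohort simulation or ingestion; recovery labelling
#' against the norms table; matched control split and bootstrap normative
#' model; EZ maps for patients and held-out normal controls; smoothness
#' estimation; extent-threshold determination (fixed or ROC-optimized);
#' group cluster catalogue; per-domain feature extraction; SVM-RFE,
#' LOOCV, optional subsampling profile and permutation test; SVR score
#' prediction (processing speed, then working memory with the same
#' subset); importance filtering; and, when a replicate source is
#' configured, frozen external validation with the original model and
#' catalogue. Rerunning with the same config reproduces every number.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_result` list; see the elements for per-stage
#'   outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  bundle <- load_cohort(config$cohort)
  norms <- if (inherits(config$cohort, "simulation_config"))
    config$cohort$norms_table else default_norms()

  pat_ids <- bundle$covariates$id[bundle$covariates$group == "patient"]
  ctl_ids <- bundle$covariates$id[bundle$covariates$group == "control"]
  labels <- label_recovery(
    bundle$outcomes[bundle$outcomes$id %in% pat_ids, ], norms)

  model <- build_normative_model(bundle$fa[ctl_ids, , drop = FALSE],
                                 bundle$covariates, B = config$B,
                                 seed = seed)
  normal_ids <- model$split$normal
  ez_pat <- compute_ez(bundle$fa[pat_ids, , drop = FALSE], model,
                       bundle$covariates)
  ez_ctl <- compute_ez(bundle$fa[normal_ids, , drop = FALSE], model,
                       bundle$covariates)
  resid <- adjust_fa(bundle$fa[normal_ids, , drop = FALSE], model,
                     bundle$covariates)
  resid <- sweep(resid, 2, model$mu)
  fwhm <- estimate_smoothness(resid, bundle$space)

  if (config$optimize) {
    opt <- optimize_thresholds(ez_pat, ez_ctl, bundle$space, bundle$atlas,
                               fwhm, mode = config$cluster_null,
                               n_fields = config$n_fields,
                               seed = stage_seed(seed, "optimize"))
    u <- opt$u; k <- opt$k
  } else {
    opt <- NULL
    u <- config$u
    k <- if (config$cluster_null == "grf")
      grf_extent_threshold(u, fwhm, n_voxels(bundle$space), config$alpha,
                           bundle$space$voxel_size)
    else as.integer(mc_extent_threshold(
      u, fwhm, bundle$space, config$alpha, n_fields = config$n_fields,
      seed = stage_seed(seed, "catalogue")))
  }

  catalogue <- build_cluster_catalogue(ez_pat, u, k, bundle$space,
                                       bundle$atlas,
                                       config$frequency_fraction,
                                       fwhm = fwhm)

  feats <- cohort_features(bundle, model, catalogue, config$domains,
                           who = "patient")
  if (length(feats) == 0) stop("no predictor domain produced features")
  X_list <- feats
  if (all(c("fa", "cytokine") %in% names(feats)))
    X_list$combined <- combine_domains(feats$fa, feats$cytokine)
  y <- labels[pat_ids]

  models <- lapply(X_list, function(X) {
    rfe <- rfe_select(X, y)
    report <- loocv_classify(X, y, rfe$optimal)
    list(rfe = rfe, loocv = report)
  })
  primary <- if ("fa" %in% names(X_list)) "fa" else names(X_list)[1]
  Xp <- X_list[[primary]]
  rfe_p <- models[[primary]]$rfe

  perm <- permutation_test(Xp, y, subset = rfe_p$optimal,
                           n_perm = config$n_perm,
                           seed = stage_seed(seed, "permute"),
                           mode = config$perm_mode)
  models[[primary]]$loocv$permutation_p <- perm$p

  subsampling <- if (config$subsample_reps > 0)
    subsampling_profile(Xp, y, rfe_p$optimal,
                        reps = config$subsample_reps,
                        seed = stage_seed(seed, "subsample"))
  else NULL

  outc <- bundle$outcomes[match(pat_ids, bundle$outcomes$id), ]
  svr_ips <- svr_predict(Xp, outc$tmta_followup, rfe_p$optimal,
                         seed = stage_seed(seed, "ml"))
  svr_wm <- if (sd(outc$bds_followup) > 0)
    svr_predict(Xp, outc$bds_followup, rfe_p$optimal,
                seed = stage_seed(seed, "ml") + 1L)
  else NULL

  imp <- if (primary == "fa" && length(catalogue) > 0) {
    ctl_feats <- cohort_features(bundle, model, catalogue, "fa",
                                 who = "control")$fa
    allX <- rbind(unclass(Xp)[, colnames(ctl_feats), drop = FALSE],
                  unclass(ctl_feats))
    grp <- c(ifelse(y == -1, "not_recovered", "recovered"),
             rep("control", nrow(ctl_feats)))
    tryCatch(importance_filter(rfe_p, allX, grp), error = function(e) NULL)
  } else NULL

  external <- NULL
  if (!is.null(config$replicate)) {
    rep_bundle <- load_cohort(config$replicate)
    rep_norms <- if (inherits(config$replicate, "simulation_config"))
      config$replicate$norms_table else norms
    rep_pat <- rep_bundle$covariates$id[
      rep_bundle$covariates$group == "patient"]
    y_rep <- label_recovery(
      rep_bundle$outcomes[rep_bundle$outcomes$id %in% rep_pat, ],
      rep_norms)[rep_pat]
    rep_feats <- cohort_features(rep_bundle, model, catalogue,
                                 config$domains, who = "patient")
    rep_X <- rep_feats[[primary]]
    if (all(c("fa", "cytokine") %in% names(rep_feats)))
      rep_feats$combined <- combine_domains(rep_feats$fa,
                                            rep_feats$cytokine)
    external <- lapply(names(X_list), function(nm) {
      frozen <- finalize_model(X_list[[nm]], y, rfe = models[[nm]]$rfe)
      external_validate(frozen, rep_feats[[nm]], y_rep)
    })
    names(external) <- names(X_list)
  }

  structure(list(
    labels = labels, normative = model, fwhm = fwhm,
    thresholds = list(u = u, k = k, alpha = config$alpha,
                      mode = config$cluster_null, optimized = opt),
    catalogue = catalogue, features = X_list, models = models,
    permutation = perm, subsampling = subsampling,
    svr = list(ips = svr_ips, working_memory = svr_wm),
    importance = imp, external = external,
    provenance = list(seed = seed,
                      stage_seeds = vapply(
                        c("split", "normative", "optimize", "catalogue",
                          "ml", "subsample", "permute", "replicate"),
                        function(s) stage_seed(seed, s), numeric(1)),
                      config_hash = config_hash(
                        config[setdiff(names(config),
                                       c("cohort", "replicate"))]))),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  thresholds: |EZ| > %.2f, extent >= %d (%s, alpha = %.2f)\n",
              x$thresholds$u, x$thresholds$k, x$thresholds$mode,
              x$thresholds$alpha))
  cat(sprintf("  catalogue: %d cluster(s); smoothness %.1f mm\n",
              length(x$catalogue), attr(x$fwhm, "mean")))
  for (nm in names(x$models))
    cat(sprintf("  %s: LOOCV accuracy %.1f%% (%d features)\n", nm,
                100 * x$models[[nm]]$loocv$accuracy,
                length(x$models[[nm]]$rfe$optimal)))
  cat(sprintf("  permutation p = %.4g (%s mode)\n", x$permutation$p,
              x$permutation$mode))
  cat(sprintf("  SVR processing speed: rho = %.2f\n", x$svr$ips$rho))
  if (!is.null(x$external))
    for (nm in names(x$external))
      cat(sprintf("  external (%s): accuracy %.1f%%\n", nm,
                  100 * x$external[[nm]]$accuracy))
  invisible(x)
}
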