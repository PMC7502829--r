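#!/usr/bin/env Rscript
# Stage 3 — abnormal-cluster catalogue and lesion-load features.
#
# Determines the cluster-extent threshold on the actual skeleton mask by
# Monte-Carlo simulation (the skeleton is quasi-2D, where analytic 3D GRF
# overcorrects; both are reported), sweeps the ROC threshold grid, builds
# the group-pooled high/low cluster catalogue at |EZ| > 1.96, and cuts the
# per-subject mean-FA cluster features.

suppressPackageStartupMessages(library(faburden))

out <- "results"
cohorts <- readRDS(file.path(out, "cache", "cohorts.rds"))
norm <- readRDS(file.path(out, "cache", "normative.rds"))
b <- cohorts$orig
pat <- b$covariates$id[b$covariates$group == "patient"]

k_mc <- mc_extent_threshold(1.96, norm$fwhm, b$space, alpha = 0.05,
                            n_fields = 1000, seed = 3L)
k_grf <- grf_extent_threshold(1.96, norm$fwhm, length(b$space$idx),
                              alpha = 0.05, voxel_size = b$space$voxel_size)
message(sprintf(
  "extent threshold at u = 1.96, alpha = .05: k = %d voxels (Monte-Carlo) vs %d (3D GRF)",
  as.integer(k_mc), k_grf))

opt <- optimize_thresholds(norm$ez_pat, norm$ez_ctl, b$space, b$atlas,
                           norm$fwhm, mode = "mc", n_fields = 400,
                           seed = 5L)
message(sprintf("ROC sweep: best separation AUC %.2f at u = %.2f, k = %d",
                opt$auc, opt$u, opt$k))

catalogue <- build_cluster_catalogue(norm$ez_pat, 1.96, as.integer(k_mc),
                                     b$space, b$atlas,
                                     frequency_fraction = 0.25,
                                     fwhm = norm$fwhm)
print(catalogue)
write_catalogue(catalogue, file.path(out, "catalogue.json"),
                space = b$space)

fa_adj <- adjust_fa(b$fa[pat, ], norm$model, b$covariates)
features <- extract_features(fa_adj, catalogue)
write.csv(data.frame(id = rownames(features), features,
                     check.names = FALSE),
          file.path(out, "fa_features.csv"), row.names = FALSE)

saveRDS(list(catalogue = catalogue, features = features, k_mc = k_mc,
             k_grf = k_grf, roc = opt),
        file.path(out, "cache", "clusters.rds"))
message("wrote ", file.path(out, "catalogue.json"), " and ",
        file.path(out, "fa_features.csv"))
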