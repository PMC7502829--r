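#!/usr/bin/env Rscript
# Stage 4 — prognostic modelling and internal validation.
#
# Labels recovery against the normative TMT-A cut-offs, runs SVM-RFE on
# the FA cluster features, validates by LOOCV, repeated subsampling
# (n_test = 1..8) and label permutation, predicts the continuous
# processing-speed and working-memory scores by SVR with the same feature
# subset, compares the cytokine-only and combined-domain models, and
# applies the top-weight importance filter.

suppressPackageStartupMessages(library(faburden))

out <- "results"
cohorts <- readRDS(file.path(out, "cache", "cohorts.rds"))
norm <- readRDS(file.path(out, "cache", "normative.rds"))
clus <- readRDS(file.path(out, "cache", "clusters.rds"))
b <- cohorts$orig
pat <- b$covariates$id[b$covariates$group == "patient"]

y <- label_recovery(b$outcomes[b$outcomes$id %in% pat, ],
                    b$config$norms_table)[pat]
X_fa <- clus$features
X_cyt <- cytokine_features(b$cytokines, pat)
X_comb <- combine_domains(X_fa, X_cyt)

fits <- lapply(list(fa = X_fa, cytokine = X_cyt, combined = X_comb),
               function(X) {
                 rfe <- rfe_select(X, y)
                 list(rfe = rfe, loocv = loocv_classify(X, y, rfe$optimal))
               })
for (nm in names(fits))
  message(sprintf("%-9s LOOCV accuracy %.1f%% (%d/%d features)", nm,
                  100 * fits[[nm]]$loocv$accuracy,
                  length(fits[[nm]]$rfe$optimal),
                  length(fits[[nm]]$rfe$elimination_order)))

prof <- subsampling_profile(X_fa, y, fits$fa$rfe$optimal, n_grid = 1:8,
                            reps = 200, seed = 7L)
write.csv(prof, file.path(out, "subsampling_profile.csv"),
          row.names = FALSE)

perm <- permutation_test(X_fa, y, fits$fa$rfe$optimal, n_perm = 5000,
                         seed = 9L, mode = "fast")
message(sprintf("permutation test (%d labels reshuffles, %s mode): p = %.2g",
                perm$n_perm, perm$mode, perm$p))

outc <- b$outcomes[match(pat, b$outcomes$id), ]
svr_ips <- svr_predict(X_fa, outc$tmta_followup, fits$fa$rfe$optimal,
                       seed = 11L)
svr_wm <- svr_predict(X_fa, outc$bds_followup, fits$fa$rfe$optimal,
                      seed = 13L)
print(svr_ips)
print(svr_wm)

ctl_fa <- adjust_fa(b$fa[b$covariates$group == "control", ], norm$model,
                    b$covariates)
ctl_feats <- extract_features(ctl_fa, clus$catalogue)
allX <- rbind(unclass(X_fa), unclass(ctl_feats))
grp <- c(ifelse(y == -1, "not_recovered", "recovered"),
         rep("control", nrow(ctl_feats)))
imp <- importance_filter(fits$fa$rfe, allX, grp)
message(sprintf(
  "importance filter: top %d of %d selected features; %d survive p < %.4f in both group contrasts",
  length(imp$top), length(fits$fa$rfe$optimal), length(imp$kept),
  imp$alpha_adjusted))

report <- list(
  labels = list(n = length(y), nonrecovered_pct = 100 * mean(y == -1)),
  models = lapply(fits, function(f) list(
    accuracy_pct = 100 * f$loocv$accuracy,
    sensitivity_pct = 100 * f$loocv$sensitivity,
    specificity_pct = 100 * f$loocv$specificity,
    n_features = length(f$rfe$optimal),
    weights = as.list(f$rfe$weights))),
  subsampling_ci_pct = list(lower = 100 * min(prof$ci_lower),
                            upper = 100 * max(prof$ci_upper)),
  permutation = list(p = perm$p, mode = perm$mode, n_perm = perm$n_perm),
  svr = list(ips_rho = svr_ips$rho, ips_ci = svr_ips$ci,
             wm_rho = svr_wm$rho, wm_ci = svr_wm$ci),
  importance = list(top = imp$top, kept = imp$kept,
                    alpha_adjusted = imp$alpha_adjusted))
jsonlite::write_json(report, file.path(out, "prognostic_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
saveRDS(list(y = y, fits = fits, X = list(fa = X_fa, cytokine = X_cyt,
                                          combined = X_comb)),
        file.path(out, "cache", "models.rds"))
message("wrote ", file.path(out, "prognostic_report.json"))
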