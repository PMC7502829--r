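#!/usr/bin/env Rscript
# Stage 5 — frozen external validation on the replicate cohort.
#
# Cuts the replicate patients' features with the ORIGINAL cohort's
# normative model and cluster catalogue, then applies the frozen models
# (selected features, weights, standardization, SVM) exactly once.

suppressPackageStartupMessages(library(faburden))

out <- "results"
cohorts <- readRDS(file.path(out, "cache", "cohorts.rds"))
norm <- readRDS(file.path(out, "cache", "normative.rds"))
clus <- readRDS(file.path(out, "cache", "clusters.rds"))
mods <- readRDS(file.path(out, "cache", "models.rds"))
repl <- cohorts$repl

rep_pat <- repl$covariates$id[repl$covariates$group == "patient"]
y_rep <- label_recovery(repl$outcomes[repl$outcomes$id %in% rep_pat, ],
                        repl$config$norms_table)[rep_pat]
rep_fa <- extract_features(
  adjust_fa(repl$fa[rep_pat, ], norm$model, repl$covariates),
  clus$catalogue)
rep_cyt <- cytokine_features(repl$cytokines, rep_pat)
rep_X <- list(fa = rep_fa, cytokine = rep_cyt,
              combined = combine_domains(rep_fa, rep_cyt))

external <- lapply(names(mods$fits), function(nm) {
  frozen <- finalize_model(mods$X[[nm]], mods$y, rfe = mods$fits[[nm]]$rfe)
  rep_ <- external_validate(frozen, rep_X[[nm]], y_rep)
  message(sprintf(
    "external (%s): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%% (n = %d)",
    nm, 100 * rep_$accuracy, 100 * rep_$sensitivity,
    100 * rep_$specificity, length(y_rep)))
  list(domain = nm, accuracy_pct = 100 * rep_$accuracy,
       sensitivity_pct = 100 * rep_$sensitivity,
       specificity_pct = 100 * rep_$specificity,
       confusion = as.list(rep_$confusion))
})

jsonlite::write_json(external, file.path(out, "external_validation.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote ", file.path(out, "external_validation.json"))
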