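# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A tiny handmade space: two parallel slab tracts along x.
tiny_space <- function() {
  fixture("tiny_space", function() {
    mask <- array(FALSE, c(16, 12, 6))
    mask[, 2:4, 2:4] <- TRUE   # tract 1
    mask[, 8:10, 2:4] <- TRUE  # tract 2
    sp <- skeleton_space(mask, voxel_size = 2)
    labels <- integer(length(sp$idx))
    co <- arrayInd(sp$idx, sp$dim)
    labels[co[, 2] <= 4] <- 1L
    labels[co[, 2] >= 8] <- 2L
    list(space = sp,
         atlas = list(labels = labels,
                      table = data.frame(id = 1:2,
                                         name = c("tract_01", "tract_02"))))
  })
}

# A small but complete cohort configuration used by several module tests:
# quarter-scale grid, two lesions (one per direction).
small_config <- function(seed = 1L, ...) {
  simulation_config(
    grid_shape = c(32L, 32L, 16L), n_tracts = 8L,
    skeleton_fraction = 0.12,
    n_controls = 24L, n_patients = 40L,
    lesion_specs = data.frame(tract = 1:2,
                              direction = c("low", "high"),
                              effect = 4, extent = 60L, prevalence = 1),
    # slope rescaled to this config's full-burden scale (2 x 4 x 60)
    outcome_model = list(tmta_intercept = 27, tmta_slope = 0.066,
                         tmta_noise_sd = 5, bds_intercept = 5.0,
                         bds_slope = -0.0032, bds_noise_sd = 1.2),
    smoothing_fwhm = 5,
    seed = seed, ...)
}

small_cohort <- function() {
  fixture("small_cohort", function() generate_cohort(small_config(seed = 42L)))
}

# Monte-Carlo extent threshold for the small-cohort skeleton, computed once.
small_k <- function() {
  fixture("small_k", function() {
    b <- small_cohort()
    as.integer(mc_extent_threshold(1.96, 5, b$space, alpha = 0.05,
                                   n_fields = 300, seed = 7))
  })
}

# Extent threshold for the default-scale skeleton (shared by acceptance
# tests), computed once from one default cohort's geometry.
default_k <- function() {
  fixture("default_k", function() {
    b <- generate_cohort(simulation_config(seed = 1L))
    as.integer(mc_extent_threshold(1.96, 6, b$space, alpha = 0.05,
                                   n_fields = 300, seed = 7))
  })
}

# Run the imaging half of the pipeline on a bundle with a fixed (u, k):
# normative model, patient EZ, catalogue, features, labels.
imaging_stage <- function(bundle, k, u = 1.96, B = 60L, seed = 5L,
                          frequency_fraction = 0.25) {
  ctl <- bundle$covariates$id[bundle$covariates$group == "control"]
  pat <- bundle$covariates$id[bundle$covariates$group == "patient"]
  model <- build_normative_model(bundle$fa[ctl, , drop = FALSE],
                                 bundle$covariates, B = B, seed = seed)
  ez_pat <- compute_ez(bundle$fa[pat, , drop = FALSE], model,
                       bundle$covariates)
  catalogue <- build_cluster_catalogue(ez_pat, u, k, bundle$space,
                                       bundle$atlas, frequency_fraction)
  features <- if (length(catalogue) > 0)
    extract_features(adjust_fa(bundle$fa[pat, , drop = FALSE], model,
                               bundle$covariates), catalogue)
  else NULL
  labels <- label_recovery(
    bundle$outcomes[bundle$outcomes$id %in% pat, ],
    bundle$config$norms_table)[pat]
  list(model = model, ez_pat = ez_pat, catalogue = catalogue,
       features = features, labels = labels, patients = pat,
       controls = ctl)
}

# Default-scale cohort + imaging stage, memoized (used by the acceptance
# and prognostic tests).
default_run <- function() {
  fixture("default_run", function() {
    bundle <- generate_cohort(simulation_config(seed = 1L))
    stage <- imaging_stage(bundle, default_k(), B = 150L, seed = 11L)
    c(list(bundle = bundle), stage)
  })
}
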