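#' Configuration for the synthetic mTBI cohort generator
#'
#' Defines the study conditions the simulated cohorts follow: a common-space
#' skeleton grid partitioned into labelled tracts, healthy-control FA with
#' linear age/sex/education effects plus spatially smooth Gaussian noise,
#' patients additionally carrying contiguous clusters of raised or lowered
#' FA in named tracts, acutely elevated serum cytokines, and follow-up
#' cognitive scores (TMT-A seconds, backward digit span) driven by total
#' lesion burden. Defaults mirror a 40-control / 60-patient single-centre
#' cohort in which one third of patients fail to recover normal processing
#' speed.
#'
#' @param grid_shape integer length-3 grid dimensions (voxels).
#' @param voxel_size voxel edge length in mm.
#' @param skeleton_fraction proportion of grid voxels on the skeleton.
#' @param n_tracts number of labelled tracts partitioning the skeleton.
#' @param n_controls,n_patients cohort sizes.
#' @param covariate_effects named numeric: FA change per year of age, per
#'   sex unit (coded 0/1) and per year of education.
#' @param noise_sd marginal SD of the spatially smooth FA noise (FA units).
#' @param smoothing_fwhm FWHM of the noise smoothing kernel, mm.
#' @param lesion_specs data.frame with columns `tract` (atlas id),
#'   `direction` ("high"/"low"), `effect` (shift in units of `noise_sd`),
#'   `extent` (voxels) and `prevalence` (probability that a non-recovered
#'   patient carries the lesion).
#' @param cytokine_shift named numeric mean elevation of IL-1beta, IL-6 and
#'   CCL2 in patients (pg/mL).
#' @param nonrecovered_fraction fraction of patients assigned high lesion
#'   burden (the non-recovering stratum); the count is fixed at
#'   `round(fraction * n_patients)`.
#' @param severity_low,severity_high uniform ranges of the per-patient
#'   injury-severity grade in the low-burden and high-burden strata.
#'   Severity scales every carried lesion, so injury is graded across the
#'   whole cohort rather than all-or-none.
#' @param lesion_jitter uniform range of the independent per-(subject,
#'   lesion) multiplier (tract-to-tract heterogeneity).
#' @param outcome_model list of coefficients linking burden (effect-SD x
#'   voxels) to follow-up TMT-A and BDS plus Gaussian noise SDs.
#' @param norms_table TMT-A normative cut-offs per (age band, education
#'   band); see [default_norms()].
#' @param seed integer seed; the same config generates byte-identical
#'   cohorts.
#' @param site_seed seed for growing the lesion sites. Deliberately
#'   decoupled from `seed` and constant by default: the strategic lesion
#'   locations are a property of the injury model, so independently drawn
#'   cohorts (original vs replicate) share sites while everything
#'   subject-level varies.
#' @param cohort cohort tag, `"original"` or `"replicate"`.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(grid_shape = c(48L, 48L, 24L),
                              voxel_size = 2,
                              skeleton_fraction = 0.10,
                              n_tracts = 12L,
                              n_controls = 40L,
                              n_patients = 60L,
                              covariate_effects = c(age = -8e-4, sex = 1e-2,
                                                    education = 5e-4),
                              noise_sd = 0.04,
                              smoothing_fwhm = 6,
                              lesion_specs = default_lesion_specs(),
                              cytokine_shift = c(IL1b = 0.4, IL6 = 0.4,
                                                 CCL2 = 47),
                              nonrecovered_fraction = 0.33,
                              severity_low = c(0, 0.35),
                              severity_high = c(0.8, 1.3),
                              lesion_jitter = c(0.9, 1.1),
                              outcome_model = default_outcome_model(),
                              norms_table = default_norms(),
                              seed = 1L,
                              site_seed = 101L,
                              cohort = c("original", "replicate")) {
  cohort <- match.arg(cohort)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  stopifnot(all(grid_shape > 0), n_tracts > 0, n_controls > 0,
            n_patients > 0)
  if (skeleton_fraction <= 0 || skeleton_fraction >= 1)
    stop("skeleton_fraction must lie in (0, 1)")
  if (smoothing_fwhm < voxel_size)
    stop("smoothing_fwhm must be at least one voxel size")
  stopifnot(noise_sd > 0,
            all(c("age", "sex", "education") %in% names(covariate_effects)))
  if (nrow(lesion_specs) > 0) {
    stopifnot(all(c("tract", "direction", "effect", "extent",
                    "prevalence") %in% names(lesion_specs)),
              all(lesion_specs$direction %in% c("high", "low")),
              all(lesion_specs$extent >= 1))
    if (any(lesion_specs$prevalence < 0 | lesion_specs$prevalence > 1))
      stop("lesion prevalence must lie in [0, 1]")
  }
  if (nonrecovered_fraction < 0 || nonrecovered_fraction > 1)
    stop("nonrecovered_fraction must lie in [0, 1]")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 skeleton_fraction = skeleton_fraction,
                 n_tracts = as.integer(n_tracts),
                 n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
                 lesion_specs = lesion_specs,
                 cytokine_shift = cytokine_shift,
                 nonrecovered_fraction = nonrecovered_fraction,
                 severity_low = severity_low, severity_high = severity_high,
                 lesion_jitter = lesion_jitter,
                 outcome_model = outcome_model,
                 norms_table = norms_table,
                 seed = as.integer(seed),
                 site_seed = as.integer(site_seed), cohort = cohort),
            class = "simulation_config")
}

#' Default lesion specification: bidirectional injury in four tracts
#'
#' Four tracts carry one lesion each, two with abnormally low and two with
#' abnormally high FA, at 3.5-4 reference-SD effect and 90-voxel extent
#' (comfortably above twice the default cluster-extent threshold on the
#' default skeleton). Every patient carries every lesion, scaled by the
#' per-subject severity grade, so realized effects in the non-recovering
#' stratum stay at or above ~3 SD.
#' @return data.frame of lesion specifications.
#' @export
default_lesion_specs <- function() {
  data.frame(tract = 1:4,
             direction = c("low", "high", "low", "high"),
             effect = c(4.0, 4.0, 3.5, 3.5),
             extent = 90L,
             prevalence = 1.0)
}

#' Default outcome model linking lesion burden to follow-up scores
#'
#' Burden is measured in effect-SD x voxels. The defaults place recovered
#' patients near healthy TMT-A performance (~27 s) and carry full-burden
#' patients ~35 s slower, with 5 s residual noise; backward digit span
#' declines so that the patient-group mean sits ~1.3 points below
#' controls, the magnitude reported for acute mTBI cohorts.
#' @return list of coefficients.
#' @export
default_outcome_model <- function() {
  list(tmta_intercept = 27, tmta_slope = 0.027, tmta_noise_sd = 5,
       bds_intercept = 5.0, bds_slope = -0.002, bds_noise_sd = 1.2)
}

#' Synthetic TMT-A normative cut-offs by age and education band
#'
#' The published norms used to define recovery are cited but not printed in
#' any source shipped with this package, so a small synthetic table with the
#' expected structure (slower cut-offs with age, faster with education) is
#' provided as an editable CSV fixture.
#' @return data.frame with columns `age_min`, `age_max`, `edu_min`,
#'   `edu_max`, `tmta_cutoff` (seconds).
#' @export
default_norms <- function() {
  path <- system.file("extdata", "tmta_norms_synthetic.csv",
                      package = "faburden")
  if (!nzchar(path)) stop("norms fixture not found")
  read.csv(path)
}

# Deterministic tract geometry: parallel slabs along x, placed on a lattice
# in the (y, z) plane, cross-section sized to hit skeleton_fraction.
build_atlas <- function(config) {
  d <- config$grid_shape
  target <- config$skeleton_fraction * prod(d)
  side <- max(1L, as.integer(round(sqrt(target / (config$n_tracts * d[1])))))
  gap <- 2L
  n_cols <- max(1L, (d[2] - 1L) %/% (side + gap))
  labels <- array(0L, dim = d)
  for (t in seq_len(config$n_tracts)) {
    cy <- (t - 1L) %% n_cols
    cz <- (t - 1L) %/% n_cols
    y0 <- 2L + cy * (side + gap)
    z0 <- 2L + cz * (side + gap)
    if (y0 + side - 1L > d[2] || z0 + side - 1L > d[3])
      stop("grid too small for ", config$n_tracts, " tracts; ",
           "increase grid_shape or reduce n_tracts")
    labels[, y0:(y0 + side - 1L), z0:(z0 + side - 1L)] <- t
  }
  space <- skeleton_space(labels > 0L, config$voxel_size)
  list(space = space,
       labels = labels[space$idx],
       table = data.frame(id = seq_len(config$n_tracts),
                          name = sprintf("tract_%02d",
                                         seq_len(config$n_tracts))))
}

# Variance-preserving scale for smoothed white noise: the per-axis kernel
# shrinks variance by sum(w^2)/sum(w)^2 (interior voxels).
smoothing_var_factor <- function(fwhm, voxel_size) {
  sigma <- rep_len(fwhm / voxel_size, 3L) / sqrt(8 * log(2))
  prod(vapply(sigma, function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(3.5 * s))
    w <- exp(-0.5 * (-r:r)^2 / s^2)
    sum(w^2) / sum(w)^2
  }, numeric(1)))
}

noise_field <- function(space, config, scale) {
  arr <- array(rnorm(prod(space$dim)), dim = space$dim)
  sm <- smooth_field(arr, config$smoothing_fwhm, config$voxel_size)
  sm[space$idx] * scale
}

# Grow a contiguous lesion site of `extent` voxels inside one tract by
# breadth-first search (26-connectivity) from a random on-tract seed.
grow_lesion_site <- function(space, tract_idx, extent) {
  if (length(tract_idx) < extent)
    stop("lesion extent (", extent, ") exceeds tract skeleton size (",
         length(tract_idx), ")")
  on_tract <- logical(prod(space$dim))
  on_tract[tract_idx] <- TRUE
  d <- space$dim
  seed_vox <- tract_idx[sample.int(length(tract_idx), 1L)]
  visited <- integer(0)
  frontier <- seed_vox
  in_site <- logical(prod(space$dim))
  in_site[seed_vox] <- TRUE
  while (length(visited) < extent && length(frontier) > 0) {
    take <- min(extent - length(visited), length(frontier))
    visited <- c(visited, frontier[seq_len(take)])
    if (length(visited) >= extent) break
    nxt <- integer(0)
    for (v in frontier) {
      co <- arrayInd(v, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        x <- co[1] + dx; y <- co[2] + dy; z <- co[3] + dz
        if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3]) next
        w <- x + (y - 1L) * d[1] + (z - 1L) * d[1] * d[2]
        if (on_tract[w] && !in_site[w]) {
          in_site[w] <- TRUE
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  if (length(visited) < extent)
    stop("could not grow a contiguous lesion of ", extent,
         " voxels inside the tract")
  sort(visited)
}

#' Generate a synthetic cohort of skeletonized FA maps
#'
#' Simulates healthy controls and mTBI patients on a common skeleton:
#' control FA is a smooth baseline plus linear covariate effects plus
#' spatially smooth Gaussian noise; a fixed stratum of patients
#' (`nonrecovered_fraction`) additionally carries the configured lesions
#' (contiguous FA shifts at a cohort-level site per lesion, scaled by a
#' per-subject severity multiplier), elevated serum cytokines, and
#' follow-up cognitive scores generated from total lesion burden. The
#' injected truth (sites, per-subject burden, stratum) is returned for
#' recovery testing only and is never consumed by the analysis modules.
#'
#' @param config a [simulation_config()].
#' @return A `cohort_bundle`: FA matrix (subjects x skeleton voxels),
#'   skeleton space, atlas, covariates, cytokines, outcomes, group labels
#'   and truth.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  atlas <- build_atlas(config)
  space <- atlas$space
  if (nrow(config$lesion_specs) > 0) {
    missing_tracts <- setdiff(config$lesion_specs$tract, atlas$table$id)
    if (length(missing_tracts) > 0)
      stop("lesion tract id(s) absent from atlas: ",
           paste(missing_tracts, collapse = ", "))
  }
  # lesion sites are part of the injury model, not the cohort draw:
  # grown under site_seed so independent cohorts share locations
  sites <- lapply(seq_len(nrow(config$lesion_specs)), function(l) {
    with_seed(config$site_seed + l, {
      tract_idx <- space$idx[atlas$labels == config$lesion_specs$tract[l]]
      grow_lesion_site(space, tract_idx, config$lesion_specs$extent[l])
    })
  })
  with_seed(config$seed, {
    nC <- config$n_controls; nP <- config$n_patients
    n <- nC + nP
    ids <- c(sprintf("ctrl_%03d", seq_len(nC)),
             sprintf("pat_%03d", seq_len(nP)))
    group <- rep(c("control", "patient"), c(nC, nP))

    age <- round(pmin(70, pmax(18, rnorm(n, 36, 13))))
    sex <- rbinom(n, 1L, 0.5)
    education <- round(pmin(19, pmax(0, rnorm(n, 9, 4))))

    # baseline FA surface: smooth deterministic variation around 0.5
    co <- arrayInd(space$idx, space$dim)
    baseline <- 0.5 + 0.05 * sin(2 * pi * co[, 1] / space$dim[1]) *
      cos(2 * pi * co[, 2] / space$dim[2])

    eff <- config$covariate_effects
    cov_term <- eff[["age"]] * (age - 36) + eff[["sex"]] * sex +
      eff[["education"]] * (education - 9)

    scale <- config$noise_sd /
      sqrt(smoothing_var_factor(config$smoothing_fwhm, config$voxel_size))
    fa <- matrix(0, n, n_voxels(space), dimnames = list(ids, NULL))
    for (i in seq_len(n))
      fa[i, ] <- baseline + cov_term[i] + noise_field(space, config, scale)

    # graded injury: a fixed-count high-burden stratum (the non-recovering
    # third) on top of mild injury in the remainder; severity scales every
    # carried lesion, with independent per-lesion jitter
    n_nonrec <- round(config$nonrecovered_fraction * nP)
    severity <- integer(nP)
    severity[sample.int(nP, n_nonrec)] <- 1L
    grade <- ifelse(severity == 1L,
                    runif(nP, config$severity_high[1],
                          config$severity_high[2]),
                    runif(nP, config$severity_low[1],
                          config$severity_low[2]))

    specs <- config$lesion_specs
    carried <- matrix(FALSE, nP, max(1L, nrow(specs)))
    burden <- numeric(nP)
    if (nrow(specs) > 0) {
      for (l in seq_len(nrow(specs))) {
        carried[, l] <- runif(nP) < specs$prevalence[l]
        jitter <- runif(nP, config$lesion_jitter[1],
                        config$lesion_jitter[2])
        sgn <- if (specs$direction[l] == "high") 1 else -1
        vox <- match(sites[[l]], space$idx)
        for (p in which(carried[, l])) {
          amp <- specs$effect[l] * grade[p] * jitter[p]
          fa[nC + p, vox] <- fa[nC + p, vox] + sgn * amp * config$noise_sd
          burden[p] <- burden[p] + amp * specs$extent[l]
        }
      }
    }
    fa[] <- pmin(1, pmax(0, fa))

    # serum cytokines: elevated in patients in proportion to injury grade
    shift <- config$cytokine_shift
    sev_w <- c(rep(0, nC), 0.5 + 0.7 * grade)
    cytokines <- data.frame(
      id = ids,
      IL1b = pmax(0.1, rnorm(n, 2.2, 0.9) + sev_w * shift[["IL1b"]]),
      IL6 = pmax(0.1, rnorm(n, 0.9, 0.4) + sev_w * shift[["IL6"]]),
      CCL2 = pmax(10, rnorm(n, 212, 60) + sev_w * shift[["CCL2"]]))

    om <- config$outcome_model
    full_burden <- c(rep(0, nC), burden)
    tmta_fu <- ifelse(group == "control",
                      rnorm(n, om$tmta_intercept, 4),
                      om$tmta_intercept + om$tmta_slope * full_burden +
                        rnorm(n, 0, om$tmta_noise_sd))
    tmta_fu <- pmax(10, tmta_fu)
    tmta_base <- ifelse(group == "control",
                        0.7 * tmta_fu + 0.3 * om$tmta_intercept +
                          rnorm(n, 0, 4),
                        tmta_fu + abs(rnorm(n, 8, 8)))
    tmta_base <- pmax(10, tmta_base)
    bds_fu <- ifelse(group == "control",
                     rnorm(n, om$bds_intercept, 1.5),
                     om$bds_intercept + om$bds_slope * full_burden +
                       rnorm(n, 0, om$bds_noise_sd))
    bds_fu <- round(pmin(14, pmax(0, bds_fu)))
    bds_base <- round(pmin(14, pmax(0, bds_fu + rnorm(n, -0.3, 1))))
    outcomes <- data.frame(id = ids, age = age, education = education,
                           tmta_baseline = round(tmta_base, 1),
                           tmta_followup = round(tmta_fu, 1),
                           bds_baseline = bds_base, bds_followup = bds_fu)

    structure(list(
      fa = fa, space = space,
      atlas = list(labels = atlas$labels, table = atlas$table),
      covariates = data.frame(id = ids, age = age, sex = sex,
                              education = education, group = group,
                              cohort = config$cohort),
      cytokines = cytokines,
      outcomes = outcomes,
      truth = list(sites = sites, specs = specs,
                   burden = stats::setNames(burden, ids[group == "patient"]),
                   severity = stats::setNames(severity,
                                              ids[group == "patient"]),
                   grade = stats::setNames(grade, ids[group == "patient"]),
                   carried = carried),
      config = config), class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %s: %d controls + %d patients, %d skeleton voxels, %d tracts\n",
    x$config$cohort, sum(x$covariates$group == "control"),
    sum(x$covariates$group == "patient"), n_voxels(x$space),
    nrow(x$atlas$table)))
  invisible(x)
}

#' Label recovery from follow-up processing speed against normative cut-offs
#'
#' A subject is labelled improved (+1) iff their follow-up TMT-A time is
#' less than or equal to the cut-off for their (age, education) band;
#' otherwise not recovered (-1). The cut-off is inclusive by convention.
#'
#' @param outcomes data.frame with columns `id`, `age`, `education`,
#'   `tmta_followup`.
#' @param norms_table data.frame of cut-offs as in [default_norms()].
#' @return Named integer vector of +1 / -1 labels, one per subject.
#' @export
label_recovery <- function(outcomes, norms_table = default_norms()) {
  stopifnot(all(c("id", "age", "education", "tmta_followup")
                %in% names(outcomes)))
  labels <- vapply(seq_len(nrow(outcomes)), function(i) {
    band <- norms_table$age_min <= outcomes$age[i] &
      outcomes$age[i] <= norms_table$age_max &
      norms_table$edu_min <= outcomes$education[i] &
      outcomes$education[i] <= norms_table$edu_max
    if (!any(band))
      stop("subject ", outcomes$id[i], " (age ", outcomes$age[i],
           ", education ", outcomes$education[i],
           ") falls outside all norm bands")
    cutoff <- norms_table$tmta_cutoff[which(band)[1]]
    if (outcomes$tmta_followup[i] <= cutoff) 1L else -1L
  }, integer(1))
  stats::setNames(labels, outcomes$id)
}
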