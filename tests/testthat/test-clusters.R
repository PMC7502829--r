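ez_with_blob <- function(space, positions, value = 3) {
  ez <- numeric(length(space$idx))
  ez[positions] <- value
  ez
}

# positions (skeleton order) of a contiguous run of `len` x-steps in a
# tract, starting at a corner of its slab
blob_positions <- function(sp, atlas, tract, len, width = 3) {
  pos <- which(atlas$labels == tract)
  co <- arrayInd(sp$idx[pos], sp$dim)
  sel <- co[, 1] <= len & co[, 2] <= min(co[, 2]) + width - 1 &
    co[, 3] <= min(co[, 3]) + width - 1
  pos[sel]
}

test_that("cluster detection respects threshold, tract and direction", {
  ts <- tiny_space()
  sp <- ts$space; atlas <- ts$atlas

  expect_length(detect_clusters(numeric(length(sp$idx)), 1.96, 5, sp,
                                atlas, "high"), 0)

  blob <- blob_positions(sp, atlas, 1, len = 6)
  cl <- detect_clusters(ez_with_blob(sp, blob, 3), 1.96, 20, sp, atlas,
                        "high")
  expect_length(cl, 1)
  expect_equal(cl[[1]]$tract, 1)
  expect_equal(cl[[1]]$direction, "high")
  expect_equal(cl[[1]]$extent, length(blob))
  expect_setequal(cl[[1]]$skeleton_pos, blob)

  # same blob with negative EZ is a "low" cluster only
  expect_length(detect_clusters(ez_with_blob(sp, blob, -3), 1.96, 20, sp,
                                atlas, "high"), 0)
  cl_low <- detect_clusters(ez_with_blob(sp, blob, -3), 1.96, 20, sp,
                            atlas, "low")
  expect_length(cl_low, 1)
  expect_equal(cl_low[[1]]$direction, "low")

  expect_error(detect_clusters(numeric(10), 1.96, 5, sp, atlas, "high"),
               "voxel counts")
})

test_that("tract masking splits a blob straddling two adjacent tracts", {
  mask <- array(FALSE, c(10, 6, 4))
  mask[, 2:5, 2:3] <- TRUE
  sp <- skeleton_space(mask, voxel_size = 2)
  co <- arrayInd(sp$idx, sp$dim)
  labels <- ifelse(co[, 2] <= 3, 1L, 2L)
  atlas <- list(labels = labels,
                table = data.frame(id = 1:2, name = c("t1", "t2")))
  # contiguous blob of 2 x-slices spanning both tracts: 2*4*2 = 16 voxels,
  # but each tract-side part is 8 < k = 10
  blob <- which(co[, 1] <= 2)
  whole <- detect_clusters(ez_with_blob(sp, blob, 3), 1.96, 16, sp,
                           list(labels = rep(1L, length(sp$idx)),
                                table = data.frame(id = 1, name = "all")),
                           "high")
  expect_length(whole, 1)  # without tract masking it is one 16-voxel blob
  split <- detect_clusters(ez_with_blob(sp, blob, 3), 1.96, 10, sp, atlas,
                           "high")
  expect_length(split, 0)
})

test_that("no voxel falls into two same-direction clusters", {
  ts <- tiny_space()
  set.seed(3)
  ez <- rnorm(length(ts$space$idx)) * 2
  for (dir in c("high", "low")) {
    cl <- detect_clusters(ez, 1.5, 1, ts$space, ts$atlas, dir)
    pos <- unlist(lapply(cl, `[[`, "skeleton_pos"))
    expect_false(any(duplicated(pos)))
  }
})

test_that("threshold optimization maximizes patient-control separation", {
  ts <- tiny_space(); sp <- ts$space; atlas <- ts$atlas
  sizes_p <- c(10, 8, 7); sizes_c <- c(1, 2, 3)
  mk <- function(n) ez_with_blob(sp, blob_positions(sp, atlas, 1, len = 10)[seq_len(n)], 3)
  ezp <- do.call(rbind, lapply(sizes_p, mk))
  ezc <- do.call(rbind, lapply(sizes_c, mk))
  opt <- optimize_thresholds(ezp, ezc, sp, atlas, fwhm = 2,
                             u_grid = c(1.0, 1.96), alpha_grid = 0.9,
                             mode = "grf")
  expect_equal(opt$auc, 1.0)
  expect_equal(opt$u, 1.96)  # ties broken toward larger u
  expect_equal(opt$k, 1L)

  # brute-force oracle over all patient-control pairs
  loads_p <- vapply(seq_len(3), function(i)
    faburden:::lesion_load(ezp[i, ], opt$u, opt$k, sp, atlas), numeric(1))
  loads_c <- vapply(seq_len(3), function(i)
    faburden:::lesion_load(ezc[i, ], opt$u, opt$k, sp, atlas), numeric(1))
  pairs <- outer(loads_p, loads_c, ">") + 0.5 * outer(loads_p, loads_c, "==")
  expect_equal(opt$auc, mean(pairs))
  expect_equal(loads_p, sizes_p)
})

test_that("optimization on statistically identical groups hovers at chance", {
  ts <- tiny_space(); sp <- ts$space; atlas <- ts$atlas
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    ezp <- matrix(rnorm(20 * length(sp$idx)), 20)
    ezc <- matrix(rnorm(20 * length(sp$idx)), 20)
    optimize_thresholds(ezp, ezc, sp, atlas, fwhm = 2, u_grid = 1.64,
                        alpha_grid = 0.9, mode = "grf")$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("group catalogue follows the abnormality-frequency pooling rule", {
  ts <- tiny_space(); sp <- ts$space; atlas <- ts$atlas
  blob <- blob_positions(sp, atlas, 2, len = 5)
  one <- ez_with_blob(sp, blob, 3)

  # single patient at fraction 1: catalogue equals that patient's clusters
  cat1 <- build_cluster_catalogue(matrix(one, 1), 1.96, 10, sp, atlas, 1)
  direct <- detect_clusters(one, 1.96, 10, sp, atlas, "high")
  expect_length(cat1, length(direct))
  expect_setequal(cat1$clusters[[1]]$skeleton_pos, direct[[1]]$skeleton_pos)

  # a site abnormal in 60% of patients passes pooling at 0.5, not at 0.7
  ezm <- rbind(do.call(rbind, replicate(6, one, simplify = FALSE)),
               matrix(0, 4, length(sp$idx)))
  expect_length(build_cluster_catalogue(ezm, 1.96, 10, sp, atlas, 0.5), 1)
  expect_warning(
    empty <- build_cluster_catalogue(ezm, 1.96, 10, sp, atlas, 0.7),
    "empty")
  expect_length(empty, 0)

  expect_warning(
    none <- build_cluster_catalogue(matrix(0, 3, length(sp$idx)), 1.96,
                                    10, sp, atlas, 0.25),
    "empty")
  expect_length(none, 0)
  expect_error(build_cluster_catalogue(ezm, 1.96, 10, sp, atlas, 0),
               "frequency_fraction")

  # determinism: identical inputs give identical catalogues
  expect_identical(build_cluster_catalogue(ezm, 1.96, 10, sp, atlas, 0.5),
                   build_cluster_catalogue(ezm, 1.96, 10, sp, atlas, 0.5))
})

test_that("features are cluster means in a deterministic column order", {
  ts <- tiny_space(); sp <- ts$space
  cat_ <- structure(list(clusters = list(
    list(id = "t1_low_01", tract = 1, tract_name = "t1",
         direction = "low", voxels = sp$idx[1:2], skeleton_pos = 1:2,
         extent = 2L),
    list(id = "t2_high_01", tract = 2, tract_name = "t2",
         direction = "high", voxels = sp$idx[5:7], skeleton_pos = 5:7,
         extent = 3L)),
    provenance = list(u = 1.96, k = 2)), class = "cluster_catalogue")
  fa <- matrix(0.5, 2, length(sp$idx), dimnames = list(c("a", "b"), NULL))
  fa[, 1] <- 0.3; fa[, 2] <- 0.5
  X <- extract_features(fa, cat_)
  expect_equal(unname(X[, "t1_low_01"]), c(0.4, 0.4))
  expect_identical(X["a", ], X["b", ])  # identical subjects, identical rows
  expect_equal(colnames(X), c("t1_low_01", "t2_high_01"))
  expect_equal(feature_info(X)$domain, c("fa", "fa"))
})

test_that("low-FA lesion clusters read lower in affected patients", {
  hits <- vapply(1:50, function(s) {
    cfg <- simulation_config(
      grid_shape = c(16, 16, 8), n_tracts = 2, skeleton_fraction = 0.15,
      n_controls = 8, n_patients = 8,
      lesion_specs = data.frame(tract = 1, direction = "low", effect = 4,
                                extent = 20, prevalence = 1),
      smoothing_fwhm = 4, seed = 300 + s)
    b <- generate_cohort(cfg)
    pos <- match(b$truth$sites[[1]], b$space$idx)
    grp <- b$covariates$group
    affected <- names(b$truth$severity)[b$truth$severity == 1]
    mean(b$fa[affected, pos]) < mean(b$fa[grp == "control", pos])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (i in 1:5) {
    p <- round(rexp(15, 1 / 40))  # tied, skewed lesion loads
    c_ <- round(rexp(20, 1 / 15))
    ours <- faburden:::pairwise_auc(p, c_)
    ref <- as.numeric(pROC::auc(
      response = c(rep(1, 15), rep(0, 20)), predictor = c(p, c_),
      direction = "<", quiet = TRUE))
    expect_equal(ours, ref)
  }
})
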