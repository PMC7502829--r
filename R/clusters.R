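
as_ez_vector <- function(ez) {
  if (inherits(ez, "skeleton_image")) ez$values else as.numeric(ez)
}

#' Detect abnormal clusters in one EZ map
#'
#' Voxels exceeding the threshold in the requested direction (EZ > u for
#' "high", EZ < -u for "low"; strict inequality, boundary excluded) are
#' intersected with each atlas tract, connected components are computed
#' within each tract separately under 26-connectivity, and components
#' smaller than the extent threshold `k` are discarded.
#'
#' @param ez EZ values over the skeleton (vector or `skeleton_image`).
#' @param u voxelwise z threshold.
#' @param k minimum cluster extent (voxels).
#' @param space the [skeleton_space()].
#' @param atlas list with `labels` (tract id per skeleton voxel) and
#'   `table` (id, name).
#' @param direction `"high"` or `"low"`.
#' @return List of clusters; each has `id`, `tract`, `tract_name`,
#'   `direction`, `voxels` (grid linear indices), `skeleton_pos`
#'   (positions in `space$idx`), `extent`.
#' @export
detect_clusters <- function(ez, u, k, space, atlas,
                            direction = c("high", "low")) {
  direction <- match.arg(direction)
  ez <- as_ez_vector(ez)
  if (length(ez) != n_voxels(space))
    stop("EZ map and skeleton space have different voxel counts")
  if (length(atlas$labels) != n_voxels(space))
    stop("atlas and skeleton space have different voxel counts")
  supra <- if (direction == "high") ez > u else ez < -u
  cluster_mask(supra, k, space, atlas, direction)
}

# Shared component search over a logical skeleton-ordered mask.
cluster_mask <- function(supra, k, space, atlas, direction) {
  clusters <- list()
  for (t in atlas$table$id) {
    sel <- supra & atlas$labels == t
    if (!any(sel)) next
    arr <- array(FALSE, dim = space$dim)
    arr[space$idx[sel]] <- TRUE
    lab <- label_components(arr)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= k)
    tname <- atlas$table$name[match(t, atlas$table$id)]
    for (j in seq_along(keep)) {
      vox <- which(lab == keep[j])
      clusters[[length(clusters) + 1L]] <- list(
        id = sprintf("%s_%s_%02d", tname, direction, j),
        tract = t, tract_name = tname, direction = direction,
        voxels = vox, skeleton_pos = match(vox, space$idx),
        extent = length(vox))
    }
  }
  clusters
}

# Total abnormal-voxel count (lesion load) of one subject at (u, k):
# suprathreshold voxels surviving tract-wise extent thresholding, summed
# over both directions.
lesion_load <- function(ez, u, k, space, atlas) {
  cl <- c(detect_clusters(ez, u, k, space, atlas, "high"),
          detect_clusters(ez, u, k, space, atlas, "low"))
  sum(vapply(cl, function(x) x$extent, integer(1)))
}

# Rank-based AUC of group separation (probability a patient load exceeds a
# control load; ties count 1/2). NA when all values are identical.
pairwise_auc <- function(patients, controls) {
  if (length(unique(c(patients, controls))) == 1L) return(NA_real_)
  r <- rank(c(patients, controls))
  n1 <- length(patients); n2 <- length(controls)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC optimization of the voxel and extent thresholds
#'
#' For every candidate (u, alpha) pair, computes the extent threshold k in
#' the requested null mode, the per-subject total abnormal-voxel count
#' (lesion load) for patients and held-out normal controls, and the AUC of
#' patient-vs-control separation; returns the pair with maximal AUC (ties
#' broken toward larger u, then larger k).
#'
#' @param ez_patients,ez_controls EZ matrices (subjects x voxels).
#' @param space,atlas skeleton space and tract atlas.
#' @param fwhm estimated smoothness in mm (per axis or scalar).
#' @param u_grid candidate voxel thresholds.
#' @param alpha_grid candidate family-wise alpha levels.
#' @param mode `"grf"` (analytic) or `"mc"` (Monte-Carlo on the skeleton).
#' @param n_fields,seed Monte-Carlo settings (mode `"mc"`).
#' @return list with `u`, `alpha`, `k`, `auc` and the full `grid` of
#'   candidates.
#' @export
optimize_thresholds <- function(ez_patients, ez_controls, space, atlas,
                                fwhm, u_grid = c(1.64, 1.96, 2.33, 2.58),
                                alpha_grid = c(0.01, 0.05),
                                mode = c("grf", "mc"),
                                n_fields = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(nrow(ez_patients) > 0, nrow(ez_controls) > 0,
            length(u_grid) > 0, length(alpha_grid) > 0)
  grid <- expand.grid(u = sort(u_grid), alpha = sort(alpha_grid))
  grid$k <- NA_integer_; grid$auc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    k <- if (mode == "grf")
      grf_extent_threshold(grid$u[i], fwhm, n_voxels(space),
                           grid$alpha[i], space$voxel_size)
    else
      as.integer(mc_extent_threshold(grid$u[i], fwhm, space, grid$alpha[i],
                                     n_fields = n_fields, seed = seed))
    grid$k[i] <- k
    lp <- apply(ez_patients, 1, lesion_load, u = grid$u[i], k = k,
                space = space, atlas = atlas)
    lc <- apply(ez_controls, 1, lesion_load, u = grid$u[i], k = k,
                space = space, atlas = atlas)
    grid$auc[i] <- pairwise_auc(lp, lc)
  }
  if (all(is.na(grid$auc)))
    stop("AUC undefined for every candidate: lesion loads are constant ",
         "and identical across groups")
  best <- order(-grid$auc, -grid$u, -grid$k)[1]
  list(u = grid$u[best], alpha = grid$alpha[best], k = grid$k[best],
       auc = grid$auc[best], grid = grid, mode = mode)
}

#' Build the fixed group-level cluster catalogue
#'
#' Per direction, a voxel enters the group abnormality mask when it is
#' suprathreshold (|EZ| > u in that direction) in at least
#' `frequency_fraction` of patients; cluster detection (tract masking,
#' 26-connectivity, extent >= k) is then run on that mask. The resulting
#' catalogue is the fixed feature-cutting frame shared by every subject.
#' High and low catalogues are built independently, so a tract may
#' contribute clusters of both directions.
#'
#' @param ez_patients EZ matrix (patients x voxels).
#' @param u,k voxel and extent thresholds in force.
#' @param space,atlas skeleton space and tract atlas.
#' @param frequency_fraction pooling fraction in (0, 1].
#' @param fwhm smoothness recorded in the provenance (optional).
#' @return An object of class `cluster_catalogue`.
#' @export
build_cluster_catalogue <- function(ez_patients, u, k, space, atlas,
                                    frequency_fraction = 0.25,
                                    fwhm = NULL) {
  stopifnot(is.matrix(ez_patients), nrow(ez_patients) >= 1)
  if (frequency_fraction <= 0 || frequency_fraction > 1)
    stop("frequency_fraction must lie in (0, 1]")
  clusters <- list()
  for (direction in c("high", "low")) {
    abnormal <- if (direction == "high") ez_patients > u else
      ez_patients < -u
    group_mask <- colMeans(abnormal) >= frequency_fraction
    clusters <- c(clusters,
                  cluster_mask(group_mask, k, space, atlas, direction))
  }
  if (length(clusters) == 0)
    warning("empty cluster catalogue: no voxel abnormal in >= ",
            frequency_fraction, " of patients survived extent thresholding")
  ord <- order(vapply(clusters, function(x) x$tract, numeric(1)),
               vapply(clusters, function(x) x$direction, character(1)),
               vapply(clusters, function(x) x$id, character(1)))
  structure(list(clusters = clusters[ord],
                 provenance = list(u = u, k = k, connectivity = 26L,
                                   fwhm = fwhm,
                                   frequency_fraction = frequency_fraction,
                                   n_patients = nrow(ez_patients))),
            class = "cluster_catalogue")
}

#' @export
print.cluster_catalogue <- function(x, ...) {
  n <- length(x$clusters)
  tracts <- unique(vapply(x$clusters, function(c) c$tract_name, character(1)))
  cat(sprintf(
    "<cluster_catalogue> %d cluster(s) in %d tract(s) (u=%.2f, k=%d, pooling >= %.0f%%)\n",
    n, length(tracts), x$provenance$u, x$provenance$k,
    100 * x$provenance$frequency_fraction))
  invisible(x)
}

#' @export
length.cluster_catalogue <- function(x) length(x$clusters)

#' Cut per-subject mean-FA features from the cluster catalogue
#'
#' Cell (s, c) is the mean of subject s's covariate-adjusted FA over the
#' voxels of catalogue cluster c. Columns are ordered by (tract id,
#' direction, cluster id) and named by cluster id; feature metadata is
#' attached as the `"feature_info"` attribute.
#'
#' @param fa_adj matrix of covariate-adjusted FA (subjects x voxels,
#'   rownames = ids).
#' @param catalogue a [build_cluster_catalogue()] result.
#' @return Feature matrix (subjects x clusters) of class `feature_matrix`.
#' @export
extract_features <- function(fa_adj, catalogue) {
  stopifnot(inherits(catalogue, "cluster_catalogue"), is.matrix(fa_adj))
  cl <- catalogue$clusters
  if (length(cl) == 0)
    stop("catalogue is empty; supply cytokine features instead")
  feats <- vapply(cl, function(c) {
    if (any(c$skeleton_pos > ncol(fa_adj)) || anyNA(c$skeleton_pos))
      stop("subject maps do not cover cluster ", c$id)
    v <- fa_adj[, c$skeleton_pos, drop = FALSE]
    if (anyNA(v)) stop("missing FA under cluster ", c$id)
    rowMeans(v)
  }, numeric(nrow(fa_adj)))
  feats <- matrix(feats, nrow = nrow(fa_adj),
                  dimnames = list(rownames(fa_adj),
                                  vapply(cl, `[[`, character(1), "id")))
  info <- data.frame(
    feature = colnames(feats),
    tract = vapply(cl, function(c) c$tract, numeric(1)),
    tract_name = vapply(cl, `[[`, character(1), "tract_name"),
    direction = vapply(cl, `[[`, character(1), "direction"),
    extent = vapply(cl, function(c) c$extent, integer(1)),
    domain = "fa")
  structure(feats, feature_info = info, class = c("feature_matrix", "matrix"))
}

#' Feature metadata of a feature matrix
#' @param x a `feature_matrix`.
#' @return data.frame of per-column metadata.
#' @export
feature_info <- function(x) attr(x, "feature_info")
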