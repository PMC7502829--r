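#' Estimate field smoothness (FWHM) from normative residual maps
#'
#' Standardizes each voxel's residuals across maps and estimates the
#' Gaussian autocorrelation scale from the mean squared spatial first
#' difference along each axis: for lag-1 correlation rho, FWHM(vox) =
#' sqrt(-2 log 2 / log rho), converted to mm and clipped below at one
#' voxel size. White (unsmoothed) residuals therefore return the voxel
#' size itself.
#'
#' @param resid matrix of residual maps (maps x skeleton voxels), at least
#'   two rows; typically adjusted control FA minus the normative mean.
#' @param space the [skeleton_space()] the maps live on.
#' @return Numeric length-3 vector of per-axis FWHM in mm, with attribute
#'   `"mean"` (geometric mean).
#' @export
estimate_smoothness <- function(resid, space) {
  stopifnot(is.matrix(resid), nrow(resid) >= 2,
            ncol(resid) == n_voxels(space))
  sds <- apply(resid, 2, sd)
  if (all(sds == 0)) stop("all residual maps are constant")
  keep <- sds > 0
  z <- sweep(resid[, keep, drop = FALSE], 2, sds[keep], "/")

  d <- space$dim
  on_skel <- logical(prod(d))
  on_skel[space$idx] <- FALSE
  on_skel[space$idx[keep]] <- TRUE
  pos <- integer(prod(d))
  pos[space$idx[keep]] <- seq_len(sum(keep))
  co <- arrayInd(space$idx[keep], d)
  strides <- c(1L, d[1], d[1] * d[2])

  fwhm <- numeric(3)
  for (ax in 1:3) {
    ok <- co[, ax] < d[ax]
    nb <- space$idx[keep][ok] + strides[ax]
    ok[ok] <- on_skel[nb]
    if (!any(ok)) { fwhm[ax] <- space$voxel_size[ax]; next }
    a <- pos[space$idx[keep][ok]]
    b <- pos[space$idx[keep][ok] + strides[ax]]
    v <- mean((z[, a, drop = FALSE] - z[, b, drop = FALSE])^2)
    rho <- 1 - v / 2
    fwhm[ax] <- if (rho <= 0) space$voxel_size[ax] else
      max(space$voxel_size[ax],
          sqrt(-2 * log(2) / log(rho)) * space$voxel_size[ax])
  }
  attr(fwhm, "mean") <- prod(fwhm)^(1 / 3)
  fwhm
}

#' Analytic cluster-extent threshold under Gaussian random field theory
#'
#' Returns the smallest cluster extent k (voxels) such that the family-wise
#' probability of observing at least one suprathreshold cluster of extent
#' >= k, in a smooth Gaussian null field of the given FWHM over a search
#' region of `n_voxels` voxels thresholded at `u` (one-sided), is at most
#' `alpha`. Uses the standard 3D expected-cluster-count and exponential
#' cluster-extent tail approximation:
#' E\[m\] = S (4 log 2)^{3/2} (2 pi)^{-2} (u^2 - 1) exp(-u^2/2) / f^3,
#' P(n >= k) = exp(-beta k^{2/3}) with beta matched to E\[n\] = E\[N\]/E\[m\].
#'
#' @param u voxelwise z threshold (> 0, one-sided).
#' @param fwhm smoothness, same units as `voxel_size` (scalar or per axis).
#' @param n_voxels number of voxels in the search region.
#' @param alpha family-wise error level in (0, 1).
#' @param voxel_size voxel edge length (default 1: `fwhm` already in
#'   voxels).
#' @return Integer extent threshold k >= 1.
#' @export
grf_extent_threshold <- function(u, fwhm, n_voxels, alpha = 0.05,
                                 voxel_size = 1) {
  if (!all(is.finite(c(u, fwhm, n_voxels, alpha, voxel_size))))
    stop("non-finite inputs to grf_extent_threshold")
  stopifnot(u > 0, alpha > 0, alpha < 1, n_voxels >= 1)
  f <- prod(rep_len(fwhm / voxel_size, 3L))^(1 / 3)
  if (f < 1) stop("fwhm must be at least one voxel size")
  S <- n_voxels
  Em <- S * (4 * log(2))^(3 / 2) * (2 * pi)^(-2) *
    max(u^2 - 1, .Machine$double.eps) * exp(-u^2 / 2) / f^3
  EN <- S * pnorm(u, lower.tail = FALSE)
  # P(>=1 cluster of extent >= k) ~ 1 - exp(-Em * P(n >= k)) <= alpha
  ptail <- -log(1 - alpha) / Em
  if (ptail >= 1) return(1L)
  beta <- (gamma(5 / 2) * Em / EN)^(2 / 3)
  k <- (-log(ptail) / beta)^(3 / 2)
  max(1L, as.integer(ceiling(k)))
}

#' Monte-Carlo cluster-extent threshold on an arbitrary search mask
#'
#' Simulates `n_fields` smooth Gaussian null fields (white noise convolved
#' with a Gaussian kernel of the given FWHM on a padded grid, rescaled to
#' unit marginal variance), thresholds each at `u` (one-sided) within the
#' mask, and returns the smallest extent k whose exceedance frequency of
#' the maximum cluster size is at most `alpha`. This is the reference
#' null for quasi-2D skeleton masks, where 3D GRF theory is only
#' approximate.
#'
#' @param u voxelwise z threshold.
#' @param fwhm smoothness in mm (scalar or per axis).
#' @param space a [skeleton_space()]; the mask is `space$mask`.
#' @param alpha family-wise error level.
#' @param n_fields number of simulated null fields.
#' @param seed integer seed.
#' @param connectivity fixed at 26 (vertex adjacency).
#' @return Integer extent threshold k >= 1, with attribute `"max_extents"`
#'   (the simulated null maxima).
#' @export
mc_extent_threshold <- function(u, fwhm, space, alpha = 0.05,
                                n_fields = 1000L, seed = 1L,
                                connectivity = 26L) {
  stopifnot(inherits(space, "skeleton_space"), u > 0,
            alpha > 0, alpha < 1, n_fields >= 100)
  if (connectivity != 26L) stop("only 26-connectivity is supported")
  fwhm <- rep_len(as.numeric(fwhm), 3L)
  sigma <- (fwhm / space$voxel_size) / sqrt(8 * log(2))
  pad <- as.integer(ceiling(3.5 * max(sigma)))
  dpad <- space$dim + 2L * pad
  scale <- 1 / sqrt(smoothing_var_factor(fwhm, space$voxel_size))
  core <- lapply(1:3, function(ax) (pad + 1):(pad + space$dim[ax]))

  maxima <- integer(n_fields)
  with_seed(seed, {
    for (i in seq_len(n_fields)) {
      field <- array(rnorm(prod(dpad)), dim = dpad)
      field <- smooth_field(field, fwhm, space$voxel_size) * scale
      field <- field[core[[1]], core[[2]], core[[3]]]
      supra <- (field > u) & space$mask
      if (!any(supra)) { maxima[i] <- 0L; next }
      lab <- label_components(supra)
      maxima[i] <- max(tabulate(lab[lab > 0L]))
    }
  })
  ks <- sort(unique(c(1L, maxima + 1L)))
  exceed <- vapply(ks, function(k) mean(maxima >= k), numeric(1))
  k <- ks[which(exceed <= alpha)[1]]
  structure(max(1L, k), max_extents = maxima)
}
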