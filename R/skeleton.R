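#' Skeleton sampling space
#'
#' A `skeleton_space` describes the common voxel grid and the white-matter
#' skeleton mask on which every subject's FA values live: the grid shape,
#' the voxel size in mm, and the linear indices of on-skeleton voxels.
#' All per-voxel quantities in the package (FA, EZ scores, normative means)
#' are stored as vectors over `space$idx`, in increasing index order.
#'
#' @param mask logical 3D array, `TRUE` on the skeleton.
#' @param voxel_size numeric length 1 or 3, voxel edge length(s) in mm.
#' @return An object of class `skeleton_space`.
#' @export
skeleton_space <- function(mask, voxel_size = 2) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3D array")
  if (!any(mask)) stop("skeleton mask is empty")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be positive and finite")
  structure(list(dim = dim(mask), voxel_size = voxel_size,
                 mask = mask, idx = which(mask)),
            class = "skeleton_space")
}

#' @export
print.skeleton_space <- function(x, ...) {
  cat(sprintf("<skeleton_space> grid %s, voxel %s mm, %d skeleton voxels\n",
              paste(x$dim, collapse = "x"),
              paste(format(x$voxel_size, trim = TRUE), collapse = "x"),
              length(x$idx)))
  invisible(x)
}

n_voxels <- function(space) length(space$idx)

#' A subject's FA values on the skeleton
#'
#' @param values numeric vector of FA values, one per on-skeleton voxel in
#'   the order of `space$idx`. Must lie in \[0, 1\].
#' @param space a [skeleton_space()].
#' @param id subject identifier.
#' @return An object of class `skeleton_image`.
#' @export
skeleton_image <- function(values, space, id = NA_character_) {
  stopifnot(inherits(space, "skeleton_space"))
  values <- as.numeric(values)
  if (length(values) != n_voxels(space))
    stop("values must have one entry per skeleton voxel (",
         n_voxels(space), "), got ", length(values))
  if (anyNA(values) || any(values < 0 | values > 1))
    stop("FA values must be finite and within [0, 1] on the skeleton")
  structure(list(values = values, space = space, id = id),
            class = "skeleton_image")
}

#' @export
print.skeleton_image <- function(x, ...) {
  cat(sprintf("<skeleton_image> id=%s, %d voxels, FA range [%.3f, %.3f]\n",
              x$id, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# Embed a skeleton-ordered vector into the full 3D grid (off-skeleton = fill).
embed_skeleton <- function(values, space, fill = NA_real_) {
  arr <- array(fill, dim = space$dim)
  arr[space$idx] <- values
  arr
}

# Gaussian smoothing of a full-grid array; fwhm in mm, per axis or scalar.
smooth_field <- function(arr, fwhm, voxel_size) {
  fwhm <- rep_len(as.numeric(fwhm), 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  sigma <- (fwhm / voxel_size) / sqrt(8 * log(2))
  out <- .gaussian_smooth_3d(as.numeric(arr), as.integer(dim(arr)), sigma)
  array(out, dim = dim(arr))
}

# Connected components (26-connectivity) of a logical array restricted to
# the skeleton; returns integer labels over the full grid (0 = background).
label_components <- function(mask_arr) {
  lab <- .label_components_26(as.logical(mask_arr), as.integer(dim(mask_arr)))
  array(lab, dim = dim(mask_arr))
}
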