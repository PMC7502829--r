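
nifti_of <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep_len(voxel_size, 3L)
  img
}

#' Write a synthetic cohort to disk (NIfTI + CSV + YAML)
#'
#' Writes one FA volume per subject (off-skeleton voxels zero), the binary
#' skeleton mask, the integer tract atlas with its label table, the
#' covariate/cytokine/outcome tables, the injected truth, and the
#' generating configuration.
#'
#' @param bundle a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(file.path(dir, "fa"), recursive = TRUE, showWarnings = FALSE)
  sp <- bundle$space
  RNifti::writeNifti(nifti_of(array(as.integer(sp$mask), sp$dim),
                              sp$voxel_size),
                     file.path(dir, "skeleton.nii.gz"))
  atlas_arr <- array(0L, sp$dim)
  atlas_arr[sp$idx] <- bundle$atlas$labels
  RNifti::writeNifti(nifti_of(atlas_arr, sp$voxel_size),
                     file.path(dir, "atlas.nii.gz"))
  write.csv(bundle$atlas$table, file.path(dir, "atlas_labels.csv"),
            row.names = FALSE)
  for (id in rownames(bundle$fa)) {
    arr <- array(0, sp$dim)
    arr[sp$idx] <- bundle$fa[id, ]
    RNifti::writeNifti(nifti_of(arr, sp$voxel_size),
                       file.path(dir, "fa", paste0(id, ".nii.gz")))
  }
  write.csv(bundle$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write.csv(bundle$cytokines, file.path(dir, "cytokines.csv"),
            row.names = FALSE)
  write.csv(bundle$outcomes, file.path(dir, "outcomes.csv"),
            row.names = FALSE)
  truth <- data.frame(id = names(bundle$truth$burden),
                      burden = unname(bundle$truth$burden),
                      severity = unname(bundle$truth$severity))
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- bundle$config
  cfg$norms_table <- NULL
  cfg$lesion_specs <- as.list(cfg$lesion_specs)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort of skeletonized FA volumes
#'
#' Validates that every volume shares the skeleton's grid and affine, that
#' FA lies in \[0, 1\] on the skeleton, and that every atlas label appears
#' in the label table.
#'
#' @param dir directory containing a `fa/` subdirectory of per-subject
#'   NIfTI volumes (file name = subject id).
#' @param skeleton path to the binary skeleton mask NIfTI.
#' @param atlas path to the integer tract-label NIfTI.
#' @param atlas_table path to the label CSV (`id`, `name`).
#' @return list with `fa` (matrix subjects x skeleton voxels), `space`,
#'   `atlas`.
#' @export
read_skeleton_cohort <- function(dir, skeleton = file.path(dir, "skeleton.nii.gz"),
                                 atlas = file.path(dir, "atlas.nii.gz"),
                                 atlas_table = file.path(dir, "atlas_labels.csv")) {
  sk_img <- RNifti::readNifti(skeleton)
  sp <- skeleton_space(array(sk_img != 0, dim(sk_img)),
                       RNifti::pixdim(sk_img))
  ref_xform <- RNifti::xform(sk_img)

  at_img <- RNifti::readNifti(atlas)
  if (!identical(dim(at_img), dim(sk_img)))
    stop("atlas shape mismatch: ", atlas)
  labels <- array(as.integer(at_img), dim(at_img))[sp$idx]
  table <- read.csv(atlas_table)
  orphans <- setdiff(setdiff(unique(labels), 0L), table$id)
  if (length(orphans) > 0)
    stop("atlas labels absent from label table: ",
         paste(sort(orphans), collapse = ", "))

  files <- sort(list.files(file.path(dir, "fa"), full.names = TRUE,
                           pattern = "\\.nii(\\.gz)?$"))
  if (length(files) == 0) stop("no FA volumes found under ", dir)
  fa <- matrix(NA_real_, length(files), n_voxels(sp))
  ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
  for (i in seq_along(files)) {
    img <- RNifti::readNifti(files[i])
    if (!identical(dim(img), dim(sk_img)))
      stop("FA volume shape mismatch: ", files[i])
    if (!isTRUE(all.equal(RNifti::xform(img), ref_xform,
                          check.attributes = FALSE, tolerance = 1e-5)))
      stop("FA volume affine mismatch: ", files[i])
    v <- as.numeric(img)[sp$idx]
    if (anyNA(v) || any(v < 0 | v > 1))
      stop("FA outside [0, 1] on the skeleton: ", files[i])
    fa[i, ] <- v
  }
  rownames(fa) <- ids
  list(fa = fa, space = sp, atlas = list(labels = labels, table = table))
}

#' Serialize a cluster catalogue to JSON (plus optional NIfTI label volume)
#'
#' @param catalogue a [build_cluster_catalogue()] result.
#' @param path output JSON path.
#' @param space optional [skeleton_space()]; when given, a cluster-id label
#'   volume is written next to the JSON (`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(catalogue, path, space = NULL) {
  stopifnot(inherits(catalogue, "cluster_catalogue"))
  payload <- list(
    provenance = catalogue$provenance,
    clusters = lapply(catalogue$clusters, function(c)
      c[c("id", "tract", "tract_name", "direction", "extent", "voxels")]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(space)) {
    arr <- array(0L, space$dim)
    for (i in seq_along(catalogue$clusters))
      arr[catalogue$clusters[[i]]$voxels] <- i
    RNifti::writeNifti(nifti_of(arr, space$voxel_size),
                       sub("\\.json$", ".nii.gz", path))
  }
  invisible(path)
}

#' Read a cluster catalogue written by [write_catalogue()]
#'
#' @param path JSON path.
#' @param space the [skeleton_space()] the catalogue refers to.
#' @return A `cluster_catalogue`.
#' @export
read_catalogue <- function(path, space) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  clusters <- lapply(payload$clusters, function(c) {
    c$voxels <- as.integer(unlist(c$voxels))
    c$skeleton_pos <- match(c$voxels, space$idx)
    c$extent <- as.integer(c$extent)
    c$tract <- as.numeric(c$tract)
    c
  })
  structure(list(clusters = clusters, provenance = payload$provenance),
            class = "cluster_catalogue")
}

# Cheap content hash (md5 of the JSON serialization) for provenance fields.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}
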