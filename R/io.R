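#' NIfTI-1 volume adapters
#'
#' Thin wrappers around RNifti preserving the affine and voxel size.
#' `write_nifti_volume()` writes 3D/4D numeric or logical arrays (masks are
#' written as uint8); `read_nifti_volume()` returns a plain array with
#' attributes `voxel_size` and `affine`.
#'
#' @param vol Numeric or logical array (3D or 4D).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return `write_nifti_volume()` the path, invisibly; `read_nifti_volume()`
#'   the array.
#' @export
write_nifti_volume <- function(vol, path, voxel_size = 2, affine = NULL) {
  is_mask <- is.logical(vol)
  arr <- if (is_mask) array(as.integer(vol), dim(vol)) else vol
  img <- RNifti::asNifti(arr)
  if (is.null(affine)) affine <- diag(c(rep(voxel_size, 3), 1))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[1]
  attr(arr, "affine") <- unclass(RNifti::xform(img))
  arr
}

#' Write a DWI acquisition to NIfTI plus FSL gradient files
#'
#' @param dwi A [dwi_volume()].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_volume"))
  nii <- paste0(prefix, ".nii.gz")
  write_nifti_volume(dwi$signal, nii, voxel_size = dwi$voxel_size,
                     affine = dwi$affine)
  grad <- write_bvals_bvecs(dwi$gradients, paste0(prefix, ".bval"),
                            paste0(prefix, ".bvec"))
  invisible(c(dwi = nii, grad))
}

#' @rdname write_dwi
#' @export
read_dwi <- function(prefix) {
  arr <- read_nifti_volume(paste0(prefix, ".nii.gz"))
  gt <- read_bvals_bvecs(paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  dwi_volume(array(arr, dim(arr)), gt,
             voxel_size = attr(arr, "voxel_size"),
             affine = attr(arr, "affine"))
}

#' Write tensor-fit and scalar maps as NIfTI volumes
#'
#' Writes the six tensor component volumes, fitted s0, fit mask, FA, MD,
#' `|V1|` component maps and the three axis diffusivities into a directory,
#' all sharing the input affine.
#'
#' @param fit A [fit_tensor()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_scalar_maps <- function(fit, dir) {
  stopifnot(inherits(fit, "tensor_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- fit$voxel_size; af <- fit$affine
  paths <- character(0)
  wr <- function(vol, name) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    write_nifti_volume(vol, p, voxel_size = vx, affine = af)
    paths <<- c(paths, p)
  }
  for (k in seq_along(TENSOR_COMP)) wr(fit$tensor[, , , k],
                                       paste0("tensor_", TENSOR_COMP[k]))
  wr(fit$s0, "s0"); wr(fit$mask, "mask")
  sc <- eigendecompose(fit)
  wr(sc$fa, "fa"); wr(sc$md, "md")
  for (k in 1:3) wr(sc$abs_v1[, , , k], paste0("abs_v1_", c("x", "y", "z")[k]))
  ax <- axis_diffusivities(fit)
  wr(ax$dxx, "dxx"); wr(ax$dyy, "dyy"); wr(ax$dzz, "dzz")
  invisible(paths)
}

#' Write a per-subject ALPS record
#'
#' Serializes an [compute_alps()] result (with ROI voxel counts, pipeline
#' parameters and package version) to JSON.
#'
#' @param result An `alps_result`.
#' @param path Output JSON path.
#' @param parameters Optional named list of pipeline parameters to embed.
#' @return The path, invisibly.
#' @export
write_alps_record <- function(result, path, parameters = list()) {
  stopifnot(inherits(result, "alps_result"))
  rec <- list(
    software = list(
      package = "glymphalps",
      version = as.character(utils::packageVersion("glymphalps"))),
    parameters = parameters,
    left = result$left, right = result$right,
    mean_alps_index = result$mean_alps_index
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write label or ROI masks as uint8 NIfTI files
#'
#' @param x A [label_set()] or [select_rois()] result.
#' @param dir Output directory.
#' @param voxel_size,affine Geometry to stamp on the files.
#' @return Character vector of written paths, invisibly.
#' @export
write_mask_set <- function(x, dir, voxel_size = 2, affine = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (h in c("left", "right")) for (t in c("proj", "assoc")) {
    m <- x[[h]][[t]]
    attributes(m) <- list(dim = dim(m))
    p <- file.path(dir, sprintf("%s_%s.nii.gz", h, t))
    write_nifti_volume(array(as.logical(m), dim(m)), p,
                       voxel_size = voxel_size, affine = affine)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_mask_set
#' @param provenance Provenance string for the returned label set.
#' @export
read_mask_set <- function(dir, provenance = dir) {
  rd <- function(h, t) {
    arr <- read_nifti_volume(file.path(dir, sprintf("%s_%s.nii.gz", h, t)))
    array(arr != 0, dim(arr))
  }
  label_set(left_proj = rd("left", "proj"), left_assoc = rd("left", "assoc"),
            right_proj = rd("right", "proj"),
            right_assoc = rd("right", "assoc"),
            provenance = provenance)
}
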