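#' Eigenstructure and rotation-invariant scalars of a tensor field
#'
#' Per fitted voxel, performs the symmetric 3x3 eigendecomposition, sorts
#' eigenvalues in descending order, and derives the standard DTI scalars:
#' mean diffusivity `MD = (l1 + l2 + l3) / 3`, fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((li - MD)^2)) / sqrt(sum(li^2))` (0 for the
#' zero tensor), the principal eigenvector V1, and its componentwise absolute
#' values, the "color-FA" channel maps.  Taking absolute values discards the
#' eigenvector's arbitrary sign, so only the inclination of V1 to each
#' scanner axis is retained.  Voxels with non-finite tensor components are
#' masked out and counted.
#'
#' @param field A [fit_tensor()] result, a `phantom_field`, or a bare
#'   `[x, y, z, 6]` tensor array.
#' @param mask Logical 3D array restricting computation; defaults to the fit
#'   mask when available, else all voxels.
#' @return Object of class `diffusion_scalars`: list with `lambda`
#'   (`[x, y, z, 3]`, descending), `v1` (`[x, y, z, 3]`, unit), `abs_v1`
#'   (componentwise absolute V1), `fa`, `md` (3D arrays), `mask`, and
#'   `n_nonfinite` (voxels masked out).
#' @examples
#' ph <- simulate_tensor_field(phantom_spec())
#' sc <- eigendecompose(ph$tensor)
#' sc$abs_v1[5, 5, 5, ] # projection voxel: (0, 0, 1)
#' @export
eigendecompose <- function(field, mask = NULL) {
  arr <- extract_tensor_array(field)
  gs <- dim(arr)[1:3]
  if (is.null(mask)) {
    mask <- if (inherits(field, "tensor_fit")) field$mask else array(TRUE, gs)
  }
  if (!identical(dim(mask), gs)) stopf("mask does not match the tensor grid")
  comp <- tensor_flat(arr)
  idx <- which(mask)
  finite <- rowSums(!is.finite(comp[idx, , drop = FALSE])) == 0
  n_nonfinite <- sum(!finite)
  idx <- idx[finite]

  n_vox <- prod(gs)
  lambda <- matrix(0, n_vox, 3L)
  v1 <- matrix(0, n_vox, 3L)
  for (i in idx) {
    e <- eigen(comp_to_mat(comp[i, ]), symmetric = TRUE)
    lambda[i, ] <- e$values           # descending for symmetric = TRUE
    v1[i, ] <- e$vectors[, 1]
  }
  md <- rowMeans(lambda)
  dev2 <- (lambda - md)^2
  ss <- lambda[, 1]^2 + lambda[, 2]^2 + lambda[, 3]^2
  fa <- ifelse(ss > 0, sqrt(1.5 * rowSums(dev2) / ss), 0)
  fa[-idx] <- 0
  md[-idx] <- 0
  outmask <- array(FALSE, gs); outmask[idx] <- TRUE
  structure(list(
    lambda = array(lambda, c(gs, 3L)),
    v1 = array(v1, c(gs, 3L)),
    abs_v1 = array(abs(v1), c(gs, 3L)),
    fa = array(pmin(fa, 1), gs),
    md = array(md, gs),
    mask = outmask,
    n_nonfinite = n_nonfinite
  ), class = "diffusion_scalars")
}

#' @export
print.diffusion_scalars <- function(x, ...) {
  m <- x$mask
  cat(sprintf("Diffusion scalars on %d voxels; FA median %.3f, MD median %.3g (1e-3 mm^2/s)\n",
              sum(m), stats::median(x$fa[m]), stats::median(x$md[m])))
  if (x$n_nonfinite)
    cat(sprintf("  %d voxels masked out for non-finite tensor components\n",
                x$n_nonfinite))
  invisible(x)
}

#' Scanner-axis diffusivities from the tensor diagonal
#'
#' Returns `e' D e` for the three canonical scanner axes, i.e. the diagonal
#' elements Dxx, Dyy, Dzz of the tensor in the acquisition frame.  These are
#' the apparent diffusivities along x (right-left, the perivascular flow
#' direction at the ventricle body), y (anterior-posterior) and z
#' (inferior-superior), and are the four ingredients of the ALPS index once
#' averaged over the projection and association ROIs.
#'
#' @param field A `tensor_fit`, `phantom_field`, or `[x, y, z, 6]` array.
#' @return Named list of three 3D arrays `dxx`, `dyy`, `dzz` (1e-3 mm^2/s).
#' @export
axis_diffusivities <- function(field) {
  arr <- extract_tensor_array(field)
  list(dxx = arr[, , , 1], dyy = arr[, , , 2], dzz = arr[, , , 3])
}

extract_tensor_array <- function(field) {
  arr <- if (inherits(field, "tensor_fit")) field$tensor
  else if (inherits(field, "phantom_field")) field$tensor
  else field
  if (length(dim(arr)) != 4L || dim(arr)[4] != 6L)
    stopf("expected a tensor_fit, phantom_field, or [x, y, z, 6] array")
  arr
}
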