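#' Specification of a synthetic diffusion phantom
#'
#' The phantom mimics the periventricular geometry exploited by the ALPS
#' method in a small voxel grid: per hemisphere, one projection-fiber box
#' (dominant diffusion along z, as in the corticospinal tract at the level of
#' the lateral-ventricle body) and one association-fiber box (dominant
#' diffusion along y, as in the superior longitudinal fasciculus).  Inside
#' both fiber boxes a perivascular term `g` is added to the x-axis
#' diffusivity, modelling fluid movement along the medullary-vein perivascular
#' spaces which run right-left, orthogonal to both tracts.  Everything else is
#' isotropic background.  All diffusivities are in 1e-3 mm^2/s.
#'
#' Axes follow the RAS convention: x = right-left, y = anterior-posterior,
#' z = inferior-superior.
#'
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param voxel_size Isotropic voxel edge in mm.
#' @param regions Named list of four boxes (`left_proj`, `left_assoc`,
#'   `right_proj`, `right_assoc`), each `list(x = c(lo, hi), y = ..., z = ...)`
#'   in inclusive 1-based voxel indices.  The defaults are mirror-symmetric
#'   about the x midline.
#' @param base_diffusivity Transverse (fiber-perpendicular) eigenvalue.
#' @param fiber_diffusivity Dominant (along-fiber) eigenvalue; must exceed
#'   `base_diffusivity`.
#' @param perivascular_boost Perivascular term `g` added to Dxx inside both
#'   fiber regions; `g = 0` gives an ALPS index of exactly 1.
#' @param background_diffusivity Isotropic diffusivity outside the fiber boxes.
#' @param impurity_fraction Fraction of each fiber box given a randomly
#'   rotated copy of the fiber tensor, emulating contamination (crossing
#'   fibers, CSF partial volume) that color-FA thresholding must reject.
#'   `floor(impurity_fraction * n_box)` voxels per region are replaced.
#' @param s0 Baseline (b = 0) signal for DWI synthesis.
#' @param noise_sigma Rician noise scale for DWI synthesis (same units as
#'   `s0`); 0 means noiseless.
#' @param seed Integer seed for impurity placement, orientations and noise.
#' @return A validated object of class `phantom_spec`.
#' @seealso [simulate_tensor_field()], [tensor_to_dwi()]
#' @export
phantom_spec <- function(grid_shape = c(22L, 22L, 12L),
                         voxel_size = 2,
                         regions = default_phantom_regions(grid_shape),
                         base_diffusivity = 0.4,
                         fiber_diffusivity = 1.7,
                         perivascular_boost = 0.2,
                         background_diffusivity = 0.7,
                         impurity_fraction = 0,
                         s0 = 1000,
                         noise_sigma = 0,
                         seed = 1) {
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    regions = regions,
    base_diffusivity = base_diffusivity,
    fiber_diffusivity = fiber_diffusivity,
    perivascular_boost = perivascular_boost,
    background_diffusivity = background_diffusivity,
    impurity_fraction = impurity_fraction,
    s0 = s0, noise_sigma = noise_sigma, seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
}

default_phantom_regions <- function(grid_shape = c(22L, 22L, 12L)) {
  nx <- grid_shape[1]
  list(
    left_proj   = list(x = c(4L, 6L), y = c(4L, 9L), z = c(4L, 9L)),
    left_assoc  = list(x = c(4L, 6L), y = c(13L, 18L), z = c(4L, 9L)),
    right_proj  = list(x = c(nx - 5L, nx - 3L), y = c(4L, 9L), z = c(4L, 9L)),
    right_assoc = list(x = c(nx - 5L, nx - 3L), y = c(13L, 18L), z = c(4L, 9L))
  )
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(grid_shape < 1)) stopf("grid_shape must be positive")
    if (voxel_size <= 0) stopf("voxel_size must be positive (mm)")
    diffs <- c(base_diffusivity, fiber_diffusivity, background_diffusivity)
    if (any(!is.finite(diffs)) || any(diffs <= 0))
      stopf("all diffusivities must be positive")
    if (fiber_diffusivity <= base_diffusivity)
      stopf("fiber_diffusivity must exceed base_diffusivity")
    if (perivascular_boost < 0) stopf("perivascular_boost must be >= 0")
    if (impurity_fraction < 0 || impurity_fraction >= 1)
      stopf("impurity_fraction must be in [0, 1)")
    if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
    if (s0 <= 0) stopf("s0 must be positive")
  })
  expected <- c("left_proj", "left_assoc", "right_proj", "right_assoc")
  if (!setequal(names(spec$regions), expected))
    stopf("regions must be named %s", paste(expected, collapse = ", "))
  masks <- lapply(spec$regions, function(b) {
    rng <- rbind(b$x, b$y, b$z)
    if (any(rng[, 1] < 1) || any(rng[, 2] > spec$grid_shape) ||
        any(rng[, 1] > rng[, 2]))
      stopf("region box out of grid or inverted")
    box_mask(spec$grid_shape, b)
  })
  total <- Reduce(`+`, lapply(masks, as.integer))
  if (any(total > 1)) stopf("phantom fiber regions overlap")
  spec
}

#' Simulate a phantom diffusion-tensor field with labels and ground truth
#'
#' Realizes a [phantom_spec()]: projection-region voxels carry the tensor
#' `diag(base + g, base, fiber)`, association-region voxels
#' `diag(base + g, fiber, base)`, and background voxels the isotropic tensor
#' `diag(bg, bg, bg)`.  A seeded subset of in-region voxels
#' (`floor(impurity_fraction * n)` per region) is replaced by a uniformly
#' rotated copy of that region's fiber tensor.  Tract labels are returned as
#' the fiber boxes dilated by one voxel, emulating atlas labels that spill
#' beyond the tract; the exact boxes are returned as restriction masks (the
#' analogue of clipping atlas labels to the safe periventricular area) and in
#' the ground-truth record.
#'
#' @param spec A `phantom_spec`.
#' @return A list of class `phantom_field` with elements `tensor`
#'   (`[x, y, z, 6]` array, component order xx, yy, zz, xy, xz, yz, units
#'   1e-3 mm^2/s), `labels` and `restrictions` (both [label_set()] objects),
#'   `truth` (list: `g`, diffusivities, region boxes, impurity voxel indices
#'   per region), `voxel_size`, and `spec`.
#' @examples
#' ph <- simulate_tensor_field(phantom_spec(perivascular_boost = 0.2))
#' ph$tensor[5, 5, 5, ] # projection voxel: diag(0.6, 0.4, 1.7)
#' @export
simulate_tensor_field <- function(spec) {
  spec <- validate_phantom_spec(spec)
  gs <- spec$grid_shape
  tensor <- array(0, dim = c(gs, 6L))
  flat <- matrix(0, prod(gs), 6L)
  flat[, 1:3] <- spec$background_diffusivity
  base <- spec$base_diffusivity; fib <- spec$fiber_diffusivity
  g <- spec$perivascular_boost
  region_tensor <- list(
    proj  = c(base + g, base, fib, 0, 0, 0),   # dominant along z
    assoc = c(base + g, fib, base, 0, 0, 0)    # dominant along y
  )
  masks <- lapply(spec$regions, function(b) box_mask(gs, b))
  impurities <- list()
  with_seed(spec$seed, {
    for (nm in names(masks)) {
      idx <- which(masks[[nm]])
      kind <- if (grepl("proj", nm)) "proj" else "assoc"
      tcomp <- region_tensor[[kind]]
      flat[idx, ] <- matrix(tcomp, length(idx), 6L, byrow = TRUE)
      n_imp <- floor(spec$impurity_fraction * length(idx))
      imp <- if (n_imp > 0) sort(sample(idx, n_imp)) else integer(0)
      for (i in imp) {
        R <- random_rotation()
        flat[i, ] <- mat_to_comp(R %*% comp_to_mat(tcomp) %*% t(R))
      }
      impurities[[nm]] <- imp
    }
  })
  tensor <- array(flat, dim = c(gs, 6L))
  labels <- label_set(
    left_proj   = dilate1(masks$left_proj),
    left_assoc  = dilate1(masks$left_assoc),
    right_proj  = dilate1(masks$right_proj),
    right_assoc = dilate1(masks$right_assoc),
    provenance = "synthetic phantom: fiber boxes dilated by one voxel"
  )
  restrictions <- label_set(
    left_proj = masks$left_proj, left_assoc = masks$left_assoc,
    right_proj = masks$right_proj, right_assoc = masks$right_assoc,
    provenance = "synthetic phantom: exact fiber boxes"
  )
  structure(list(
    tensor = tensor,
    labels = labels,
    restrictions = restrictions,
    truth = list(
      g = g, base_diffusivity = base, fiber_diffusivity = fib,
      background_diffusivity = spec$background_diffusivity,
      regions = spec$regions, impurity_voxels = impurities
    ),
    voxel_size = spec$voxel_size,
    spec = spec
  ), class = "phantom_field")
}

#' @export
print.phantom_field <- function(x, ...) {
  gs <- dim(x$tensor)[1:3]
  cat(sprintf("Phantom tensor field %s voxels (%.1f mm), g = %.3g, impurities: %d\n",
              paste(gs, collapse = "x"), x$voxel_size, x$truth$g,
              sum(lengths(x$truth$impurity_voxels))))
  invisible(x)
}

#' Synthesize diffusion-weighted volumes from a tensor field
#'
#' Applies the monoexponential diffusion signal model
#' `S = s0 * exp(-b g' D g)` per voxel and gradient, with optional Rician
#' corruption `sqrt((S + e1)^2 + e2^2)` where `e1, e2` are zero-mean Gaussian
#' with scale `noise_sigma` (magnitude-MRI noise), or plain additive Gaussian
#' noise for debugging.
#'
#' @param field A `phantom_field`, or a bare `[x, y, z, 6]` tensor component
#'   array in 1e-3 mm^2/s.
#' @param gradients A [make_gradient_table()] table.
#' @param s0 Baseline signal: a scalar or a per-voxel volume matching the
#'   grid (defaults to the phantom spec value when `field` is a
#'   `phantom_field`).
#' @param noise_sigma Noise scale in signal units; 0 disables noise.
#' @param seed Integer seed for the noise realization.
#' @param noise_model `"rician"` (default) or `"gaussian"`.
#' @param voxel_size Voxel edge in mm (taken from the phantom when available).
#' @return An object of class `dwi_volume`: list with `signal`
#'   (`[x, y, z, n_volumes]`), `gradients`, `voxel_size` and `affine`.
#' @examples
#' gt <- make_gradient_table(6, 1000, seed = 2)
#' arr <- array(rep(c(1.7, 0.3, 0.3, 0, 0, 0), each = 8), c(2, 2, 2, 6))
#' dwi <- tensor_to_dwi(arr, gt, s0 = 1000)
#' dwi$signal[1, 1, 1, 1] # b = 0 volume: exactly 1000
#' @export
tensor_to_dwi <- function(field, gradients, s0 = NULL, noise_sigma = NULL,
                          seed = 1, noise_model = c("rician", "gaussian"),
                          voxel_size = 2) {
  noise_model <- match.arg(noise_model)
  validate_gradient_table(gradients, for_fitting = FALSE)
  if (inherits(field, "phantom_field")) {
    if (is.null(s0)) s0 <- field$spec$s0
    if (is.null(noise_sigma)) noise_sigma <- field$spec$noise_sigma
    voxel_size <- field$voxel_size
    arr <- field$tensor
  } else {
    arr <- field
    if (is.null(s0)) s0 <- 1000
    if (is.null(noise_sigma)) noise_sigma <- 0
  }
  if (length(dim(arr)) != 4L || dim(arr)[4] != 6L)
    stopf("tensor field must be an [x, y, z, 6] array")
  if (any(!is.finite(s0)) || any(s0 <= 0)) stopf("s0 must be positive")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  gs <- dim(arr)[1:3]
  comp <- tensor_flat(arr)
  quad <- tensor_quadform(comp, gradients$bvecs)     # n_vox x n_vol
  # b in s/mm^2, D stored in 1e-3 mm^2/s
  expo <- sweep(quad, 2, gradients$bvals * 1e-3, "*")
  # s0 may be a scalar or a per-voxel volume matching the grid
  if (length(s0) > 1 && !identical(dim(s0)[1:3], gs))
    stopf("per-voxel s0 must match the tensor grid")
  sig <- as.vector(s0) * exp(-expo)
  if (noise_sigma > 0) {
    sig <- with_seed(seed, {
      n <- length(sig)
      if (noise_model == "rician") {
        e1 <- stats::rnorm(n, sd = noise_sigma)
        e2 <- stats::rnorm(n, sd = noise_sigma)
        sqrt((sig + e1)^2 + e2^2)
      } else {
        sig + stats::rnorm(n, sd = noise_sigma)
      }
    })
  }
  dwi_volume(array(sig, dim = c(gs, ncol(quad))), gradients,
             voxel_size = voxel_size)
}

#' Construct a DWI volume container
#'
#' @param signal 4D nonnegative array, volumes along the 4th dimension.
#' @param gradients Matching `gradient_table`.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity with the voxel size on the diagonal.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, gradients, voxel_size = 2, affine = NULL) {
  validate_gradient_table(gradients, for_fitting = FALSE)
  if (length(dim(signal)) != 4L)
    stopf("signal must be a 4D array (x, y, z, volume)")
  if (dim(signal)[4] != length(gradients$bvals))
    stopf("signal has %d volumes but the gradient table has %d entries",
          dim(signal)[4], length(gradients$bvals))
  if (any(signal < 0)) stopf("DWI signal must be nonnegative")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  structure(list(signal = signal, gradients = gradients,
                 voxel_size = voxel_size, affine = affine),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("DWI volume %s voxels x %d volumes (%.1f mm, b = %s s/mm^2)\n",
              paste(d[1:3], collapse = "x"), d[4], x$voxel_size,
              paste(sort(unique(x$gradients$bvals)), collapse = "/")))
  invisible(x)
}
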