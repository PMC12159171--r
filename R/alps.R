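#' Mean of a diffusivity map over an ROI
#'
#' Arithmetic mean over in-ROI voxels with finite values; non-finite voxels
#' are excluded and counted rather than failing the run.
#'
#' @param map 3D diffusivity volume (1e-3 mm^2/s).
#' @param roi Logical 3D mask, non-empty.
#' @return The mean, with attribute `n_excluded` (non-finite voxels skipped).
#' @export
roi_mean <- function(map, roi) {
  if (!identical(dim(map), dim(roi)))
    stopf("diffusivity map and ROI are on different grids")
  vals <- map[roi]
  if (!length(vals)) stopf("empty ROI in roi_mean()")
  ok <- is.finite(vals)
  if (!any(ok)) stopf("ROI contains no finite diffusivity values")
  out <- mean(vals[ok])
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' The ALPS index
#'
#' Ratio of the mean perivascular-direction (x-axis) diffusivity in the
#' projection and association areas to the mean of the two diffusivities
#' perpendicular to both the tracts and the perivascular flow (y in the
#' projection area, z in the association area):
#' `((dxx_proj + dxx_assoc) / 2) / ((dyy_proj + dzz_assoc) / 2)`.
#' A value near 1 indicates no preferential diffusion along the perivascular
#' direction; larger values indicate stronger perivascular-direction flow.
#'
#' @param dxx_proj,dxx_assoc,dyy_proj,dzz_assoc ROI-mean diffusivities
#'   (1e-3 mm^2/s), all finite and positive.
#' @return The unitless ALPS index.
#' @examples
#' alps_index(1.2, 1.0, 0.8, 0.8) # 1.375
#' @export
alps_index <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc) {
  vals <- c(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all four diffusivities must be finite and positive")
  denom <- (dyy_proj + dzz_assoc) / 2
  if (denom <= 0) stopf("ALPS denominator is not positive")
  ((dxx_proj + dxx_assoc) / 2) / denom
}

#' Compute the ALPS index per hemisphere and averaged
#'
#' For each hemisphere, averages the x-axis diffusivity over the projection
#' and association ROIs (numerator terms) and the y-axis (projection) and
#' z-axis (association) diffusivities (denominator terms), forms the
#' hemisphere ALPS index with [alps_index()], and reports the arithmetic
#' mean of the two hemisphere indices.
#'
#' @param field A `tensor_fit`, `phantom_field`, or `[x, y, z, 6]` tensor
#'   array, or a precomputed list with elements `dxx`, `dyy`, `dzz` from
#'   [axis_diffusivities()].
#' @param rois A [select_rois()] result.
#' @return Object of class `alps_result`: per hemisphere the four ROI-mean
#'   diffusivities, voxel counts, excluded-voxel counts and `alps_index`,
#'   plus `mean_alps_index`.
#' @examples
#' ph <- simulate_tensor_field(phantom_spec(perivascular_boost = 0.2))
#' sc <- eigendecompose(ph$tensor)
#' rois <- select_rois(sc, restrict_label_set(ph$labels, ph$restrictions))
#' compute_alps(ph, rois)$mean_alps_index # (0.4 + 0.2) / 0.4 = 1.5
#' @export
compute_alps <- function(field, rois) {
  stopifnot(inherits(rois, "roi_set"))
  maps <- if (is.list(field) && all(c("dxx", "dyy", "dzz") %in% names(field)))
    field else axis_diffusivities(field)
  assert_same_grid(maps$dxx, rois$left$proj, "diffusivity maps and ROIs")
  hemi <- function(h) {
    r <- rois[[h]]
    dxx_proj <- roi_mean(maps$dxx, r$proj)
    dxx_assoc <- roi_mean(maps$dxx, r$assoc)
    dyy_proj <- roi_mean(maps$dyy, r$proj)
    dzz_assoc <- roi_mean(maps$dzz, r$assoc)
    list(
      dxx_proj = as.numeric(dxx_proj), dxx_assoc = as.numeric(dxx_assoc),
      dyy_proj = as.numeric(dyy_proj), dzz_assoc = as.numeric(dzz_assoc),
      n_voxels = c(proj = sum(r$proj), assoc = sum(r$assoc)),
      n_excluded = attr(dxx_proj, "n_excluded") + attr(dxx_assoc, "n_excluded") +
        attr(dyy_proj, "n_excluded") + attr(dzz_assoc, "n_excluded"),
      alps_index = alps_index(as.numeric(dxx_proj), as.numeric(dxx_assoc),
                              as.numeric(dyy_proj), as.numeric(dzz_assoc))
    )
  }
  left <- tryCatch(hemi("left"),
                   error = function(e) stopf("left hemisphere: %s", conditionMessage(e)))
  right <- tryCatch(hemi("right"),
                    error = function(e) stopf("right hemisphere: %s", conditionMessage(e)))
  structure(list(
    left = left, right = right,
    mean_alps_index = (left$alps_index + right$alps_index) / 2
  ), class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat("ALPS index\n")
  for (h in c("left", "right")) {
    hh <- x[[h]]
    cat(sprintf("  %-5s %.4f  (Dxx %0.3f/%0.3f, Dyy proj %0.3f, Dzz assoc %0.3f; %d+%d voxels)\n",
                h, hh$alps_index, hh$dxx_proj, hh$dxx_assoc, hh$dyy_proj,
                hh$dzz_assoc, hh$n_voxels["proj"], hh$n_voxels["assoc"]))
  }
  cat(sprintf("  mean  %.4f\n", x$mean_alps_index))
  invisible(x)
}

#' Flatten an ALPS result to a one-row data frame
#'
#' @param x An `alps_result`.
#' @param ... Unused.
#' @return One-row data frame with per-hemisphere diffusivities, indices and
#'   the mean index, suitable for rbinding across subjects.
#' @export
as.data.frame.alps_result <- function(x, ...) {
  row <- list()
  for (h in c("left", "right")) {
    hh <- x[[h]]
    row[[paste0(h, "_dxx_proj")]] <- hh$dxx_proj
    row[[paste0(h, "_dxx_assoc")]] <- hh$dxx_assoc
    row[[paste0(h, "_dyy_proj")]] <- hh$dyy_proj
    row[[paste0(h, "_dzz_assoc")]] <- hh$dzz_assoc
    row[[paste0(h, "_alps")]] <- hh$alps_index
  }
  row$mean_alps <- x$mean_alps_index
  as.data.frame(row)
}
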