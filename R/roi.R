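#' Per-hemisphere tract label sets
#'
#' Holds the four binary masks the ALPS analysis needs: a projection-tract
#' (corticospinal) and an association-tract (superior longitudinal fasciculus)
#' label per hemisphere, already in the subject's diffusion voxel grid.
#' Within a hemisphere the two labels must be disjoint and non-empty.
#'
#' @param left_proj,left_assoc,right_proj,right_assoc Logical (or 0/1) 3D
#'   arrays on a common grid.
#' @param provenance Free-text description of where the labels came from.
#' @return Object of class `label_set` with elements `left` and `right`, each
#'   a list with `proj` and `assoc` masks.
#' @export
label_set <- function(left_proj, left_assoc, right_proj, right_assoc,
                      provenance = "") {
  masks <- list(left_proj = left_proj, left_assoc = left_assoc,
                right_proj = right_proj, right_assoc = right_assoc)
  masks <- lapply(masks, function(m) {
    if (!is.logical(m)) {
      if (!all(m %in% c(0, 1))) stopf("label masks must be binary")
      m <- array(m != 0, dim(m))
    }
    m
  })
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), d))
      stopf("label mask '%s' is on a different grid", nm)
    if (!any(masks[[nm]])) stopf("label mask '%s' is empty", nm)
  }
  if (any(masks$left_proj & masks$left_assoc) ||
      any(masks$right_proj & masks$right_assoc))
    stopf("projection and association labels overlap within a hemisphere")
  structure(list(
    left = list(proj = masks$left_proj, assoc = masks$left_assoc),
    right = list(proj = masks$right_proj, assoc = masks$right_assoc),
    provenance = provenance
  ), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("Label set on a %s grid (%s)\n",
              paste(dim(x$left$proj), collapse = "x"),
              if (nzchar(x$provenance)) x$provenance else "no provenance"))
  for (h in c("left", "right")) for (t in c("proj", "assoc"))
    cat(sprintf("  %s %s: %d voxels\n", h, t, sum(x[[h]][[t]])))
  invisible(x)
}

#' Restrict a tract label to a region
#'
#' Voxelwise intersection of a label mask with a restriction mask, the
#' analogue of clipping atlas tract labels to the area at the top of the
#' lateral ventricles before ROI scoring.
#'
#' @param label Logical 3D label mask.
#' @param restriction Logical 3D mask (or a box `list(x =, y =, z =)` of
#'   inclusive index ranges) to intersect with.
#' @param name Label name used in error messages.
#' @return The intersected logical mask; an empty intersection is an error.
#' @export
restrict_label <- function(label, restriction, name = "label") {
  if (is.list(restriction)) restriction <- box_mask(dim(label), restriction)
  if (!identical(dim(label), dim(restriction)))
    stopf("restriction mask does not match the grid of '%s'", name)
  out <- label & restriction
  if (!any(out))
    stopf("restriction leaves label '%s' empty", name)
  out
}

#' Restrict every label in a set
#'
#' @param labels A [label_set()].
#' @param restrictions A `label_set` (or list with the same structure) of
#'   restriction masks.
#' @return A restricted `label_set`.
#' @export
restrict_label_set <- function(labels, restrictions) {
  stopifnot(inherits(labels, "label_set"))
  label_set(
    left_proj = restrict_label(labels$left$proj, restrictions$left$proj, "left proj"),
    left_assoc = restrict_label(labels$left$assoc, restrictions$left$assoc, "left assoc"),
    right_proj = restrict_label(labels$right$proj, restrictions$right$proj, "right proj"),
    right_assoc = restrict_label(labels$right$assoc, restrictions$right$assoc, "right assoc"),
    provenance = paste0(labels$provenance, " [restricted]")
  )
}

#' Color-FA axis-purity score
#'
#' Scores every voxel by how exclusively its principal eigenvector points
#' along the desired scanner axis: the two nuisance-axis components of
#' `|V1|` are subtracted from the desired-axis component and the result is
#' multiplied by FA.  Pure desired-axis fibers score `+FA`, pure
#' nuisance-axis fibers `-FA`, and isotropic voxels 0, so ranking by this
#' score favors strongly oriented voxels of the wanted tract.
#'
#' @param scalars A [eigendecompose()] result.
#' @param desired_axis `"x"`, `"y"` or `"z"`.
#' @return 3D score volume with values in `[-FA, FA]`, a subset of `[-1, 1]`.
#' @export
color_fa_score <- function(scalars, desired_axis) {
  stopifnot(inherits(scalars, "diffusion_scalars"))
  ax <- match(desired_axis, c("x", "y", "z"))
  if (is.na(ax)) stopf("desired_axis must be one of 'x', 'y', 'z' (got '%s')",
                       as.character(desired_axis)[1])
  a <- scalars$abs_v1
  others <- setdiff(1:3, ax)
  (a[, , , ax] - a[, , , others[1]] - a[, , , others[2]]) * scalars$fa
}

#' Keep the highest-scoring fraction of in-mask voxels
#'
#' Retains the `k = ceiling(fraction * N)` voxels of `mask` with the highest
#' score.  Ties at the cutoff are broken by ascending linearized voxel index,
#' so the result is deterministic.
#'
#' @param score 3D score volume.
#' @param mask Logical 3D mask of candidate voxels (non-empty).
#' @param fraction Fraction to keep, in (0, 1]; default 0.87.
#' @return Logical mask of kept voxels with attributes `threshold` (lowest
#'   kept score) and `n_kept`.
#' @examples
#' s <- array(1:27, c(3, 3, 3))
#' m <- array(TRUE, c(3, 3, 3))
#' sum(threshold_top_fraction(s, m, 0.5)) # ceiling(0.5 * 27) = 14
#' @export
threshold_top_fraction <- function(score, mask, fraction = 0.87) {
  if (!(is.numeric(fraction) && length(fraction) == 1 &&
        fraction > 0 && fraction <= 1))
    stopf("fraction must be in (0, 1]")
  if (!identical(dim(score), dim(mask)))
    stopf("score and mask are on different grids")
  idx <- which(mask)
  if (!length(idx)) stopf("mask is empty")
  k <- ceiling(fraction * length(idx))
  # order by descending score, ties by ascending linear index
  ord <- order(-score[idx], idx)
  kept_idx <- idx[ord[seq_len(k)]]
  out <- array(FALSE, dim(mask))
  out[kept_idx] <- TRUE
  attr(out, "threshold") <- min(score[kept_idx])
  attr(out, "n_kept") <- k
  out
}

#' Automatic ALPS ROI selection
#'
#' Reproduces the automated "color-FA thresholded" ROI selection: per
#' hemisphere, projection-tract voxels are scored for z-axis purity and
#' association-tract voxels for y-axis purity with [color_fa_score()], and
#' the top `fraction` of voxels within each label is kept with
#' [threshold_top_fraction()].  Hemispheres are processed independently and
#' only combined when the ALPS index is averaged.
#'
#' @param scalars A [eigendecompose()] result on the label grid.
#' @param labels A [label_set()] (already restricted, if desired; see
#'   [restrict_label_set()]).
#' @param fraction Fraction of voxels kept per label; default 0.87.
#' @return Object of class `roi_set`: per hemisphere, `proj` and `assoc`
#'   logical masks plus per-ROI voxel counts and realized score thresholds.
#' @export
select_rois <- function(scalars, labels, fraction = 0.87) {
  stopifnot(inherits(scalars, "diffusion_scalars"), inherits(labels, "label_set"))
  assert_same_grid(scalars$fa, labels$left$proj, "scalars and labels")
  score_z <- color_fa_score(scalars, "z")
  score_y <- color_fa_score(scalars, "y")
  pick <- function(score, mask, what) {
    m <- threshold_top_fraction(score, mask, fraction)
    if (!any(m)) stopf("empty final ROI for %s", what)
    m
  }
  rois <- list(
    left = list(proj = pick(score_z, labels$left$proj, "left projection"),
                assoc = pick(score_y, labels$left$assoc, "left association")),
    right = list(proj = pick(score_z, labels$right$proj, "right projection"),
                 assoc = pick(score_y, labels$right$assoc, "right association"))
  )
  counts <- thresholds <- list()
  for (h in c("left", "right")) for (t in c("proj", "assoc")) {
    key <- paste(h, t, sep = "_")
    counts[[key]] <- attr(rois[[h]][[t]], "n_kept")
    thresholds[[key]] <- attr(rois[[h]][[t]], "threshold")
  }
  structure(list(left = rois$left, right = rois$right,
                 counts = counts, thresholds = thresholds,
                 fraction = fraction),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ALPS ROI set (top %.0f%% per label):\n", 100 * x$fraction))
  for (key in names(x$counts))
    cat(sprintf("  %-12s %4d voxels (score threshold %.4f)\n",
                key, x$counts[[key]], x$thresholds[[key]]))
  invisible(x)
}
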