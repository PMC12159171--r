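#' Diffusion gradient tables
#'
#' A gradient table pairs one b-value (s/mm^2) with one encoding direction per
#' acquired volume.  `make_gradient_table()` builds a single-shell table with
#' `n_b0` unweighted volumes followed by `n_directions` noncollinear unit
#' vectors obtained by electrostatic repulsion of antipodal point pairs on the
#' sphere, so directions cover orientation space evenly and the tensor design
#' matrix is well conditioned.
#'
#' @param n_directions Number of diffusion-weighted directions (at least 6,
#'   the number of unique tensor components).
#' @param b_value Diffusion weighting in s/mm^2 for the weighted volumes.
#' @param n_b0 Number of unweighted (b = 0) volumes, placed first.
#' @param seed Integer seed; the optimization is deterministic given the seed.
#' @param n_iter Repulsion iterations.
#' @return An object of class `gradient_table`: a list with `bvals` (length
#'   `n_b0 + n_directions`) and `bvecs` (3 x n matrix, FSL row convention).
#' @examples
#' gt <- make_gradient_table(30, 1000, n_b0 = 1, seed = 7)
#' range(colSums(gt$bvecs[, gt$bvals > 0]^2)) # unit norms
#' @export
make_gradient_table <- function(n_directions, b_value = 1000, n_b0 = 1,
                                seed = 1, n_iter = 250) {
  if (!is_count(n_directions) || n_directions < 6)
    stopf("n_directions must be an integer >= 6 (got %s): the diffusion tensor has 6 free components", format(n_directions))
  if (!is.numeric(b_value) || length(b_value) != 1 || !is.finite(b_value) || b_value <= 0)
    stopf("b_value must be a single positive number (s/mm^2)")
  if (!is_count(n_b0 + 1)) stopf("n_b0 must be a nonnegative integer")
  dirs <- with_seed(seed, repulsion_directions(n_directions, n_iter))
  bvals <- c(rep(0, n_b0), rep(b_value, n_directions))
  bvecs <- cbind(matrix(0, 3, n_b0), dirs)
  rownames(bvecs) <- c("x", "y", "z")
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

# Electrostatic repulsion on the sphere treating each direction and its
# antipode as a charge pair (diffusion encoding is antipodally symmetric).
repulsion_directions <- function(n, n_iter) {
  p <- matrix(stats::rnorm(3 * n), nrow = 3)
  p <- sweep(p, 2, sqrt(colSums(p^2)), "/")
  step <- 0.05
  for (it in seq_len(n_iter)) {
    f <- matrix(0, 3, n)
    for (i in seq_len(n)) {
      d1 <- p - p[, i]          # repulsion from +p_j
      d2 <- -p - p[, i]         # repulsion from -p_j
      r1 <- sqrt(colSums(d1^2)); r2 <- sqrt(colSums(d2^2))
      r1[i] <- Inf
      w1 <- 1 / pmax(r1, 1e-6)^3
      w2 <- 1 / pmax(r2, 1e-6)^3
      f[, i] <- -(d1 %*% w1) - (d2 %*% w2)
    }
    # project force onto tangent plane and take a damped step
    f <- f - sweep(p, 2, colSums(f * p), "*")
    p <- p + step * f / max(1, max(abs(f)))
    p <- sweep(p, 2, sqrt(colSums(p^2)), "/")
    step <- step * 0.98
  }
  # canonical hemisphere (z >= 0, ties toward +x) for reproducible output
  flip <- p[3, ] < 0 | (p[3, ] == 0 & p[1, ] < 0)
  p[, flip] <- -p[, flip]
  p[, order(p[1, ], p[2, ], p[3, ])]
}

#' Validate a gradient table
#'
#' Checks structural invariants: nonnegative b-values and unit-norm
#' directions (within 1e-6) wherever b > 0.  With `for_fitting = TRUE`
#' (the [fit_tensor()] contract) additionally requires at least one b = 0
#' volume and at least six distinct weighted directions, without which the
#' tensor is underdetermined.
#'
#' @param gt A `gradient_table`.
#' @param for_fitting Also enforce the tensor-fitting requirements.
#' @return `gt`, invisibly; errors name the offending volume otherwise.
#' @export
validate_gradient_table <- function(gt, for_fitting = TRUE) {
  stopifnot(inherits(gt, "gradient_table"))
  if (length(gt$bvals) != ncol(gt$bvecs))
    stopf("gradient table has %d b-values but %d directions",
          length(gt$bvals), ncol(gt$bvecs))
  if (any(gt$bvals < 0)) stopf("negative b-values are not allowed")
  wtd <- which(gt$bvals > 0)
  norms <- sqrt(colSums(gt$bvecs[, wtd, drop = FALSE]^2))
  bad <- which(abs(norms - 1) > 1e-6)
  if (length(bad))
    stopf("non-unit gradient direction at volume %d (|g| = %.8f)",
          wtd[bad[1]], norms[bad[1]])
  if (for_fitting) {
    if (!any(gt$bvals == 0)) stopf("at least one b = 0 volume is required")
    uniq <- unique(round(t(gt$bvecs[, wtd, drop = FALSE]), 6))
    if (nrow(uniq) < 6) stopf("fewer than 6 distinct weighted directions")
  }
  invisible(gt)
}

#' @export
print.gradient_table <- function(x, ...) {
  wtd <- x$bvals > 0
  cat(sprintf("Gradient table: %d volumes (%d b=0, %d weighted, b = %s s/mm^2)\n",
              length(x$bvals), sum(!wtd), sum(wtd),
              paste(unique(x$bvals[wtd]), collapse = ", ")))
  if (sum(wtd) > 1) {
    d <- t(x$bvecs[, wtd]) %*% x$bvecs[, wtd]
    ang <- acos(pmin(1, abs(d[upper.tri(d)]))) * 180 / pi
    cat(sprintf("  minimum pairwise angle: %.1f deg\n", min(ang)))
  }
  invisible(x)
}

#' Read and write FSL-dialect gradient files
#'
#' `bvals` is a single whitespace-separated row; `bvecs` holds three rows
#' (x, y, z components).  `read_bvals_bvecs()` validates the result with
#' [validate_gradient_table()].
#'
#' @param gt A `gradient_table`.
#' @param bvals_path,bvecs_path File paths.
#' @return `write_bvals_bvecs()` returns the paths invisibly;
#'   `read_bvals_bvecs()` returns a `gradient_table`.
#' @export
write_bvals_bvecs <- function(gt, bvals_path, bvecs_path) {
  stopifnot(inherits(gt, "gradient_table"))
  writeLines(paste(format(gt$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvals_path)
  writeLines(apply(gt$bvecs, 1, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = " ")), bvecs_path)
  invisible(c(bvals = bvals_path, bvecs = bvecs_path))
}

#' @rdname write_bvals_bvecs
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  rows <- lapply(readLines(bvecs_path), function(l) scan(text = l, quiet = TRUE))
  rows <- rows[vapply(rows, length, 1L) > 0]
  if (length(rows) != 3) stopf("bvecs file must have exactly 3 rows (x, y, z)")
  bvecs <- do.call(rbind, rows)
  rownames(bvecs) <- c("x", "y", "z")
  gt <- structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
  validate_gradient_table(gt)
  gt
}
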