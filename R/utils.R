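# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x > 0

# Logical 3D mask for an axis-aligned voxel box given inclusive index ranges.
box_mask <- function(grid_shape, box) {
  stopifnot(length(grid_shape) == 3L, is.list(box) || is.matrix(box))
  if (is.list(box)) box <- rbind(box$x, box$y, box$z)
  m <- array(FALSE, dim = grid_shape)
  m[box[1, 1]:box[1, 2], box[2, 1]:box[2, 2], box[3, 1]:box[3, 2]] <- TRUE
  m
}

# Binary dilation by one voxel with a full 3x3x3 (26-connected) structuring
# element, implemented by OR-ing shifted copies of the mask.
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    ti <- max(1L, 1L - dx):min(d[1], d[1] - dx)
    tj <- max(1L, 1L - dy):min(d[2], d[2] - dy)
    tk <- max(1L, 1L - dz):min(d[3], d[3] - dz)
    out[ti, tj, tk] <- out[ti, tj, tk, drop = FALSE] |
      mask[ti + dx, tj + dy, tk + dz, drop = FALSE]
  }
  out
}

# Uniform random rotation matrix (Haar measure) from a random unit quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Tensor component storage order used throughout: xx, yy, zz, xy, xz, yz.
TENSOR_COMP <- c("xx", "yy", "zz", "xy", "xz", "yz")

# 3x3 symmetric matrix from a length-6 component vector (or n x 6 matrix
# -> list of matrices is avoided; callers use tensor_quadform for bulk work).
comp_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), nrow = 3, byrow = TRUE)
}

mat_to_comp <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

# g' D g for all rows of an n x 6 component matrix and all unit columns of a
# 3 x m direction matrix; returns n x m.
tensor_quadform <- function(comp, dirs) {
  gx <- dirs[1, ]; gy <- dirs[2, ]; gz <- dirs[3, ]
  des <- rbind(gx^2, gy^2, gz^2, 2 * gx * gy, 2 * gx * gz, 2 * gy * gz)
  comp %*% des
}

# Flatten a [X,Y,Z,6] tensor array into an n_voxel x 6 matrix (and back).
tensor_flat <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = prod(d[1:3]), ncol = 6L)
}

assert_same_grid <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:3], dim(b)[1:3]))
    stopf("%s are on different voxel grids (%s vs %s)", what,
          paste(dim(a)[1:3], collapse = "x"), paste(dim(b)[1:3], collapse = "x"))
  invisible(TRUE)
}
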