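#' Fit the diffusion tensor by log-linear least squares
#'
#' Per masked voxel, fits `log S = log s0 - b g' D g` by ordinary (default)
#' or signal-weighted least squares over the design rows
#' `(1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz)`.
#' `s0` is estimated jointly as the intercept, which is more robust than the
#' mean b = 0 image when only one unweighted volume is acquired.  Volumes
#' with nonpositive signal are excluded from that voxel's fit; voxels left
#' with fewer than 7 usable volumes are dropped from the mask.  Tensors with
#' negative eigenvalues are clamped to positive semidefinite (eigenvalues
#' floored at 0) and counted.
#'
#' @param dwi A [dwi_volume()].
#' @param mask Logical 3D array of voxels to fit; default all voxels.
#' @param method `"ols"` for plain log-linear least squares or `"wls"` for a
#'   second pass weighted by the squared predicted signal.
#' @return An object of class `tensor_fit` with elements `tensor`
#'   (`[x, y, z, 6]`, order xx, yy, zz, xy, xz, yz, units 1e-3 mm^2/s), `s0`
#'   (fitted baseline per voxel), `mask` (voxels actually fitted), and a
#'   `log` list (dropped voxel count, clamped eigenvalue count, excluded
#'   signal count).  Methods: [coef.tensor_fit()], [predict.tensor_fit()],
#'   [residuals.tensor_fit()], [simulate.tensor_fit()], `print`, `summary`.
#' @examples
#' gt <- make_gradient_table(30, 1000, seed = 7)
#' ph <- simulate_tensor_field(phantom_spec())
#' fit <- fit_tensor(tensor_to_dwi(ph, gt))
#' fit
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("ols", "wls")) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "dwi_volume"))
  gt <- validate_gradient_table(dwi$gradients)
  gs <- dim(dwi$signal)[1:3]
  n_vol <- dim(dwi$signal)[4]
  if (is.null(mask)) mask <- array(TRUE, dim = gs)
  if (!identical(dim(mask), gs)) stopf("mask does not match the DWI grid")

  X <- tensor_design(gt)
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stopf("rank-deficient tensor design (collinear directions): all %d masked voxels unfittable",
          sum(mask))

  idx <- which(mask)
  sig <- matrix(dwi$signal, prod(gs), n_vol)[idx, , drop = FALSE]
  usable <- sig > 0
  n_usable <- rowSums(usable)
  dropped <- n_usable < 7L
  n_excluded <- sum(!usable[!dropped, ])

  comp <- matrix(NA_real_, length(idx), 6L)
  s0 <- rep(NA_real_, length(idx))
  full <- !dropped & n_usable == n_vol
  if (any(full)) {
    beta <- qr.coef(qrX, t(log(sig[full, , drop = FALSE])))
    if (method == "wls") beta <- wls_pass(X, sig[full, , drop = FALSE], beta)
    s0[full] <- exp(beta[1, ])
    comp[full, ] <- t(beta[-1, , drop = FALSE])
  }
  partial <- which(!dropped & n_usable < n_vol)
  for (i in partial) {
    keep <- usable[i, ]
    Xi <- X[keep, , drop = FALSE]
    if (qr(Xi)$rank < 7L) { dropped[i] <- TRUE; next }
    beta <- qr.coef(qr(Xi), log(sig[i, keep]))
    if (method == "wls") beta <- wls_pass(Xi, matrix(sig[i, keep], 1), matrix(beta))
    s0[i] <- exp(beta[1]); comp[i, ] <- beta[-1]
  }

  # clamp negative eigenvalues to zero (cheap PSD screen via leading minors)
  fitted <- which(!dropped)
  n_clamped <- 0L
  if (length(fitted)) {
    cc <- comp[fitted, , drop = FALSE]
    det2 <- cc[, 1] * cc[, 2] - cc[, 4]^2
    det3 <- cc[, 1] * (cc[, 2] * cc[, 3] - cc[, 6]^2) -
      cc[, 4] * (cc[, 4] * cc[, 3] - cc[, 6] * cc[, 5]) +
      cc[, 5] * (cc[, 4] * cc[, 6] - cc[, 2] * cc[, 5])
    suspect <- which(cc[, 1] < 0 | det2 < 0 | det3 < 0)
    for (j in suspect) {
      e <- eigen(comp_to_mat(cc[j, ]), symmetric = TRUE)
      if (any(e$values < 0)) {
        n_clamped <- n_clamped + 1L
        lam <- pmax(e$values, 0)
        comp[fitted[j], ] <- mat_to_comp(e$vectors %*% diag(lam) %*% t(e$vectors))
      }
    }
  }

  tensor <- array(0, dim = c(gs, 6L))
  tflat <- matrix(tensor, prod(gs), 6L)
  tflat[idx, ] <- comp
  s0vol <- array(0, dim = gs)
  s0vol[idx] <- s0
  fitmask <- array(FALSE, dim = gs)
  fitmask[idx[!dropped]] <- TRUE
  structure(list(
    tensor = array(tflat, dim = c(gs, 6L)),
    s0 = s0vol,
    mask = fitmask,
    gradients = gt,
    voxel_size = dwi$voxel_size,
    affine = dwi$affine,
    method = method,
    log = list(n_dropped = sum(dropped), n_clamped = n_clamped,
               n_excluded_signals = n_excluded)
  ), class = "tensor_fit")
}

# Design matrix for log-signal regression; b scaled so components come out
# in 1e-3 mm^2/s.
tensor_design <- function(gt) {
  b <- gt$bvals * 1e-3
  gx <- gt$bvecs[1, ]; gy <- gt$bvecs[2, ]; gz <- gt$bvecs[3, ]
  cbind(1, -b * gx^2, -b * gy^2, -b * gz^2,
        -2 * b * gx * gy, -2 * b * gx * gz, -2 * b * gy * gz)
}

# One signal-weighted refinement pass: weights are squared predicted signals,
# the standard variance-stabilizing choice for log-transformed Rician data.
wls_pass <- function(X, sig, beta) {
  out <- beta
  for (k in seq_len(ncol(beta))) {
    w <- exp(X %*% beta[, k])^2
    out[, k] <- stats::lm.wfit(X, log(sig[k, ]), w = as.vector(w))$coefficients
  }
  out
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("Diffusion tensor fit (%s): %d voxels fitted on a %s grid\n",
              toupper(x$method), sum(x$mask),
              paste(dim(x$mask), collapse = "x")))
  lg <- x$log
  if (lg$n_dropped || lg$n_clamped || lg$n_excluded_signals)
    cat(sprintf("  dropped voxels: %d; clamped tensors: %d; excluded signals: %d\n",
                lg$n_dropped, lg$n_clamped, lg$n_excluded_signals))
  invisible(x)
}

#' @export
summary.tensor_fit <- function(object, ...) {
  sc <- eigendecompose(object)
  m <- object$mask
  out <- list(
    n_voxels = sum(m),
    fa = summary(sc$fa[m]),
    md = summary(sc$md[m]),
    log = object$log
  )
  class(out) <- "summary.tensor_fit"
  out
}

#' @export
print.summary.tensor_fit <- function(x, ...) {
  cat(sprintf("Tensor fit over %d voxels\n", x$n_voxels))
  cat("FA:\n"); print(x$fa)
  cat("MD (1e-3 mm^2/s):\n"); print(x$md)
  invisible(x)
}

#' Extract fitted tensor components
#'
#' @param object A `tensor_fit`.
#' @param ... Unused.
#' @return Matrix with one row per fitted voxel and columns
#'   xx, yy, zz, xy, xz, yz (1e-3 mm^2/s).
#' @export
coef.tensor_fit <- function(object, ...) {
  out <- tensor_flat(object$tensor)[which(object$mask), , drop = FALSE]
  colnames(out) <- TENSOR_COMP
  out
}

#' Predict noiseless DWI signal from a fitted tensor field
#'
#' @param object A `tensor_fit`.
#' @param gradients Gradient table to predict for; defaults to the table the
#'   fit used.
#' @param ... Unused.
#' @return A `dwi_volume` of model-predicted signals (zero outside the mask).
#' @export
predict.tensor_fit <- function(object, gradients = object$gradients, ...) {
  validate_gradient_table(gradients)
  comp <- tensor_flat(object$tensor)
  quad <- tensor_quadform(comp, gradients$bvecs)
  expo <- sweep(quad, 2, gradients$bvals * 1e-3, "*")
  sig <- as.vector(object$s0) * exp(-expo)
  sig[!object$mask, ] <- 0
  dwi_volume(array(sig, dim = c(dim(object$mask), length(gradients$bvals))),
             gradients, voxel_size = object$voxel_size, affine = object$affine)
}

#' Residuals of a tensor fit
#'
#' @param object A `tensor_fit`.
#' @param dwi The observed `dwi_volume` the model was fitted to.
#' @param type `"signal"` (observed minus predicted) or `"log"`.
#' @param ... Unused.
#' @return 4D array of residuals (zero outside the fitted mask).
#' @export
residuals.tensor_fit <- function(object, dwi, type = c("signal", "log"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(dwi, "dwi_volume"))
  pred <- predict(object)$signal
  obs <- dwi$signal
  r <- if (type == "signal") obs - pred else {
    lr <- array(NA_real_, dim(obs))
    ok <- obs > 0 & pred > 0
    lr[ok] <- log(obs[ok]) - log(pred[ok])
    lr
  }
  r[!array(object$mask, dim(r))] <- 0
  r
}

#' Simulate DWI realizations from a fitted tensor field
#'
#' Runs the forward signal model of [tensor_to_dwi()] on the fitted tensors,
#' adding Rician noise.
#'
#' @param object A `tensor_fit`.
#' @param nsim Number of realizations.
#' @param seed Integer seed.
#' @param noise_sigma Rician noise scale; defaults to 0 (noiseless).
#' @param ... Unused.
#' @return A list of `nsim` `dwi_volume` objects.
#' @export
simulate.tensor_fit <- function(object, nsim = 1, seed = 1, noise_sigma = 0, ...) {
  s0 <- object$s0
  s0[!object$mask] <- 1  # arbitrary positive filler outside the fitted mask
  lapply(seq_len(nsim), function(k) {
    tensor_to_dwi(object$tensor, object$gradients, s0 = s0,
                  noise_sigma = noise_sigma, seed = seed + k - 1,
                  voxel_size = object$voxel_size)
  })
}
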