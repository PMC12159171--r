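test_that("noiseless fits are exact for random positive-definite tensors", {
  gt <- std_gradients()
  set.seed(42)
  comp <- t(replicate(50, tensor_components(random_spd_tensor())))
  est <- fit_component_matrix(comp, gt)
  scale <- sqrt(rowSums(comp^2))
  expect_lt(max(abs(est - comp) / scale), 1e-10)
})

test_that("noiseless isotropic input yields zero off-diagonals", {
  gt <- std_gradients()
  comp <- matrix(rep(c(0.8, 0.8, 0.8, 0, 0, 0), 5), 5, 6, byrow = TRUE)
  est <- fit_component_matrix(comp, gt)
  expect_lt(max(abs(est[, 4:6])), 1e-10)
})

test_that("noisy fit error stays below the frozen Monte-Carlo bound", {
  # Bound computed once from an independent 20-replicate Monte-Carlo run of
  # the forward model at sigma = 2% of s0 (500 voxels, 30 directions), then
  # frozen with ~15% headroom.
  gt <- std_gradients()
  truth <- c(1.2, 0.5, 0.9, 0.1, -0.05, 0.08)
  comp <- matrix(truth, 500, 6, byrow = TRUE)
  est <- fit_component_matrix(comp, gt, noise_sigma = 20, seed = 99)
  rmse <- sqrt(colMeans((est - comp)^2))
  bound <- c(0.040, 0.033, 0.036, 0.021, 0.023, 0.019)
  expect_true(all(rmse < bound))
})

test_that("voxels with too few usable volumes are dropped and logged", {
  gt <- std_gradients()
  arr <- array(rep(c(1.0, 0.8, 0.6, 0, 0, 0), each = 4), c(4, 1, 1, 6))
  dwi <- tensor_to_dwi(arr, gt, s0 = 1000)
  dwi$signal[2, 1, 1, 1:26] <- 0       # 5 usable volumes left
  dwi$signal[3, 1, 1, 4] <- 0          # one excluded, still fittable
  fit <- fit_tensor(dwi)
  expect_false(fit$mask[2, 1, 1])
  expect_true(fit$mask[3, 1, 1])
  expect_equal(fit$log$n_dropped, 1L)
  expect_gte(fit$log$n_excluded_signals, 1L)
  est <- fit$tensor[3, 1, 1, ]
  expect_equal(est, c(1.0, 0.8, 0.6, 0, 0, 0), tolerance = 1e-8)
})

test_that("eigendecomposition produces sorted eigenvalues and unit |V1|", {
  ch <- std_phantom_chain()
  sc <- ch$sc
  m <- which(sc$mask)
  lam <- matrix(sc$lambda, prod(dim(sc$mask)), 3)[m, ]
  expect_true(all(diff(t(lam)) <= 1e-12))
  v <- matrix(sc$abs_v1, prod(dim(sc$mask)), 3)[m, ]
  expect_true(all(abs(rowSums(v^2) - 1) < 1e-9))
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(sc$fa[m] >= 0 & sc$fa[m] <= 1))
})

test_that("diagonal and isotropic tensors give the known scalars", {
  arr <- array(c(1.7, 0.3, 0.3, 0, 0, 0), c(1, 1, 1, 6))
  sc <- eigendecompose(arr)
  expect_equal(sc$abs_v1[1, 1, 1, ], c(1, 0, 0))
  expect_equal(sc$md[1, 1, 1], (1.7 + 0.3 + 0.3) / 3, tolerance = 1e-12)
  # FA closed form: sqrt(1.5 * sum((l - MD)^2) / sum(l^2)) = 0.7990222
  expect_equal(sc$fa[1, 1, 1], 0.7990222, tolerance = 1e-6)

  iso <- array(c(0.6, 0.6, 0.6, 0, 0, 0), c(1, 1, 1, 6))
  sci <- eigendecompose(iso)
  expect_equal(sci$fa[1, 1, 1], 0)
  expect_equal(as.vector(sci$lambda[1, 1, 1, ]), rep(0.6, 3), tolerance = 1e-12)

  zero <- array(0, c(1, 1, 1, 6))
  expect_equal(eigendecompose(zero)$fa[1, 1, 1], 0)
})

test_that("trace is conserved and FA is rotation invariant", {
  set.seed(7)
  for (i in 1:20) {
    D <- random_spd_tensor()
    arr <- array(tensor_components(D), c(1, 1, 1, 6))
    sc <- eigendecompose(arr)
    expect_equal(sum(sc$lambda[1, 1, 1, ]), sum(diag(D)), tolerance = 1e-9)
    R <- glymphalps:::random_rotation()
    arr_rot <- array(tensor_components(R %*% D %*% t(R)), c(1, 1, 1, 6))
    expect_equal(eigendecompose(arr_rot)$fa[1, 1, 1], sc$fa[1, 1, 1],
                 tolerance = 1e-9)
  }
})

test_that("axis diffusivities return the scanner-frame diagonal", {
  arr <- array(c(0.6, 0.4, 1.7, 0.1, 0.05, -0.02), c(1, 1, 1, 6))
  ax <- axis_diffusivities(arr)
  expect_equal(c(ax$dxx[1], ax$dyy[1], ax$dzz[1]), c(0.6, 0.4, 1.7))
  # rotating diag(a, b, c) by 90 degrees about z swaps the x and y entries
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  D <- diag(c(1.1, 0.5, 0.9))
  rot <- array(tensor_components(Rz %*% D %*% t(Rz)), c(1, 1, 1, 6))
  axr <- axis_diffusivities(rot)
  expect_equal(c(axr$dxx[1], axr$dyy[1], axr$dzz[1]), c(0.5, 1.1, 0.9),
               tolerance = 1e-12)
})

test_that("non-finite tensors are masked out with a count", {
  arr <- array(rep(c(1, 1, 1, 0, 0, 0), each = 3), c(3, 1, 1, 6))
  arr[2, 1, 1, 1] <- NaN
  sc <- eigendecompose(arr)
  expect_false(sc$mask[2, 1, 1])
  expect_equal(sc$n_nonfinite, 1L)
})

test_that("tensor_fit methods expose coefficients, predictions and residuals", {
  ch <- std_phantom_chain()
  fit <- ch$fit
  cf <- coef(fit)
  expect_equal(colnames(cf), c("xx", "yy", "zz", "xy", "xz", "yz"))
  expect_equal(nrow(cf), sum(fit$mask))
  pred <- predict(fit)
  expect_s3_class(pred, "dwi_volume")
  expect_equal(pred$signal, ch$dwi$signal, tolerance = 1e-8)
  res <- residuals(fit, ch$dwi)
  expect_lt(max(abs(res)), 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 3, noise_sigma = 10)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$signal, sims[[2]]$signal))
})
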