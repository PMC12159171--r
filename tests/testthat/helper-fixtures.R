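# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

std_gradients <- function() {
  fixture("gt30", function() make_gradient_table(30, 1000, n_b0 = 1, seed = 7))
}

# Noiseless default phantom (g = 0.2) taken through the full imaging chain.
std_phantom_chain <- function() {
  fixture("chain", function() {
    ph <- simulate_tensor_field(phantom_spec())
    dwi <- tensor_to_dwi(ph, std_gradients())
    fit <- fit_tensor(dwi)
    sc <- eigendecompose(fit)
    rois <- select_rois(sc, restrict_label_set(ph$labels, ph$restrictions))
    list(ph = ph, dwi = dwi, fit = fit, sc = sc, rois = rois)
  })
}

# Random symmetric positive-definite tensor with eigenvalues in [lo, hi]
# (units 1e-3 mm^2/s), via a random rotation of a random diagonal.
random_spd_tensor <- function(lo = 0.1, hi = 2.5) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
  lam <- sort(stats::runif(3, lo, hi), decreasing = TRUE)
  R %*% diag(lam) %*% t(R)
}

tensor_components <- function(m) c(m[1, 1], m[2, 2], m[3, 3],
                                   m[1, 2], m[1, 3], m[2, 3])

# Fit a set of tensors (rows of n x 6 components) arranged as a flat grid.
fit_component_matrix <- function(comp, gt, s0 = 1000, noise_sigma = 0,
                                 seed = 1) {
  n <- nrow(comp)
  arr <- array(comp, c(n, 1, 1, 6))
  dwi <- tensor_to_dwi(arr, gt, s0 = s0, noise_sigma = noise_sigma,
                       seed = seed)
  fit <- fit_tensor(dwi)
  matrix(fit$tensor, n, 6)
}
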