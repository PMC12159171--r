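test_that("small tie-free Mann-Whitney p-values are exact", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_equal(res$mode, "exact")
  # symmetry: swapping samples mirrors U and keeps p
  swapped <- mann_whitney(c(3, 4), c(1, 2))
  expect_equal(swapped$U, 2 * 2 - res$U)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
})

test_that("identical pooled samples degenerate to p = 1 with a warning", {
  expect_warning(res <- mann_whitney(c(2, 2, 2), c(2, 2)), "identical")
  expect_equal(res$p, 1)
  expect_equal(res$mode, "degenerate")
})

test_that("exact p matches the wilcox.test oracle on tie-free samples", {
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(100, n1 + n2)
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    mine <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$U, unname(ref$statistic))
  }
})

test_that("the normal approximation matches wilcox.test with ties", {
  set.seed(77)
  for (rep in 1:15) {
    a <- sample(1:6, 15, replace = TRUE)
    b <- sample(2:7, 12, replace = TRUE)
    mine <- mann_whitney(a, b)
    expect_equal(mine$mode, "approximate")
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("spearman_ci reproduces hand-computed rank correlations", {
  res <- spearman_ci(1:4, c(2, 4, 6, 8))
  expect_equal(res$rho, 1)
  expect_equal(res$ci[2], 1)
  # rank-difference formula: 1 - 6 * 6 / (3 * 8) = -0.5 (n = 3 padded to 4)
  res2 <- spearman_ci(c(1, 2, 3, 4), c(3, 1, 2, 4))
  d <- rank(c(1, 2, 3, 4)) - rank(c(3, 1, 2, 4))
  expect_equal(res2$rho, 1 - 6 * sum(d^2) / (4 * (16 - 1)), tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(100)
  res3 <- spearman_ci(x, -x)
  expect_equal(res3$rho, -1)
  expect_equal(res3$p, 0)
})

test_that("spearman estimates agree with the cor.test oracle under ties", {
  set.seed(11)
  for (rep in 1:10) {
    x <- sample(1:8, 30, replace = TRUE)
    y <- x + sample(1:5, 30, replace = TRUE)
    mine <- spearman_ci(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("spearman CI uses the Fisher z transform and handles degeneracy", {
  set.seed(6)
  x <- rnorm(54); y <- 0.5 * x + rnorm(54)
  res <- spearman_ci(x, y)
  zr <- atanh(res$rho)
  expect_equal(res$ci,
               tanh(zr + c(-1, 1) * qnorm(0.975) / sqrt(54 - 3)),
               tolerance = 1e-12)
  expect_true(res$ci[1] <= res$rho && res$rho <= res$ci[2])
  const <- spearman_ci(rep(1, 10), rnorm(10))
  expect_true(const$undefined)
  expect_true(is.na(const$rho))
  expect_error(spearman_ci(1:3, 3:1), "4")
})

test_that("bonferroni flags apply the alpha / m cutoff", {
  expect_equal(bonferroni_flags(c(0.001, 0.01, 0.04), m = 14),
               c(TRUE, FALSE, FALSE))
  expect_equal(bonferroni_flags(0.04, m = 1), TRUE)
  expect_equal(bonferroni_flags(0.06, m = 1), FALSE)
  # supplying more p-values than the declared family warns
  expect_warning(bonferroni_flags(c(0.04, 0.06), m = 1), "family size")
  expect_false(any(bonferroni_flags(rep(1, 5), m = 5)))
  expect_error(bonferroni_flags(0.5, m = 0), "positive")
})

test_that("OLS with interaction recovers exact and planted coefficients", {
  # perfect fit: y = 2 x
  tab <- data.frame(y = 2 * (1:20), x = 1:20)
  res <- ols_with_interaction(tab, "y", "x", interaction = NULL)
  expect_equal(res$B[res$term == "x"], 2, tolerance = 1e-12)
  expect_equal(res$Beta[res$term == "x"], 1, tolerance = 1e-12)
  expect_lt(attr(res, "sigma"), 1e-10)
  # t = B / SE and two-sided p hold row-wise on a stochastic fit
  coh <- simulate_cohort(cohort_spec(seed = 21))
  rt <- ols_with_interaction(coh, "alps_true",
                             c("ahi", "age", "sex", "se", "plmi", "group"),
                             interaction = c("ahi", "group"))
  expect_equal(rt$t, rt$B / rt$SE, tolerance = 1e-9)
  expect_true(all(rt$p >= 0 & rt$p <= 1))
  expect_true("ahi:group" %in% rt$term)
  # cross-check against lm() as an independent route
  dat <- glymphalps:::recode_binary(coh)
  ref <- lm(alps_true ~ ahi + age + sex + se + plmi + group + ahi:group,
            data = dat)
  expect_equal(rt$B, unname(coef(ref)), tolerance = 1e-9)
  expect_equal(rt$SE, unname(coef(summary(ref))[, 2]), tolerance = 1e-9)
})

test_that("single-group interaction designs are rejected as singular", {
  coh <- simulate_cohort(cohort_spec(seed = 2))
  pd <- coh[coh$group == "PD", ]
  expect_error(
    ols_with_interaction(pd, "alps_true", c("ahi", "age", "group"),
                         interaction = c("ahi", "group")),
    "singular|constant")
})

test_that("the interaction coefficient recovers the planted effect size", {
  hits <- 0L
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    coh <- simulate_cohort(cohort_spec(seed = 4000 + s))
    rt <- ols_with_interaction(coh, "alps_true",
                               c("ahi", "age", "sex", "se", "plmi", "group"),
                               interaction = c("ahi", "group"))
    b <- rt$B[rt$term == "ahi:group"]
    if (b < 0 && abs(b - (-0.004)) <= 0.3 * 0.004) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.5)
  bs <- vapply(1:60, function(s) {
    coh <- simulate_cohort(cohort_spec(seed = 7000 + s))
    rt <- ols_with_interaction(coh, "alps_true",
                               c("ahi", "age", "sex", "se", "plmi", "group"),
                               interaction = c("ahi", "group"))
    rt$B[rt$term == "ahi:group"]
  }, 0)
  expect_lt(abs(mean(bs) - (-0.004)), 0.001)
})

test_that("monte_carlo_p_interval is seeded, bounded, and degenerates to 1", {
  a <- rnorm(20, 0); b <- rnorm(20, 5)   # clearly separated
  r1 <- monte_carlo_p_interval(a, b, n_permutations = 2000, seed = 4)
  r2 <- monte_carlo_p_interval(a, b, n_permutations = 2000, seed = 4)
  expect_identical(r1, r2)
  expect_lte(r1$p, 0.001)
  expect_true(r1$interval[1] >= 0 && r1$interval[2] <= 1)
  # constant statistic: every permutation ties the observed value
  rc <- monte_carlo_p_interval(rep(1, 5), rep(1, 5),
                               n_permutations = 200, seed = 1)
  expect_equal(rc$p, 1)
  expect_equal(rc$interval[2], 1)
  expect_error(monte_carlo_p_interval(a, b, n_permutations = 50), "100")
})
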