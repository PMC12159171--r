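test_that("group comparisons cover the cohort variables with Bonferroni flags", {
  coh <- simulate_cohort(cohort_spec(seed = 14))
  res <- run_group_comparisons(coh)
  expect_s3_class(res, "group_comparisons")
  expect_true(all(c("age", "bmi", "ahi", "odi", "n1", "arousal_index",
                    "alps_true") %in% res$variable))
  expect_true(all(res$p >= 0 & res$p <= 1))
  n1n2 <- sum(coh$group == "PD") * sum(coh$group == "control")
  expect_true(all(res$U >= 0 & res$U <= n1n2))
  expect_equal(attr(res, "family_m"), nrow(res))
})

test_that("the sex split uses an exact 2x2 test matching an enumeration oracle", {
  # counts mirroring a published F/M split of 17/37 vs 10/22
  sex <- c(rep("F", 17), rep("M", 37), rep("F", 10), rep("M", 22))
  grp <- c(rep("PD", 54), rep("control", 32))
  coh <- simulate_cohort(cohort_spec(seed = 1))
  coh$sex <- factor(sex, levels = c("F", "M"))
  coh$group <- factor(grp, levels = c("control", "PD"))
  res <- run_group_comparisons(coh)
  p_pkg <- attr(res, "sex")$p
  # hypergeometric enumeration: sum of table probabilities <= observed
  x_obs <- 17; m <- 27; n <- 59; k <- 54   # F total, M total, PD draws
  probs <- dhyper(max(0, k - n):min(k, m), m, n, k)
  p_oracle <- sum(probs[probs <= dhyper(x_obs, m, n, k) * (1 + 1e-7)])
  expect_equal(p_pkg, p_oracle, tolerance = 1e-9)
  expect_equal(p_pkg, 1, tolerance = 1e-3)
})

test_that("an extreme group separation is flagged significant", {
  coh <- simulate_cohort(cohort_spec(seed = 8))
  coh$alps_true[coh$group == "PD"] <-
    coh$alps_true[coh$group == "PD"] + 10 * sd(coh$alps_true)
  res <- run_group_comparisons(coh)
  expect_true(res$bonferroni[res$variable == "alps_true"])
})

test_that("the correlation battery has the Table-2 shape", {
  coh <- simulate_cohort(cohort_spec(seed = 20))
  res <- run_correlation_battery(coh, family_m = 14)
  expect_equal(nrow(res), 28)                       # 14 variables x 2 groups
  expect_setequal(unique(res$group), c("PD", "control"))
  expect_equal(sum(res$group == "PD"), 14)
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  expect_true(all(res$ci_lo <= res$rho & res$rho <= res$ci_hi))
  # single-group mode keeps all 14 without a split
  single <- run_correlation_battery(coh[coh$group == "PD", ],
                                    per_group = FALSE, family_m = 14)
  expect_equal(nrow(single), 14)
  expect_true(all(single$group == "all"))
})

test_that("a constant target flags every correlation undefined", {
  coh <- simulate_cohort(cohort_spec(seed = 2))
  coh$alps_true <- 1.3
  res <- run_correlation_battery(coh, target = "alps_true", family_m = 14)
  expect_true(all(res$undefined))
  expect_false(any(res$bonferroni))
})

test_that("inert comorbidity flags leave the AHI coefficient unchanged", {
  coh <- simulate_cohort(cohort_spec(seed = 33))
  coh$rbd <- 0L; coh$rls <- 0L; coh$plms <- 0L
  expect_warning(adj <- run_confounder_adjustment(coh), "dropped")
  simple <- ols_with_interaction(coh[coh$group == "PD", ], "alps_true",
                                 "ahi", interaction = NULL)
  expect_equal(adj$B[adj$term == "ahi"], simple$B[simple$term == "ahi"],
               tolerance = 1e-9)
  expect_setequal(attr(adj, "dropped_confounders"), c("rbd", "rls", "plms"))
})

test_that("planted confounding attenuates the adjusted AHI coefficient", {
  # RBD both raises AHI and lowers ALPS; adjusting for it should pull the
  # AHI coefficient toward zero relative to the unadjusted fit
  deltas <- vapply(1:30, function(s) {
    coh <- simulate_cohort(cohort_spec(seed = 900 + s, beta_ahi_pd = 0))
    pd_idx <- which(coh$group == "PD")
    rbd <- rbinom(length(pd_idx), 1, 0.4)
    coh$rbd <- 0L; coh$rbd[pd_idx] <- rbd
    coh$ahi[pd_idx] <- coh$ahi[pd_idx] + 25 * rbd
    coh$alps_true[pd_idx] <- coh$alps_true[pd_idx] - 0.15 * rbd
    adj <- suppressWarnings(run_confounder_adjustment(coh))
    un <- ols_with_interaction(coh[pd_idx, ], "alps_true", "ahi",
                               interaction = NULL)
    abs(un$B[un$term == "ahi"]) - abs(adj$B[adj$term == "ahi"])
  }, 0)
  expect_gt(mean(deltas > 0), 0.8)
})

test_that("the full cohort report reproduces the planted group pattern", {
  hits_pd <- hits_ctrl <- 0L
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    coh <- simulate_cohort(cohort_spec(seed = 1200 + s))
    an <- suppressWarnings(run_cohort_analysis(coh))
    pd <- an$posthoc$PD; ct <- an$posthoc$control
    if (pd$p[pd$term == "ahi"] < 0.05 && pd$B[pd$term == "ahi"] < 0)
      hits_pd <- hits_pd + 1L
    if (ct$p[ct$term == "ahi"] >= 0.05) hits_ctrl <- hits_ctrl + 1L
  }
  # AHI term significant in the patient subset in the majority of runs,
  # and not significant in controls in most runs
  expect_gt(hits_pd / n_rep, 0.5)
  expect_gt(hits_ctrl / n_rep, 0.8)
})

test_that("requesting comparisons on a single-group table errors", {
  coh <- simulate_cohort(cohort_spec(seed = 4))
  expect_error(run_group_comparisons(coh[coh$group == "PD", ]), "both groups")
})

test_that("type-I error is controlled on a fully null cohort", {
  # fully null: no effect of anything on ALPS; raw two-sided tests should
  # reject at 5% (binomial 99% band) and the Bonferroni-corrected battery
  # should flag a family at most at the corrected level (99% band of 5%)
  tpl <- cohort_spec(beta_ahi_pd = 0, beta_age = 0, beta_sex = 0)
  n_rep <- 400
  raw <- matrix(NA, n_rep, 14)
  fam <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    ns <- tpl; ns$seed <- as.integer(s + 50000L)
    coh <- simulate_cohort(ns)
    cb <- run_correlation_battery(coh, target = "alps_true", family_m = 14)
    pd <- cb[cb$group == "PD", ]
    raw[s, ] <- pd$p <= 0.05
    fam[s] <- any(pd$bonferroni)
  }
  n_draws <- length(raw)
  band <- qbinom(c(0.005, 0.995), n_draws, 0.05) / n_draws
  expect_gte(mean(raw), band[1])
  expect_lte(mean(raw), band[2])
  expect_lte(sum(fam), qbinom(0.995, n_rep, 0.05))
})
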