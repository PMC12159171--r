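#' Specification of a simulated sleep-apnea / Parkinson cohort
#'
#' Describes a two-group cohort (de novo Parkinson's disease patients and
#' controls) with demographic and polysomnographic covariates and a ground
#' truth ALPS index generated as
#' `alps = baseline + beta_age * age + beta_sex * male +
#' beta_ahi_pd * AHI * [PD] + N(0, residual_sd)`,
#' i.e. a negative ALPS-AHI coupling present only in the patient group.  The
#' defaults emulate a published 54-patient / 32-control cohort: ages around
#' 59 years, right-skewed AHI with mean 16-18 and SD 16-20 events/h, and
#' effect sizes taken from that cohort's interaction regression (AHI-by-group
#' term -0.004 ALPS units per event/h).  With these defaults the population
#' Spearman correlation between ALPS and AHI within the patient group is
#' approximately -0.4.
#'
#' @param n_pd,n_control Group sizes.
#' @param age_mean,age_sd Per-group age parameters, years; order (PD, control).
#' @param male_fraction Per-group fraction of male subjects.
#' @param ahi_mean,ahi_sd Per-group AHI marginals (events/h); simulated as a
#'   gamma distribution matched to mean/SD and clipped at `ahi_max`.
#' @param ahi_max Upper clip for simulated AHI.
#' @param beta_ahi_pd ALPS change per AHI event/h, patients only.
#' @param beta_age ALPS change per year of age (both groups).
#' @param beta_sex ALPS difference for male versus female subjects.
#' @param baseline_alps Intercept of the ALPS model.
#' @param residual_sd SD of the ALPS residual.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return Validated object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_pd = 54L, n_control = 32L,
                        age_mean = c(58.9, 59.4), age_sd = c(12.2, 8.3),
                        male_fraction = c(37 / 54, 22 / 32),
                        ahi_mean = c(16.0, 18.5), ahi_sd = c(19.9, 15.8),
                        ahi_max = 120,
                        beta_ahi_pd = -0.004,
                        beta_age = -0.005,
                        beta_sex = -0.116,
                        baseline_alps = 1.72,
                        residual_sd = 0.105,
                        seed = 1L) {
  spec <- structure(list(
    n_pd = as.integer(n_pd), n_control = as.integer(n_control),
    age_mean = age_mean, age_sd = age_sd, male_fraction = male_fraction,
    ahi_mean = ahi_mean, ahi_sd = ahi_sd, ahi_max = ahi_max,
    beta_ahi_pd = beta_ahi_pd, beta_age = beta_age, beta_sex = beta_sex,
    baseline_alps = baseline_alps, residual_sd = residual_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_pd < 1 || spec$n_control < 1) stopf("group sizes must be positive")
  if (spec$residual_sd < 0) stopf("residual_sd must be >= 0")
  if (any(spec$age_sd < 0) || any(spec$ahi_sd < 0)) stopf("SDs must be >= 0")
  if (any(spec$ahi_mean < 0)) stopf("AHI means must be >= 0")
  if (any(spec$male_fraction < 0 | spec$male_fraction > 1))
    stopf("male_fraction must be in [0, 1]")
  if (spec$baseline_alps <= 0) stopf("baseline_alps must be positive")
  spec
}

# Polysomnographic marginals (mean, sd) per group, order (PD, control),
# and latent Gaussian-copula correlations to AHI for the coupled variables.
psg_marginals <- function() {
  list(
    bmi     = list(mean = c(27.5, 27.6), sd = c(3.7, 4.0), dist = "normal", lo = 15, hi = 50),
    tst     = list(mean = c(334.4, 332.1), sd = c(60, 72.3), dist = "normal", lo = 120, hi = 470),
    sl      = list(mean = c(25.9, 13.9), sd = c(37.3, 13.0), dist = "gamma"),
    wake    = list(mean = c(30.0, 22.7), sd = c(20.4, 13.8), dist = "gamma"),
    n1      = list(mean = c(7.9, 8.6), sd = c(5.1, 4.0), dist = "gamma"),
    n2      = list(mean = c(33.1, 35.3), sd = c(12.6, 9.9), dist = "normal", lo = 5, hi = 70),
    n3      = list(mean = c(16.7, 17.4), sd = c(9.8, 7.1), dist = "gamma"),
    r       = list(mean = c(12.2, 16.0), sd = c(7.9, 7.0), dist = "gamma"),
    odi     = list(mean = c(14.2, 13.9), sd = c(17.1, 11.4), dist = "gamma"),
    arousal_index = list(mean = c(8.1, 16.6), sd = c(7.2, 7.5), dist = "gamma"),
    plmi    = list(mean = c(8.9, 10.6), sd = c(19.5, 23.0), dist = "gamma")
  )
}

# Latent copula correlations with AHI (package choices; the source cohort
# reports only marginal summaries).
psg_copula_rho <- c(odi = 0.85, n1 = 0.35, arousal_index = 0.25)

# Comorbidity prevalences among patients (fractions of the PD group).
comorbidity_prev <- c(rbd = 8 / 54, rls = 1 / 54, plms = 10 / 54)

qdist <- function(u, mean, sd, dist, lo = -Inf, hi = Inf) {
  x <- if (dist == "gamma") {
    if (mean <= 0 || sd == 0) rep(mean, length(u))
    else stats::qgamma(u, shape = (mean / sd)^2, scale = sd^2 / mean)
  } else {
    stats::qnorm(u, mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Simulate a cohort table
#'
#' Draws a per-subject table from a [cohort_spec()]: age, sex and group; AHI
#' from a clipped gamma distribution matched to the per-group mean/SD; ODI,
#' sleep stage N1 and arousal index tied to AHI through a Gaussian copula
#' with fixed latent correlations; remaining polysomnographic variables from
#' independent marginals; sleep-stage percentages (wake, N1, N2, N3, R)
#' rescaled to sum to exactly 100 with N1 kept as drawn; comorbidity flags
#' (RBD, RLS, PLMS) as independent Bernoulli draws among patients; and the
#' ground-truth ALPS index from the linear model described in
#' [cohort_spec()].
#'
#' @param spec A `cohort_spec`.
#' @param phantom_specs If `TRUE`, attach (as attribute `"phantom_specs"`) one
#'   [phantom_spec()] per subject whose perivascular boost reproduces the
#'   subject's ALPS under the noiseless forward model
#'   (`g = base * (alps - 1)`).
#' @return A `data.frame` (classed `cohort_table`) with columns `subject_id`,
#'   `group` (`"PD"`/`"control"`), `age`, `sex` (`"F"`/`"M"`), `bmi`, `ahi`,
#'   `odi`, `plmi`, `arousal_index`, `tst`, `sl`, `se`, `wake`, `n1`, `n2`,
#'   `n3`, `r`, `alps_true`, `rbd`, `rls`, `plms`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(seed = 42))
#' table(coh$group)
#' @export
simulate_cohort <- function(spec, phantom_specs = FALSE) {
  spec <- validate_cohort_spec(spec)
  n <- spec$n_pd + spec$n_control
  grp_i <- c(rep(1L, spec$n_pd), rep(2L, spec$n_control)) # 1 = PD, 2 = control
  marg <- psg_marginals()
  tab <- with_seed(spec$seed, {
    age <- pmin(pmax(stats::rnorm(n, spec$age_mean[grp_i], spec$age_sd[grp_i]), 25), 90)
    male <- stats::rbinom(n, 1, spec$male_fraction[grp_i])

    # Gaussian copula across (AHI, ODI, N1, arousal index)
    rho <- psg_copula_rho
    cm <- diag(4)
    cm[1, 2:4] <- cm[2:4, 1] <- rho
    L <- chol(cm)
    z <- matrix(stats::rnorm(n * 4), n, 4) %*% L
    u <- stats::pnorm(z)
    ahi <- vapply(seq_len(n), function(i)
      qdist(u[i, 1], spec$ahi_mean[grp_i[i]], spec$ahi_sd[grp_i[i]], "gamma",
            lo = 0, hi = spec$ahi_max), 0)
    draw_marg <- function(u, nm)
      vapply(seq_len(n), function(i)
        qdist(u[i], marg[[nm]]$mean[grp_i[i]], marg[[nm]]$sd[grp_i[i]],
              marg[[nm]]$dist,
              lo = if (is.null(marg[[nm]]$lo)) 0 else marg[[nm]]$lo,
              hi = if (is.null(marg[[nm]]$hi)) Inf else marg[[nm]]$hi), 0)
    odi <- draw_marg(u[, 2], "odi")
    n1 <- pmin(draw_marg(u[, 3], "n1"), 60)
    arousal <- draw_marg(u[, 4], "arousal_index")

    indep <- lapply(c("bmi", "tst", "sl", "wake", "n2", "n3", "r", "plmi"),
                    function(nm) draw_marg(stats::runif(n), nm))
    names(indep) <- c("bmi", "tst", "sl", "wake", "n2", "n3", "r", "plmi")

    # stage percentages: keep N1 as drawn, rescale the rest to fill 100%
    rest <- cbind(indep$wake, indep$n2, indep$n3, indep$r)
    rest_sum <- pmax(rowSums(rest), 1e-9)
    rest <- rest * (100 - n1) / rest_sum
    se <- pmin(pmax(100 - rest[, 1] + stats::rnorm(n, 0, 4), 0), 100)

    rbd <- ifelse(grp_i == 1L, stats::rbinom(n, 1, comorbidity_prev["rbd"]), 0L)
    rls <- ifelse(grp_i == 1L, stats::rbinom(n, 1, comorbidity_prev["rls"]), 0L)
    plms <- ifelse(grp_i == 1L, stats::rbinom(n, 1, comorbidity_prev["plms"]), 0L)

    alps <- spec$baseline_alps + spec$beta_age * age + spec$beta_sex * male +
      spec$beta_ahi_pd * ahi * (grp_i == 1L) +
      stats::rnorm(n, 0, spec$residual_sd)
    alps <- pmax(alps, 0.05)

    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = factor(ifelse(grp_i == 1L, "PD", "control"),
                     levels = c("control", "PD")),
      age = age,
      sex = factor(ifelse(male == 1L, "M", "F"), levels = c("F", "M")),
      bmi = indep$bmi,
      ahi = ahi, odi = odi, plmi = indep$plmi, arousal_index = arousal,
      tst = indep$tst, sl = indep$sl, se = se,
      wake = rest[, 1], n1 = n1, n2 = rest[, 2], n3 = rest[, 3], r = rest[, 4],
      alps_true = alps,
      rbd = as.integer(rbd), rls = as.integer(rls), plms = as.integer(plms),
      stringsAsFactors = FALSE
    )
  })
  class(tab) <- c("cohort_table", "data.frame")
  if (phantom_specs) {
    base <- 0.4
    attr(tab, "phantom_specs") <- lapply(seq_len(nrow(tab)), function(i)
      phantom_spec(perivascular_boost = max(base * (tab$alps_true[i] - 1), 0),
                   seed = spec$seed + i))
  }
  tab
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d subjects (%d PD, %d control)\n",
              nrow(x), sum(x$group == "PD"), sum(x$group == "control")))
  NextMethod()
}

#' Read and write cohort CSV files
#'
#' The CSV schema matches the columns produced by [simulate_cohort()]; the
#' comorbidity flags `rbd`, `rls`, `plms` and the `alps_true` column are
#' optional on read (an `alps` column from a computed pipeline is accepted as
#' the index variable too).  `read_cohort_csv()` validates the schema, checks
#' that percentage columns lie in `[0, 100]`, and warns (naming the subject)
#' when the sleep-stage percentages `wake + n1 + n2 + n3 + r` do not sum
#' to 100.
#'
#' @param table A cohort `data.frame`.
#' @param path CSV file path.
#' @param tolerance Allowed deviation of the stage sum from 100.
#' @return `read_cohort_csv()` returns a validated `cohort_table`;
#'   `write_cohort_csv()` the path, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, tolerance = 1e-6) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "bmi", "ahi", "odi",
                "plmi", "arousal_index", "tst", "sl", "se", "wake", "n1",
                "n2", "n3", "r")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stopf("cohort CSV is missing required column(s): %s",
          paste(missing, collapse = ", "))
  if (!any(c("alps_true", "alps") %in% names(tab)))
    stopf("cohort CSV must contain an 'alps' or 'alps_true' column")
  tab$group <- factor(tab$group, levels = c("control", "PD"))
  if (any(is.na(tab$group)))
    stopf("column 'group' must contain only 'PD' and 'control'")
  tab$sex <- factor(tab$sex, levels = c("F", "M"))
  pct <- c("se", "wake", "n1", "n2", "n3", "r")
  for (nm in pct) {
    bad <- which(tab[[nm]] < 0 | tab[[nm]] > 100)
    if (length(bad))
      stopf("column '%s' outside [0, 100] for subject %s", nm,
            tab$subject_id[bad[1]])
  }
  ssum <- rowSums(tab[, c("wake", "n1", "n2", "n3", "r")])
  off <- which(abs(ssum - 100) > tolerance)
  if (length(off))
    warnf("sleep-stage percentages do not sum to 100 for subject(s): %s",
          paste(utils::head(tab$subject_id[off], 5), collapse = ", "))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
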