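# Variables entering the correlation battery against the ALPS index: the 14
# demographic and polysomnographic measures reported per group.
correlation_variables <- function(table) {
  cand <- c("age", "bmi", "updrs", "tst", "sl", "se", "wake", "n1", "n2",
            "n3", "r", "ahi", "odi", "plmi", "arousal_index")
  intersect(cand, names(table))
}

comparison_variables <- function(table) {
  cand <- c("age", "bmi", "alps", "alps_true", "tst", "sl", "se", "wake",
            "n1", "n2", "n3", "r", "ahi", "odi", "plmi", "arousal_index")
  intersect(cand, names(table))
}

# Resolve which column carries the ALPS index.
alps_column <- function(table, target = NULL) {
  if (!is.null(target)) {
    if (!target %in% names(table)) stopf("column '%s' not found", target)
    return(target)
  }
  for (nm in c("alps", "alps_true")) if (nm %in% names(table)) return(nm)
  stopf("cohort table has no 'alps' or 'alps_true' column")
}

#' Group comparison battery
#'
#' Compares every continuous demographic/polysomnographic variable (and the
#' ALPS index) between patients and controls with [mann_whitney()], compares
#' the sex split with a two-sided exact test on the 2x2 table
#' ([stats::fisher.test()]), and flags Bonferroni-significant results over
#' the family of continuous comparisons.
#'
#' @param table A cohort `data.frame` with both group levels present.
#' @param family_m Bonferroni family size; defaults to the number of
#'   continuous comparisons performed.
#' @param alpha Familywise error level.
#' @param mc_permutations If positive, additionally report a Monte-Carlo
#'   permutation p with a 99% Clopper-Pearson interval per variable
#'   ([monte_carlo_p_interval()]).
#' @param seed Seed for the Monte-Carlo p-values.
#' @return Object of class `group_comparisons`: a data frame with one row
#'   per variable (group means/SDs, U, p, optional Monte-Carlo p and
#'   interval, Bonferroni flag) plus a `sex` attribute holding the 2x2 exact
#'   test result.
#' @export
run_group_comparisons <- function(table, family_m = NULL, alpha = 0.05,
                                  mc_permutations = 0, seed = 1) {
  grp <- table$group
  if (length(unique(grp[!is.na(grp)])) < 2)
    stopf("both groups must be present for comparisons")
  pd <- table[grp == "PD", , drop = FALSE]
  ctrl <- table[grp == "control", , drop = FALSE]
  vars <- comparison_variables(table)
  rows <- lapply(vars, function(v) {
    cmp <- mann_whitney(pd[[v]], ctrl[[v]])
    row <- data.frame(variable = v,
                      mean_pd = cmp$mean[1], sd_pd = cmp$sd[1],
                      mean_control = cmp$mean[2], sd_control = cmp$sd[2],
                      U = cmp$U, p = cmp$p, mode = cmp$mode)
    if (mc_permutations > 0) {
      mc <- monte_carlo_p_interval(
        pd[[v]][is.finite(pd[[v]])], ctrl[[v]][is.finite(ctrl[[v]])],
        statistic = function(a, b) mean(a) - mean(b),
        n_permutations = mc_permutations, seed = seed)
      row$mc_p <- mc$p; row$mc_lo <- mc$interval[1]; row$mc_hi <- mc$interval[2]
    }
    row
  })
  out <- do.call(rbind, rows)
  m <- if (is.null(family_m)) nrow(out) else family_m
  out$bonferroni <- bonferroni_flags(out$p, m = m, alpha = alpha)
  sex_tab <- table(factor(table$sex, levels = c("F", "M")),
                   factor(table$group, levels = c("PD", "control")))
  sex <- stats::fisher.test(sex_tab, alternative = "two.sided")
  structure(out, class = c("group_comparisons", "data.frame"),
            sex = list(table = sex_tab, p = sex$p.value),
            family_m = m, alpha = alpha)
}

#' @export
print.group_comparisons <- function(x, ...) {
  cat(sprintf("Group comparisons (Mann-Whitney, Bonferroni m = %d):\n",
              attr(x, "family_m")))
  df <- as.data.frame(x)
  df$p <- sprintf("%.4g", df$p)
  print(df[, c("variable", "mean_pd", "sd_pd", "mean_control", "sd_control",
               "U", "p", "bonferroni")], row.names = FALSE, digits = 3)
  sx <- attr(x, "sex")
  cat(sprintf("Sex (F/M) exact test: p = %.4g\n", sx$p))
  invisible(x)
}

#' Correlation battery of the ALPS index against cohort variables
#'
#' Spearman correlations ([spearman_ci()]) of the ALPS index against each of
#' the demographic/polysomnographic variables, within each group separately
#' (or pooled with `per_group = FALSE`), with Bonferroni flags over the
#' per-group family.
#'
#' @param table A cohort `data.frame`.
#' @param target Column holding the ALPS index; defaults to `alps` or
#'   `alps_true`, whichever is present.
#' @param per_group Analyze PD and control subjects separately (default).
#' @param family_m Bonferroni family size per group (default 14).
#' @param alpha Familywise error level.
#' @return Object of class `correlation_battery`: data frame with columns
#'   `group`, `variable`, `rho`, `p`, `ci_lo`, `ci_hi`, `n`, `undefined`,
#'   `bonferroni`.
#' @export
run_correlation_battery <- function(table, target = NULL, per_group = TRUE,
                                    family_m = 14, alpha = 0.05) {
  ycol <- alps_column(table, target)
  vars <- setdiff(correlation_variables(table), ycol)
  groups <- if (per_group) c("PD", "control") else "all"
  rows <- list()
  for (g in groups) {
    sub <- if (g == "all") table else table[table$group == g, , drop = FALSE]
    if (nrow(sub) < 4) stopf("fewer than 4 subjects in group '%s'", g)
    for (v in vars) {
      res <- spearman_ci(sub[[ycol]], sub[[v]], alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, rho = res$rho, p = res$p,
        ci_lo = res$ci[1], ci_hi = res$ci[2], n = res$n,
        undefined = res$undefined)
    }
  }
  out <- do.call(rbind, rows)
  out$bonferroni <- FALSE
  for (g in groups) {
    sel <- out$group == g
    out$bonferroni[sel] <- bonferroni_flags(out$p[sel], m = family_m,
                                            alpha = alpha)
  }
  structure(out, class = c("correlation_battery", "data.frame"),
            target = ycol, family_m = family_m, alpha = alpha)
}

#' @export
print.correlation_battery <- function(x, ...) {
  cat(sprintf("Spearman correlations of %s (Bonferroni m = %d per group):\n",
              attr(x, "target"), attr(x, "family_m")))
  df <- as.data.frame(x)
  df$rho <- sprintf("%.3f", df$rho)
  df$p <- sprintf("%.4g", df$p)
  df$ci <- sprintf("%.3f to %.3f", df$ci_lo, df$ci_hi)
  print(df[, c("group", "variable", "rho", "p", "ci", "n", "bonferroni")],
        row.names = FALSE)
  invisible(x)
}

#' Comorbidity-adjusted regression of the ALPS index on AHI
#'
#' Within the patient subset, regresses the ALPS index on AHI plus binary
#' sleep-comorbidity flags (REM-sleep behavior disorder, restless legs
#' syndrome, periodic limb movements in sleep) to check whether the ALPS-AHI
#' association survives adjustment.  Flags with zero variance in the subset
#' (e.g. no affected subjects) are dropped from the design and listed in the
#' result.
#'
#' @param table A cohort `data.frame` containing the flag columns.
#' @param dependent ALPS column; defaults as in [run_correlation_battery()].
#' @param exposure Exposure column (default `"ahi"`).
#' @param confounders Flag columns (default `c("rbd", "rls", "plms")`).
#' @param group Subset analyzed (default `"PD"`).
#' @return A [ols_with_interaction()]-style `regression_table` with an
#'   additional attribute `dropped_confounders`.
#' @export
run_confounder_adjustment <- function(table, dependent = NULL,
                                      exposure = "ahi",
                                      confounders = c("rbd", "rls", "plms"),
                                      group = "PD") {
  ycol <- alps_column(table, dependent)
  sub <- table[table$group == group, , drop = FALSE]
  miss <- setdiff(c(exposure, confounders), names(sub))
  if (length(miss))
    stopf("missing column(s): %s", paste(miss, collapse = ", "))
  keep <- confounders[vapply(confounders, function(v)
    stats::sd(sub[[v]], na.rm = TRUE) > 0, logical(1))]
  dropped <- setdiff(confounders, keep)
  if (length(dropped))
    warnf("constant confounder flag(s) dropped: %s", paste(dropped, collapse = ", "))
  out <- ols_with_interaction(sub, ycol, c(exposure, keep), interaction = NULL)
  attr(out, "dropped_confounders") <- dropped
  out
}

#' Full cohort statistical report
#'
#' Runs the complete statistical battery on a cohort table: group
#' comparisons, per-group Spearman correlations of the ALPS index, the
#' multivariable regression with an AHI-by-group interaction, post-hoc
#' per-group regressions, and (when comorbidity flags are present) the
#' comorbidity-adjusted patient regression.
#'
#' @param table A cohort `data.frame` (see [simulate_cohort()] /
#'   [read_cohort_csv()]).
#' @param target ALPS column; defaults to `alps` or `alps_true`.
#' @param family_m Bonferroni family size for the correlation battery.
#' @param regression_terms Terms of the interaction regression besides the
#'   interaction itself.
#' @param mc_permutations Monte-Carlo permutations for comparison p-value
#'   intervals (0 disables).
#' @param seed Seed for Monte-Carlo p-values.
#' @return Object of class `cohort_analysis`: list with `comparisons`,
#'   `correlations`, `interaction_model`, `posthoc` (per-group regression
#'   tables), and `confounders` (or `NULL`).
#' @export
run_cohort_analysis <- function(table, target = NULL, family_m = 14,
                                regression_terms = c("ahi", "age", "sex",
                                                     "se", "plmi", "group"),
                                mc_permutations = 0, seed = 1) {
  ycol <- alps_column(table, target)
  comparisons <- run_group_comparisons(table, mc_permutations = mc_permutations,
                                       seed = seed)
  correlations <- run_correlation_battery(table, target = ycol,
                                          family_m = family_m)
  interaction_model <- ols_with_interaction(table, ycol, regression_terms,
                                            interaction = c("ahi", "group"))
  posthoc_terms <- setdiff(regression_terms, "group")
  posthoc <- lapply(c(PD = "PD", control = "control"), function(g)
    ols_with_interaction(table[table$group == g, , drop = FALSE], ycol,
                         posthoc_terms, interaction = NULL))
  confounders <- NULL
  if (all(c("rbd", "rls", "plms") %in% names(table))) {
    confounders <- tryCatch(
      suppressWarnings(run_confounder_adjustment(table, dependent = ycol)),
      error = function(e) NULL)
  }
  structure(list(comparisons = comparisons, correlations = correlations,
                 interaction_model = interaction_model, posthoc = posthoc,
                 confounders = confounders),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  print(x$comparisons); cat("\n")
  print(x$correlations); cat("\n")
  cat("Interaction model:\n"); print(x$interaction_model); cat("\n")
  cat("Post-hoc, PD:\n"); print(x$posthoc$PD); cat("\n")
  cat("Post-hoc, controls:\n"); print(x$posthoc$control)
  if (!is.null(x$confounders)) {
    cat("\nComorbidity-adjusted (PD):\n"); print(x$confounders)
  }
  invisible(x)
}
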