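#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of two independent samples.  For small tie-free
#' problems (`n1 + n2 <= 12`, no tied values) the p-value is computed by
#' complete enumeration of all rank assignments; otherwise the normal
#' approximation with tie correction and continuity correction is used.  The
#' mode actually used is recorded in the result.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param exact_limit Largest pooled sample size for which enumeration is
#'   attempted.
#' @return Object of class `comparison_result`: list with per-sample `n`,
#'   `mean`, `sd`, the `U` statistic of sample `a`, two-sided `p`, and
#'   `mode` (`"exact"`, `"approximate"` or `"degenerate"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p # exact: 1/3
#' @export
mann_whitney <- function(a, b, exact_limit = 12L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stopf("both samples must contain at least one value")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1L) {
    warnf("all pooled values identical; Mann-Whitney p set to 1")
    p <- 1; mode <- "degenerate"
  } else if (!has_ties && n1 + n2 <= exact_limit) {
    p <- mw_exact_p(U, n1, n2)
    mode <- "exact"
  } else {
    p <- mw_approx_p(U, r, n1, n2)
    mode <- "approximate"
  }
  structure(list(
    n = c(n1, n2), mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
    U = U, p = p, mode = mode
  ), class = "comparison_result")
}

# Exact two-sided p by enumerating every assignment of pooled ranks to the
# first sample: P(|U* - n1 n2 / 2| >= |U - n1 n2 / 2|).
mw_exact_p <- function(U, n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(seq_len(n)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
}

# Normal approximation with tie correction and continuity correction.
mw_approx_p <- function(U, pooled_ranks, n1, n2) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled_ranks)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  2 * stats::pnorm(-z)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d/%d), two-sided p = %.4g [%s]\n",
              x$U, x$n[1], x$n[2], x$p, x$mode))
  invisible(x)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Computes rho as the Pearson correlation of average ranks, a two-sided
#' p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' and a confidence interval from the Fisher z transform
#' `tanh(atanh(rho) +/- z / sqrt(n - 3))`.  Non-finite pairs are dropped
#' (pairwise deletion) and the retained `n` is reported.
#'
#' @param x,y Numeric vectors of equal length.
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @return Object of class `correlation_result`: list with `rho`, `p`,
#'   `ci` (length 2), `n`, and `undefined` (TRUE when either ranked variable
#'   has zero variance, in which case rho and p are `NA`).
#' @examples
#' spearman_ci(1:4, c(2, 4, 6, 8))$rho # 1
#' @export
spearman_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stopf("need at least 4 complete pairs (got %d)", n)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(structure(list(rho = NA_real_, p = NA_real_,
                          ci = c(NA_real_, NA_real_), n = n,
                          undefined = TRUE), class = "correlation_result"))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  zq <- stats::qnorm(1 - alpha / 2)
  zr <- atanh(max(min(rho, 1 - 1e-15), -1 + 1e-15))
  ci <- tanh(zr + c(-1, 1) * zq / sqrt(n - 3))
  if (abs(rho) == 1) ci[if (rho > 0) 2 else 1] <- rho
  structure(list(rho = rho, p = p, ci = ci, n = n, undefined = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (isTRUE(x$undefined)) cat("Spearman rho undefined (zero rank variance)\n")
  else cat(sprintf("Spearman rho = %.3f (n = %d), p = %.4g, 95%% CI %.3f to %.3f\n",
                   x$rho, x$n, x$p, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Bonferroni familywise significance flags
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size; defaults to `length(p_values)` and may be larger
#'   when the supplied p-values are a subset of the family.
#' @param alpha Familywise error level.
#' @return Logical vector: `p <= alpha / m` per entry (`NA` p gives `FALSE`).
#' @export
bonferroni_flags <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (!is.numeric(m) || length(m) != 1 || m <= 0)
    stopf("family size m must be a positive number")
  if (m < length(p_values))
    warnf("family size m (%g) smaller than the number of p-values (%d)",
          m, length(p_values))
  out <- p_values <= alpha / m
  out[is.na(out)] <- FALSE
  out
}

#' Ordinary least squares with a group-by-exposure interaction
#'
#' Fits `dependent ~ intercept + terms + exposure:group` by OLS on a cohort
#' table.  The group factor is coded PD = 1 / control = 0 and sex
#' male = 1 / female = 0 (the coding is recorded in the output, since
#' coefficient signs are only interpretable jointly with it).  The
#' interaction column is `exposure * group_indicator`.  For each coefficient
#' the unstandardized estimate B, its standard error, the standardized
#' coefficient `Beta = B * sd(x) / sd(y)`, `t = B / SE` and the two-sided
#' p-value on the residual degrees of freedom are reported.
#'
#' @param table A cohort `data.frame`.
#' @param dependent Name of the dependent variable column.
#' @param terms Character vector of explanatory column names (`"group"` and
#'   `"sex"` are recoded to 0/1 indicators).
#' @param interaction Length-2 character vector `(exposure, group_column)`
#'   naming the interaction, or `NULL` for no interaction term.
#' @return Object of class `regression_table`: data frame with columns
#'   `term`, `B`, `SE`, `Beta`, `t`, `p`; attributes `n`, `dependent`,
#'   `coding`, `sigma` (residual SE) and `r_squared`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(seed = 3))
#' ols_with_interaction(coh, "alps_true",
#'                      c("ahi", "age", "sex", "group"),
#'                      interaction = c("ahi", "group"))
#' @export
ols_with_interaction <- function(table, dependent, terms,
                                 interaction = c("ahi", "group")) {
  dat <- recode_binary(table)
  miss <- setdiff(c(dependent, terms, interaction), names(dat))
  if (length(miss))
    stopf("column(s) not found in cohort table: %s", paste(miss, collapse = ", "))
  use <- stats::complete.cases(dat[, unique(c(dependent, terms, interaction))])
  dat <- dat[use, , drop = FALSE]
  y <- dat[[dependent]]
  X <- do.call(cbind, lapply(terms, function(t) dat[[t]]))
  colnames(X) <- terms
  if (!is.null(interaction)) {
    if (length(interaction) != 2) stopf("interaction must name two columns")
    int_col <- dat[[interaction[1]]] * dat[[interaction[2]]]
    int_name <- paste0(interaction[1], ":", interaction[2])
    X <- cbind(X, int_col)
    colnames(X)[ncol(X)] <- int_name
  }
  n <- nrow(X)
  if (n <= ncol(X) + 2)
    stopf("too few complete observations (%d) for %d terms", n, ncol(X))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stopf("singular design: constant column(s) %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  Xfull <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xfull)
  if (qrX$rank < ncol(Xfull)) {
    dropped <- colnames(Xfull)[qrX$pivot[-seq_len(qrX$rank)]]
    stopf("singular design: collinear term(s) %s", paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(Xfull, y)
  df <- n - fit$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- solve(crossprod(Xfull))
  se <- sqrt(diag(XtXinv) * sigma2)
  B <- fit$coefficients
  tval <- B / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  sy <- stats::sd(y)
  beta_std <- c(NA_real_, B[-1] * sds / sy)
  out <- data.frame(term = names(B), B = unname(B), SE = unname(se),
                    Beta = unname(beta_std), t = unname(tval),
                    p = unname(pval), row.names = NULL)
  structure(out, class = c("regression_table", "data.frame"),
            n = n, dependent = dependent,
            coding = c(group = "PD = 1, control = 0", sex = "M = 1, F = 0"),
            sigma = sqrt(sigma2),
            r_squared = 1 - rss / sum((y - mean(y))^2))
}

# 0/1 indicator coding for the group and sex columns (coding recorded in
# regression outputs).
recode_binary <- function(table) {
  dat <- as.data.frame(table)
  if ("group" %in% names(dat))
    dat$group <- as.integer(as.character(dat$group) == "PD")
  if ("sex" %in% names(dat))
    dat$sex <- as.integer(as.character(dat$sex) == "M")
  dat
}

#' @export
print.regression_table <- function(x, ...) {
  cat(sprintf("OLS: %s ~ %s (n = %d)\n", attr(x, "dependent"),
              paste(setdiff(x$term, "(Intercept)"), collapse = " + "),
              attr(x, "n")))
  df <- as.data.frame(x)
  df$B <- sprintf("%.4f", df$B); df$SE <- sprintf("%.4f", df$SE)
  df$Beta <- ifelse(is.na(df$Beta), "", sprintf("%.3f", df$Beta))
  df$t <- sprintf("%.3f", df$t); df$p <- sprintf("%.4g", df$p)
  print(df, row.names = FALSE)
  cat(sprintf("Coding: %s\n", paste(attr(x, "coding"), collapse = "; ")))
  invisible(x)
}

#' Monte-Carlo permutation p-value with a Clopper-Pearson interval
#'
#' Estimates a permutation p-value for a two-sample statistic by randomly
#' reallocating the pooled observations to the two groups.  The add-one
#' estimate `(k + 1) / (B + 1)` is reported (where `k` counts permutations
#' with `|T*| >= |T_observed|`), together with a Clopper-Pearson interval for
#' the exceedance proportion.
#'
#' @param a,b The two observed samples.
#' @param statistic Function of two samples returning a scalar; default is
#'   the difference in means.
#' @param n_permutations Number of random permutations (at least 100).
#' @param seed Integer seed.
#' @param level Confidence level of the interval (default 0.99).
#' @return List with `p`, `interval` (length 2), `k`, `n_permutations`,
#'   `observed`.
#' @export
monte_carlo_p_interval <- function(a, b,
                                   statistic = function(a, b) mean(a) - mean(b),
                                   n_permutations = 10000, seed = 1,
                                   level = 0.99) {
  if (n_permutations < 100) stopf("n_permutations must be at least 100")
  obs <- statistic(a, b)
  pooled <- c(a, b)
  n1 <- length(a)
  exceed <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(length(pooled), n1)
      abs(statistic(pooled[idx], pooled[-idx])) >= abs(obs) - 1e-12
    }, logical(1))
  })
  k <- sum(exceed)
  p <- (k + 1) / (n_permutations + 1)
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n_permutations - k + 1)
  hi <- if (k == n_permutations) 1 else
    stats::qbeta(1 - alpha / 2, k + 1, n_permutations - k)
  list(p = p, interval = c(lo, hi), k = k,
       n_permutations = n_permutations, observed = obs)
}
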