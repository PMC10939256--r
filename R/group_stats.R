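# Two-group statistics layer: covariate-adjusted GLM group tests,
# Benjamini-Hochberg FDR, Cohen's d with noncentral-t confidence interval,
# and partial correlations.  Group labels follow the study design: "WT"
# (wild type) vs "ARTE10" (amyloid model).

#' Validate an ROI summary table
#'
#' A per-animal table with one row per animal: `animal_id`, `group`
#' (two levels, reference `"WT"`), numeric measures (AREX values, qT1, MRS
#' concentrations) and covariates (e.g. `roi_volume`, `water_linewidth_hz`).
#'
#' @param table A data.frame.
#' @param group_levels Expected group levels (reference first).
#' @return The table with `group` as a factor (invisibly checked).
#' @export
validate_roi_table <- function(table, group_levels = c("WT", "ARTE10")) {
  stopifnot(is.data.frame(table))
  if (!all(c("animal_id", "group") %in% names(table)))
    stop("table must have animal_id and group columns")
  if (anyDuplicated(table$animal_id)) stop("duplicated animal_id")
  g <- factor(as.character(table$group), levels = group_levels)
  if (any(is.na(g))) stop("unknown group label")
  if (any(table(g) == 0)) stop("both groups must be non-empty")
  table$group <- g
  table
}

#' Covariate-adjusted two-group difference (GLM t-test)
#'
#' Ordinary least squares of the measure on a group indicator plus
#' covariates.  The reported `mean_difference` is the adjusted WT - ARTE10
#' contrast (the negated group coefficient with WT as reference); the t
#' statistic and two-sided p-value test the group coefficient.  With no
#' covariates this is exactly the classical pooled two-sample t-test.
#'
#' @param table ROI table (see [validate_roi_table()]).
#' @param measure Column name of the dependent measure.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return List of class `group_test`: `measure`, `mean_difference`
#'   (WT - ARTE10, adjusted), `t`, `df`, `p`, `n`, plus Cohen's d fields
#'   from [cohens_d_ci()] computed on the raw group values.
#' @export
glm_group_difference <- function(table, measure, covariates = character()) {
  table <- validate_roi_table(table)
  if (!measure %in% names(table)) stop(sprintf("no column '%s'", measure))
  miss <- setdiff(covariates, names(table))
  if (length(miss)) stop(sprintf("missing covariate(s): %s",
                                 paste(miss, collapse = ", ")))
  dat <- table[, c(measure, "group", covariates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (any(table(dat$group) < 1L) || nrow(dat) < 3L)
    stop("need both groups present and >= 3 animals in total")
  fml <- stats::reformulate(c("group", covariates), response = measure)
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("singular design; collinear term(s): %s",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  row <- grep("^group", rownames(sm))[1L]
  a <- dat[[measure]][dat$group == levels(dat$group)[1L]]
  b <- dat[[measure]][dat$group == levels(dat$group)[2L]]
  d <- if (length(a) >= 2L && length(b) >= 2L) cohens_d_ci(a, b)
       else list(d = NA_real_, ci = c(NA_real_, NA_real_))
  structure(list(measure = measure,
                 mean_difference = -sm[row, "Estimate"],
                 t = sm[row, "t value"],
                 df = fit$df.residual,
                 p = sm[row, "Pr(>|t|)"],
                 n = nrow(dat),
                 covariates = covariates,
                 cohens_d = d$d, d_ci = d$ci),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf(
    "%s: adj. mean diff (WT-ARTE10) = %.4g, t(%d) = %.3f, p = %.4g, d = %.3f [%.3f, %.3f]\n",
    x$measure, x$mean_difference, x$df, x$t, x$p,
    x$cohens_d, x$d_ci[1L], x$d_ci[2L]))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in the raw p-values and capped at 1.
#'
#' @param pvalues Numeric vector in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value list")
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Cohen's d with noncentral-t confidence interval
#'
#' Standardized mean difference `(mean(groupB) - mean(groupA)) / pooled SD`;
#' with groupA = WT and groupB = ARTE10 the sign convention is ARTE10 - WT
#' (a measure lower in ARTE10 gives negative d).  The d is bias-uncorrected
#' (not Hedges' g).  The confidence interval inverts the noncentral-t
#' distribution of `t = d / sqrt(1/nA + 1/nB)` with `df = nA + nB - 2`; if
#' the inversion fails numerically a normal-approximation interval
#' `d +/- z * SE(d)` is used.
#'
#' @param groupA,groupB Numeric vectors (>= 2 each).
#' @param conf Confidence level (default 0.95).
#' @return List with `d`, `ci` (length 2), `method` (`"noncentral-t"` or
#'   `"normal-approx"`).
#' @export
#' @examples
#' cohens_d_ci(c(1, 2, 3), c(3, 4, 5))$d   # +2
cohens_d_ci <- function(groupA, groupB, conf = 0.95) {
  groupA <- groupA[is.finite(groupA)]; groupB <- groupB[is.finite(groupB)]
  na <- length(groupA); nb <- length(groupB)
  if (na < 2L || nb < 2L) stop("need >= 2 values per group")
  sp2 <- ((na - 1) * stats::var(groupA) + (nb - 1) * stats::var(groupB)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("pooled SD is zero")
  d <- (mean(groupB) - mean(groupA)) / sqrt(sp2)
  se_factor <- sqrt(1 / na + 1 / nb)
  tobs <- d / se_factor
  df <- na + nb - 2
  alpha <- 1 - conf
  ncp_bound <- function(prob) {
    # ncp such that pt(tobs, df, ncp) == prob
    f <- function(ncp) suppressWarnings(stats::pt(tobs, df, ncp = ncp)) - prob
    lo <- tobs - 10 * (1 + abs(tobs)); hi <- tobs + 10 * (1 + abs(tobs))
    tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-9)$root,
             error = function(e) NA_real_)
  }
  lo <- ncp_bound(1 - alpha / 2)
  hi <- ncp_bound(alpha / 2)
  if (is.na(lo) || is.na(hi)) {
    se_d <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb - 2)))
    z <- stats::qnorm(1 - alpha / 2)
    return(list(d = d, ci = c(d - z * se_d, d + z * se_d),
                method = "normal-approx"))
  }
  list(d = d, ci = sort(c(lo, hi)) * se_factor, method = "noncentral-t")
}

#' Partial correlation
#'
#' Pearson correlation of the OLS residuals of `x` and `y` after regressing
#' each on the covariates (with intercept).  The p-value uses the t
#' distribution with `df = n - 2 - k` for `k` covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix/data.frame of covariates (or `NULL` for
#'   a plain Pearson correlation).
#' @return List with `r`, `p`, `df`, `n`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y length mismatch")
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match x")
    k <- ncol(covariates)
  }
  if (n <= k + 2L) stop("need n > number of covariates + 2")
  if (k > 0L) {
    x <- stats::lm.fit(cbind(1, covariates), x)$residuals
    y <- stats::lm.fit(cbind(1, covariates), y)$residuals
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant residuals; correlation undefined")
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, p = p, df = df, n = n)
}

#' Group comparison table for a set of measures
#'
#' Runs [glm_group_difference()] for every measure, applies BH-FDR across
#' the measures as one family, and returns a table shaped like the study's
#' comparison tables: mean difference (WT - ARTE10), FDR-adjusted p,
#' Cohen's d and its 95% CI.
#'
#' @param table ROI table.
#' @param measures Character vector of measure columns.
#' @param covariates Covariate column names shared by all tests.
#' @param alpha Significance threshold on the FDR-adjusted p.
#' @return data.frame with one row per measure.
#' @export
roi_group_stats <- function(table, measures, covariates = character(),
                            alpha = 0.05) {
  tests <- lapply(measures, function(m)
    glm_group_difference(table, m, covariates))
  p <- vapply(tests, `[[`, numeric(1), "p")
  p_fdr <- bh_fdr(p)
  data.frame(
    measure = measures,
    mean_difference = vapply(tests, `[[`, numeric(1), "mean_difference"),
    t = vapply(tests, `[[`, numeric(1), "t"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p = p, p_fdr = p_fdr,
    cohens_d = vapply(tests, `[[`, numeric(1), "cohens_d"),
    d_ci_low = vapply(tests, function(t) t$d_ci[1L], numeric(1)),
    d_ci_high = vapply(tests, function(t) t$d_ci[2L], numeric(1)),
    significant = p_fdr < alpha,
    row.names = NULL)
}
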