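# Statistics layer: GLM group contrasts, BH-FDR, Cohen's d with CI and
# partial correlations.

mk_table <- function(wt, arte, cov = NULL) {
  n <- length(wt) + length(arte)
  t <- data.frame(animal_id = sprintf("A%02d", seq_len(n)),
                  group = rep(c("WT", "ARTE10"), c(length(wt), length(arte))),
                  y = c(wt, arte))
  if (!is.null(cov)) t$v <- cov
  t
}

# brute-force BH step-up, written from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

test_that("group difference matches hand OLS on a 3-row example", {
  res <- glm_group_difference(mk_table(c(1, 2), 4), "y")
  expect_equal(res$mean_difference, -2.5)
  expect_equal(res$n, 3L)
})

test_that("identical groups give zero difference and p near 1", {
  res <- glm_group_difference(mk_table(c(1, 2, 3), c(1, 2, 3)), "y")
  expect_equal(res$mean_difference, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-9)
})

test_that("a covariate orthogonal to group leaves the difference unchanged", {
  wt <- c(1, 2, 3, 4); arte <- c(3, 4, 5, 6)
  cov <- c(-1, 1, -1, 1, -1, 1, -1, 1)   # balanced across groups
  raw <- glm_group_difference(mk_table(wt, arte), "y")
  adj <- glm_group_difference(mk_table(wt, arte, cov), "y", "v")
  expect_equal(adj$mean_difference, raw$mean_difference, tolerance = 1e-12)
})

test_that("GLM with no covariates reproduces the pooled two-sample t-test", {
  set.seed(8)
  for (i in 1:20) {
    wt <- stats::rnorm(7, 1, 1.5); arte <- stats::rnorm(9, 0.4, 1.5)
    res <- glm_group_difference(mk_table(wt, arte), "y")
    tt <- stats::t.test(wt, arte, var.equal = TRUE)
    expect_equal(abs(res$t), abs(unname(tt$statistic)), tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
    expect_equal(res$mean_difference, mean(wt) - mean(arte),
                 tolerance = 1e-10)
  }
})

test_that("singular designs name the collinear covariate", {
  t <- mk_table(c(1, 2, 3), c(4, 5, 6))
  t$v <- as.numeric(t$group == "WT")   # collinear with group
  expect_error(glm_group_difference(t, "y", "v"), "collinear")
})

test_that("BH-FDR matches the hand example and the brute-force definition", {
  p <- c(0.001, 0.011, 0.013, 0.03, 0.18)
  expect_equal(bh_fdr(p), c(0.005, 0.013 * 5 / 3, 0.013 * 5 / 3, 0.0375,
                            0.18), tolerance = 1e-9)
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  set.seed(9)
  for (i in 1:200) {
    p <- stats::runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("Cohen's d follows the ARTE10-minus-WT convention with sane CI", {
  res <- cohens_d_ci(c(1, 2, 3), c(3, 4, 5))
  expect_equal(res$d, 2)
  expect_lt(res$ci[1], 2); expect_gt(res$ci[2], 2)
  # antisymmetry under label swap
  swap <- cohens_d_ci(c(3, 4, 5), c(1, 2, 3))
  expect_equal(swap$d, -2)
  expect_equal(swap$ci, -rev(res$ci), tolerance = 1e-6)
  # identical groups: d = 0, CI straddles 0
  same <- cohens_d_ci(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(same$d, 0)
  expect_lt(same$ci[1], 0); expect_gt(same$ci[2], 0)
  expect_error(cohens_d_ci(c(1, 1), c(1, 1)), "pooled")
})

test_that("noncentral-t CI covers the true d at about the nominal rate", {
  set.seed(10)
  cover <- replicate(300, {
    wt <- stats::rnorm(10); arte <- stats::rnorm(10, -1.3)
    ci <- cohens_d_ci(wt, arte)$ci
    ci[1] <= -1.3 && -1.3 <= ci[2]
  })
  expect_gt(mean(cover), 0.90)
})

test_that("partial correlation reduces to Pearson and matches the residual oracle", {
  set.seed(11)
  x <- stats::rnorm(20); y <- 0.5 * x + stats::rnorm(20)
  expect_equal(partial_corr(x, y)$r, stats::cor(x, y), tolerance = 1e-12)
  expect_equal(partial_corr(x, x + 0 * x)$r, 1, tolerance = 1e-12)
  # 6-point constructed dataset with one covariate, vs explicit residuals
  x6 <- c(1, 2, 3, 4, 5, 6.5)
  y6 <- c(2.1, 2.9, 4.2, 4.8, 6.1, 7.4)
  v6 <- c(0.3, 0.1, 0.4, 0.2, 0.5, 0.35)
  pc <- partial_corr(x6, y6, v6)
  rx <- stats::resid(stats::lm(x6 ~ v6))
  ry <- stats::resid(stats::lm(y6 ~ v6))
  expect_equal(pc$r, stats::cor(rx, ry), tolerance = 1e-12)
  expect_equal(pc$df, 3L)
  tref <- pc$r * sqrt(3 / (1 - pc$r^2))
  expect_equal(pc$p, 2 * stats::pt(-abs(tref), 3), tolerance = 1e-12)
  expect_error(partial_corr(1:3, 1:3, cbind(1:3, 4:6)), "covariates")
})

test_that("roi_group_stats applies one FDR family across measures", {
  set.seed(12)
  tbl <- make_roi_table(effects_spec(seed = 12))
  out <- roi_group_stats(tbl, c("AREX_Glu", "AREX_PCr", "AREX_Cr", "qT1"),
                         covariates = "roi_volume")
  expect_equal(nrow(out), 4L)
  expect_equal(out$p_fdr, bh_fdr(out$p), tolerance = 1e-12)
  expect_true(all(out$d_ci_low <= out$cohens_d &
                  out$cohens_d <= out$d_ci_high))
  expect_true(all(out$p >= 0 & out$p <= 1))
})

test_that("validate_roi_table rejects malformed tables", {
  t <- data.frame(animal_id = c("a", "a"), group = c("WT", "ARTE10"),
                  y = 1:2)
  expect_error(validate_roi_table(t), "duplicated")
  t2 <- data.frame(animal_id = c("a", "b"), group = c("WT", "XX"), y = 1:2)
  expect_error(validate_roi_table(t2), "group")
})
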