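# WASSR B0 estimation, B0 resampling, double-angle B1 and variable-TR T1.

wassr_dip <- function(center, offs = seq(-1, 1, by = 0.025),
                      depth = 0.8, width = 0.1)
  zspectrum(offs, 1 - depth / (1 + 4 * ((offs - center) / width)^2))

test_that("WASSR locates a symmetric dip at its center", {
  expect_lt(abs(estimate_b0_wassr(wassr_dip(0))), 1e-3)
  expect_equal(estimate_b0_wassr(wassr_dip(0.125)), 0.125,
               tolerance = 5e-3)
  expect_equal(estimate_b0_wassr(wassr_dip(-0.31)), -0.31,
               tolerance = 5e-3)
})

test_that("WASSR dip outside the sampled range is an error", {
  expect_error(estimate_b0_wassr(wassr_dip(1.2)), "boundary|range")
  expect_error(estimate_b0_wassr(zspectrum(seq(-1, 1, 0.5), rep(1, 5))),
               "9")
})

test_that("WASSR recovers simulator-generated shifts", {
  wp <- wassr_protocol()
  zs <- simulate_zspectrum(water_only(), wp, offsets = wp$offsets - 0.125)
  expect_equal(estimate_b0_wassr(zspectrum(wp$offsets, zs$z)), 0.125,
               tolerance = 5e-3)
})

test_that("WASSR shift recovery under Rician noise stays within 0.01 ppm", {
  # condensed version of the 1000-draw acceptance property
  wp <- wassr_protocol()
  base <- simulate_zspectrum(water_only(), wp)$z
  f <- stats::splinefun(wp$offsets, base, method = "monoH.FC")
  set.seed(33)
  errs <- replicate(100, {
    shift <- stats::runif(1, -0.3, 0.3)
    z <- f(wp$offsets - shift)
    z <- add_rician_noise(z, 0.02)  # SNR 50
    est <- tryCatch(estimate_b0_wassr(zspectrum(wp$offsets, z)),
                    error = function(e) NA_real_)
    abs(est - shift)
  })
  expect_gt(mean(errs <= 0.01, na.rm = TRUE), 0.9)
})

test_that("B0 resampling is an identity at zero shift and inverts a known shift", {
  offs <- seq(-8, 8, length.out = 57)
  z <- 1 - 0.8 / (1 + 4 * (offs / 1.4)^2)
  zs <- zspectrum(offs, z)
  expect_equal(apply_b0_shift(zs, 0)$z, z, tolerance = 1e-12)
  # spectrum acquired with a +0.1 ppm water shift: samples of the true
  # spectrum at offs - 0.1
  shifted <- zspectrum(offs, 1 - 0.8 / (1 + 4 * ((offs - 0.1) / 1.4)^2))
  corr <- apply_b0_shift(shifted, 0.1)
  interior <- abs(offs) < 7.5
  expect_lt(max(abs(corr$z - z)[interior], na.rm = TRUE), 5e-3)
})

test_that("B0 resampling never extrapolates and is monotone-consistent", {
  offs <- seq(-2, 2, by = 0.25)
  z <- 1 - 0.9 / (1 + 4 * (offs / 1.2)^2)
  out <- apply_b0_shift(zspectrum(offs, z), 0.4)
  expect_true(any(is.na(out$z)))          # endpoints flagged missing
  # on the monotone flanks the resampled values stay within their
  # bracketing samples (no spline overshoot), even for a shift larger
  # than the grid spacing
  flank <- which(offs >= 0.5 & offs <= 1.25)   # targets 0.9..1.65, rising
  for (i in flank) {
    tgt <- offs[i] + 0.4
    lo <- max(which(offs <= tgt)); hi <- min(which(offs >= tgt))
    expect_gte(out$z[i], min(z[lo], z[hi]) - 1e-12)
    expect_lte(out$z[i], max(z[lo], z[hi]) + 1e-12)
  }
})

test_that("double-angle ratio is exact on sinusoidal signals and scale-invariant", {
  a <- 30
  s1 <- sin(a * pi / 180); s2 <- sin(2 * a * pi / 180)
  expect_equal(estimate_b1_double_angle(s1, s2)$b1_ratio, 1.0,
               tolerance = 1e-12)
  # true flip 1.2x nominal
  s1 <- sin(36 * pi / 180); s2 <- sin(72 * pi / 180)
  expect_equal(estimate_b1_double_angle(s1, s2)$b1_ratio, 1.2,
               tolerance = 1e-12)
  for (c_ in c(0.1, 7, 1234)) {
    expect_equal(estimate_b1_double_angle(c_ * s1, c_ * s2)$b1_ratio, 1.2,
                 tolerance = 1e-12)
  }
})

test_that("double-angle clamps noisy ratios and masks invalid voxels", {
  out <- estimate_b1_double_angle(c(1, 0, 1), c(2.1, 0.5, 0.9))
  expect_true(out$clamped[1])         # 2.1/2 > 1 -> clamped, theta = 0
  expect_equal(out$b1_ratio[1], 0)
  expect_false(out$mask[2])           # img_alpha = 0 -> masked
  expect_true(is.na(out$b1_ratio[2]))
  expect_false(out$clamped[3])
})

test_that("variable-TR fit recovers T1 exactly on noise-free data", {
  tr <- vtr_times()
  ft <- fit_t1_variable_tr(1 - exp(-tr / 2), tr)
  expect_lt(abs(ft$t1 - 2), 1e-6)
  expect_lt(abs(ft$s0 - 1), 1e-6)
  expect_false(ft$at_bound)
  # S0 scale invariance
  ft2 <- fit_t1_variable_tr(123 * (1 - exp(-tr / 2)), tr)
  expect_lt(abs(ft2$t1 - 2), 1e-6)
  expect_equal(ft2$s0, 123, tolerance = 1e-6)
})

test_that("constant signals drive T1 to the lower bound and are flagged", {
  ft <- fit_t1_variable_tr(rep(5, 8), vtr_times())
  expect_true(ft$at_bound)
})

test_that("variable-TR fit handles 1% noise with small median error", {
  set.seed(44)
  tr <- vtr_times()
  errs <- replicate(100, {
    s <- 100 * (1 - exp(-tr / 1.4)) + stats::rnorm(8, 0, 1)
    s[s < 0] <- 0
    abs(fit_t1_variable_tr(s, tr)$t1 - 1.4) / 1.4
  })
  expect_lt(stats::median(errs), 0.03)
})

test_that("map wrappers mask failing voxels", {
  offs <- seq(-1, 1, by = 0.025)
  good <- 1 - 0.8 / (1 + 4 * ((offs - 0.1) / 0.1)^2)
  bad <- 1 - 0.8 / (1 + 4 * ((offs - 1.5) / 0.1)^2)  # dip out of range
  stack <- rbind(good, bad)
  bm <- wassr_b0_map(stack, offs)
  expect_true(bm$mask[1]); expect_false(bm$mask[2])
  expect_equal(bm$b0_shift[1], 0.1, tolerance = 5e-3)

  tr <- vtr_times()
  tstack <- rbind(1 - exp(-tr / 2), rep(3, 8))
  tm <- t1_map_variable_tr(tstack, tr)
  expect_true(tm$mask[1]); expect_false(tm$mask[2])
  expect_equal(tm$t1[1], 2, tolerance = 1e-5)
})
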