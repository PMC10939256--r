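# Multi-pool Lorentzian model: component shape, Table-defaults loading,
# normalization, bounded fitting and baseline evaluation.

test_that("Lorentzian component has peak A, FWHM sigma and vanishing tails", {
  expect_equal(lorentzian_component(2, 0.5, 1.3, 2), 0.5)
  expect_equal(lorentzian_component(2 + 1.3 / 2, 0.5, 1.3, 2), 0.25)
  expect_equal(lorentzian_component(2 - 1.3 / 2, 0.5, 1.3, 2), 0.25)
  expect_lt(lorentzian_component(1e6, 0.5, 1.3, 2), 1e-10)
  expect_error(lorentzian_component(0, 1, -1, 0), "sigma")
})

test_that("shipped model defaults match the published bounds table", {
  m <- lorentzian_model("threepool_sym")
  expect_named(m$components, c("Water", "NOE_-3.5", "MT_symmetric"))
  expect_equal(unlist(m$components$Water$A), c(lb = 0.02, ub = 1, sv = 0.9))
  expect_equal(unlist(m$components$Water$sigma),
               c(lb = 0.3, ub = 10, sv = 1.4))
  expect_equal(unlist(m$components$Water$center), c(lb = -1, ub = 1, sv = 0))
  m4 <- lorentzian_model("fourpool_asym")
  expect_named(m4$components,
               c("Water", "NOE_-3.5", "NOE_-1.6", "MT_asymmetric"))
  expect_equal(unlist(m4$components$`NOE_-1.6`$A),
               c(lb = 0, ub = 0.2, sv = 0.001))
  expect_equal(m4$components$MT_asymmetric$center$sv, -2)
  expect_equal(m$components$MT_symmetric$center$sv, 0)
})

test_that("model overrides are merged and validated", {
  m <- lorentzian_model("threepool_sym",
                        overrides = list(Water = list(A = list(sv = 0.8))))
  expect_equal(m$components$Water$A$sv, 0.8)
  expect_error(
    lorentzian_model("threepool_sym",
                     overrides = list(Water = list(A = list(sv = 2)))),
    "lb <= sv <= ub")
})

test_that("stack normalization divides by the reference and masks bad voxels", {
  raw <- rbind(c(0.45, 0.9), c(0.2, 0.4), c(0.1, 0.2))
  ref <- c(0.9, 0, 0.5)
  out <- normalize_stack(raw, ref)
  expect_equal(out$z[1, ], c(0.5, 1.0))
  expect_false(out$mask[2])
  expect_true(all(is.na(out$z[2, ])))
  # round trip: z * ref recovers z
  z <- matrix(runif(12, 0.2, 1), 3)
  ref2 <- c(2, 3, 4)
  expect_equal(normalize_stack(z * ref2, ref2)$z, z, tolerance = 1e-12)
})

test_that("noise-free spectra from table starting values are recovered exactly", {
  for (lab in c("threepool_sym", "fourpool_asym")) {
    pv <- table1_sv(lab)
    offs <- if (lab == "threepool_sym") seq(-8, 8, length.out = 57)
            else cr_offsets()
    zs <- forward_zspec(lab, offs)
    init <- pv$sv * 1.1
    names(init) <- pv$names
    fit <- fit_multipool(zs, lab, exclusion = c(1.6, 4), init = init)
    expect_true(fit$converged)
    expect_lt(max(scaled_err(as.vector(t(coef(fit))), pv$sv)), 1e-3)
  }
})

test_that("a flat spectrum drives all amplitudes to their lower bounds", {
  offs <- seq(-8, 8, length.out = 57)
  fit <- fit_multipool(zspectrum(offs, rep(1, 57)), "threepool_sym",
                       exclusion = NULL)
  m <- lorentzian_model("threepool_sym")
  lbs <- vapply(m$components, function(co) co$A$lb, numeric(1))
  expect_equal(unname(coef(fit)[, "A"]), unname(lbs), tolerance = 1e-6)
  # residual after accounting for the bound-level components
  zres <- 1 - predict(fit)
  depth <- sum(coef(fit)[, "A"] / (1 + 4 * ((0 - coef(fit)[, "center"]) /
                                             coef(fit)[, "sigma"])^2))
  expect_lt(abs(max(zres) - depth), 0.05)
})

test_that("fit is deterministic and pre-conditions are enforced", {
  zs <- forward_zspec("threepool_sym", seq(-8, 8, length.out = 57))
  f1 <- fit_multipool(zs, "threepool_sym")
  f2 <- fit_multipool(zs, "threepool_sym")
  expect_identical(coef(f1), coef(f2))
  expect_error(fit_multipool(zspectrum(seq(-1, 1, 0.5), rep(0.9, 5)),
                             "threepool_sym"), "offsets")
})

test_that("fit methods are mutually consistent", {
  offs <- seq(-8, 8, length.out = 57)
  zs <- forward_zspec("threepool_sym", offs)
  fit <- fit_multipool(zs, "threepool_sym")
  expect_equal(fitted(fit), predict(fit, offs))
  expect_length(residuals(fit), length(fit$fitted_offsets))
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_output(print(fit), "Multi-pool Lorentzian")
  s <- summary(fit)
  expect_lt(s$rmse, 1e-8)
})

test_that("baseline_spectrum evaluates component subsets", {
  offs <- seq(-8, 8, length.out = 57)
  zs <- forward_zspec("threepool_sym", offs)
  fit <- fit_multipool(zs, "threepool_sym")
  full <- baseline_spectrum(fit, offs)
  expect_equal(full$z, predict(fit), tolerance = 1e-12)
  mt <- baseline_spectrum(fit, offs, include = "MT_symmetric")
  expect_true(all(mt$z >= full$z - 1e-12))
  expect_error(baseline_spectrum(fit, offs, include = character()),
               "non-empty")
  expect_error(baseline_spectrum(fit, offs, include = "Glu"), "unknown")
  # dense-grid evaluation stays within the data range of the coarse grid
  dense <- baseline_spectrum(fit, seq(-8, 8, by = 0.01))
  expect_true(all(dense$z <= 1 + 1e-9))
  expect_gt(min(dense$z), min(full$z) - 0.05)
})

test_that("parameter recovery under noise tracks the information bound for water", {
  set.seed(55)
  pv <- table1_sv("threepool_sym")
  offs <- seq(-8, 8, length.out = 57)
  z0 <- forward_zspec("threepool_sym", offs)$z
  errs <- replicate(60, {
    f <- fit_multipool(zspectrum(offs, add_rician_noise(z0, 0.01)),
                       "threepool_sym")
    abs(coef(f)["Water", "A"] - 0.9) / 0.9
  })
  expect_lt(stats::median(errs), 0.05)
})
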