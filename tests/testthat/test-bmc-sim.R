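# Bloch-McConnell simulator: generator structure, analytic limits, ODE oracle
# agreement and saturation-transfer properties.

test_that("zero irradiation decouples transverse and longitudinal dynamics", {
  sys <- two_pool()
  pr <- saturation_protocol(0, 1, 8, 0)
  g <- bmc_generator(sys, pr, 2.5)
  # no My-Mz coupling anywhere
  for (i in 1:2) {
    r <- 3 * (i - 1)
    expect_identical(g$A[r + 2, r + 3], 0)
    expect_identical(g$A[r + 3, r + 2], 0)
  }
  # stationary point is thermal equilibrium
  expect_lt(max(abs(g$A %*% g$M0 + g$b)), 1e-12)
  expect_equal(simulate_zvalue(sys, pr, 2.5), 1)
})

test_that("zero exchange gives a block-diagonal generator", {
  sys <- pool_system(list(pool("water", 0, 1, 0, 2, 0.05),
                          pool("p2", 3, 1e-3, 0, 1.3, 0.01)))
  g <- bmc_generator(sys, glu_protocol(), 1)
  expect_true(all(g$A[1:3, 4:6] == 0))
  expect_true(all(g$A[4:6, 1:3] == 0))
})

test_that("invalid pool parameters are rejected", {
  expect_error(pool("water", 0, 1, 0, -1, 0.05), "positive")
  expect_error(pool("p", 3, -0.1, 100, 1, 0.01), "fraction")
  expect_error(pool_system(list(pool("w", 0, 1, 0, 2, 0.05))), "water")
  expect_error(pool_system(list(pool("water", 0.5, 1, 0, 2, 0.05))),
               "delta_ppm")
})

test_that("two-pool stationary solution matches long-time ODE integration", {
  sys <- two_pool(f = 1e-3, k = 2000)
  pr <- saturation_protocol(2, 50, 50, 0)
  g <- bmc_generator(sys, pr, 2.8)
  stationary <- solve(g$A, -g$b)
  sol <- deSolve::lsoda(g$M0, c(0, 50),
                        function(t, y, p) list(g$A %*% y + g$b),
                        rtol = 1e-12, atol = 1e-14, maxsteps = 1e6)
  expect_lt(max(abs(stationary - sol[nrow(sol), -1])), 1e-8)
})

test_that("far off-resonance saturation leaves water untouched", {
  expect_gt(simulate_zvalue(water_only(), glu_protocol(), -300), 0.99)
  expect_gt(simulate_zvalue(two_pool(), glu_protocol(), -300), 0.99)
  # the broad semisolid MT pool still absorbs a little at -300 ppm
  expect_gt(simulate_zvalue(default_pool_system(), glu_protocol(), -300),
            0.97)
})

test_that("single-pool long-saturation Z matches the rotating-frame steady state", {
  # liquid-like relaxation so the closed form (valid for R2 << delta-omega)
  # is exact to 1e-6
  sys <- water_only(t1 = 3, t2 = 0.5)
  pr <- saturation_protocol(1, 100, 100, 0)
  for (off in c(0.8, 1.5, 4, -2.5)) {
    expect_equal(simulate_zvalue(sys, pr, off),
                 cw_steady_state_z(3, 0.5, 1, off), tolerance = 1e-6)
  }
})

test_that("water-only spectra are symmetric and preserve offset order", {
  offs <- c(4, -4, 1.25, -1.25, 0.5, -0.5)
  sp <- simulate_zspectrum(water_only(),
                           saturation_protocol(2, 1, 8, offs))
  expect_identical(sp$offsets, offs)
  expect_lt(abs(sp$z[1] - sp$z[2]), 1e-9)
  expect_lt(abs(sp$z[3] - sp$z[4]), 1e-9)
  expect_lt(abs(sp$z[5] - sp$z[6]), 1e-9)
})

test_that("default simulation grid has 201 points at 0.08 ppm increment", {
  pr <- sim_protocol()
  expect_length(pr$offsets, 201L)
  expect_equal(diff(pr$offsets)[1], 0.08)
  expect_equal(range(pr$offsets), c(-8, 8))
})

test_that("adding a solute pool lowers Z at its resonance", {
  pr <- glu_protocol()
  z_without <- simulate_zvalue(water_only(), pr, 3)
  z_with <- simulate_zvalue(two_pool(f = 1e-3, k = 2000, delta = 3), pr, 3)
  expect_lt(z_with, z_without)
  # and against the independent ODE oracle
  expect_lt(ode_zvalue(two_pool(f = 1e-3, k = 2000, delta = 3), pr, 3),
            ode_zvalue(water_only(), pr, 3))
})

test_that("matrix-exponential propagation matches the ODE oracle on random draws", {
  set.seed(101)
  for (i in 1:10) {
    rp <- random_system_protocol()
    expect_equal(simulate_zvalue(rp$system, rp$protocol, rp$offset),
                 ode_zvalue(rp$system, rp$protocol, rp$offset),
                 tolerance = 1e-7)
  }
})

test_that("Z is invariant under relabeling and reordering of solute pools", {
  pr <- glu_protocol()
  p1 <- pool("a", 3, 1e-3, 2000, 1.3, 0.01)
  p2 <- pool("b", -1.6, 2e-3, 30, 1.3, 0.005)
  w <- pool("water", 0, 1, 0, 2, 0.05)
  s1 <- pool_system(list(w, p1, p2))
  p1b <- pool("zz", 3, 1e-3, 2000, 1.3, 0.01)
  s2 <- pool_system(list(p2, w, p1b))
  for (off in c(-1.6, 1, 3))
    expect_equal(simulate_zvalue(s1, pr, off),
                 simulate_zvalue(s2, pr, off), tolerance = 1e-12)
})

test_that("Z decreases monotonically with saturation duration at a solute resonance", {
  sys <- two_pool()
  z <- vapply(c(0.5, 1, 2, 4, 6), function(ts)
    simulate_zvalue(sys, saturation_protocol(2, ts, 8, 0), 3), numeric(1))
  expect_true(all(diff(z) < 0))
})

test_that("pool_contrast is zero for an empty pool and monotone in fraction", {
  w <- pool("water", 0, 1, 0, 2, 0.05)
  pr <- saturation_protocol(2, 1, 8, c(-3, 0, 3))
  sys0 <- pool_system(list(w, pool("amine", 3, 0, 2000, 1.3, 0.01)))
  pc0 <- pool_contrast(sys0, pr, "amine")
  expect_true(all(abs(pc0$contrast) < 1e-10))
  cvals <- vapply(c(1, 2, 4) * 5e-4, function(f) {
    sys <- pool_system(list(w, pool("amine", 3, f, 2000, 1.3, 0.01)))
    pool_contrast(sys, pr, "amine")$at_resonance
  }, numeric(1))
  expect_gt(cvals[1], 0)
  expect_true(all(diff(cvals) > 0))
  expect_error(pool_contrast(sys0, pr, "water"), "water")
})

test_that("protocol_sweep consistency: a 1x1 grid equals pool_contrast", {
  sys <- two_pool()
  pr <- saturation_protocol(2, 1, 8, c(-3, 3))
  sw <- protocol_sweep(sys, pr, b1_grid = 2, tsat_grid = 1,
                       target = "solute")
  expect_equal(dim(sw), c(1L, 1L))
  expect_equal(sw[1, 1], pool_contrast(sys, pr, "solute")$at_resonance,
               tolerance = 1e-12)
})

test_that("symmetric-MT background yields a symmetric Z-spectrum", {
  sys <- background_system("symmetric_0ppm")
  sys <- drop_pool(drop_pool(sys, "noe_m3p5"), "noe_m1p6")
  offs <- seq(-6, 6, by = 1.5)
  sp <- simulate_zspectrum(sys, glu_protocol(), offsets = offs)
  expect_lt(max(abs(sp$z - rev(sp$z))), 1e-9)
})
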