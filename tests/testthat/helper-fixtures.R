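# Shared fixtures: small pool systems and an independent ODE propagation
# oracle for the Bloch-McConnell simulator.

water_only <- function(t1 = 2, t2 = 0.05)
  pool_system(list(pool("water", 0, 1, 0, t1, t2)))

two_pool <- function(f = 1e-3, k = 2000, delta = 3)
  pool_system(list(pool("water", 0, 1, 0, 2, 0.05),
                   pool("solute", delta, f, k, 1.3, 0.01)))

background_system <- function(mt_mode = "symmetric_0ppm") {
  sys <- default_pool_system(mt_mode = mt_mode)
  for (nm in c("amine", "cr", "pcr", "amide", "gaba"))
    sys <- drop_pool(sys, nm)
  sys
}

# adaptive-step ODE integration oracle, independent of the matrix-exponential
# propagation path
ode_zvalue <- function(system, protocol, offset, b1_scale = 1) {
  g <- bmc_generator(system, protocol, offset, b1_scale = b1_scale)
  sol <- deSolve::lsoda(g$M0, c(0, protocol$t_sat),
                        function(t, y, p) list(g$A %*% y + g$b),
                        rtol = 1e-10, atol = 1e-12, maxsteps = 1e6)
  unname(sol[nrow(sol), 1L + g$z_index])
}

# random small pool system + protocol draw for property tests
random_system_protocol <- function() {
  npool <- sample(2:4, 1)
  pools <- list(pool("water", 0, 1, 0, stats::runif(1, 1, 3),
                     stats::runif(1, 0.02, 0.2)))
  for (i in 2:npool)
    pools <- c(pools, list(pool(paste0("p", i), stats::runif(1, -4, 4),
                                stats::runif(1, 1e-4, 5e-3),
                                stats::runif(1, 10, 5000),
                                stats::runif(1, 0.5, 2),
                                stats::runif(1, 1e-3, 2e-2))))
  list(system = pool_system(pools),
       protocol = saturation_protocol(stats::runif(1, 0.5, 6),
                                      stats::runif(1, 0.2, 2), 8, 0),
       offset = stats::runif(1, -8, 8))
}

# Lorentzian helpers
table1_sv <- function(label) {
  m <- lorentzian_model(label)
  arexcest:::model_par_vectors(m)
}

forward_zspec <- function(label, offsets) {
  pv <- table1_sv(label)
  zspectrum(offsets,
            arexcest:::eval_multipool(pv$sv, offsets,
                                      length(pv$sv) / 3L))
}

# relative error with an absolute floor for near-zero truths
scaled_err <- function(est, truth, floor = 1e-3)
  abs(est - truth) / pmax(abs(truth), floor)
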