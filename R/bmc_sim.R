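# Bloch-McConnell CW-saturation simulator.
#
# State ordering: 3 components (Mx, My, Mz) per pool, water first, so the
# state vector is c(Mx1, My1, Mz1, Mx2, ...).  All exchange is routed through
# water (star topology) and mass-balanced: solute i loses magnetization at
# k_i and water loses to solute i at fraction_i * k_i.

#' Build the Bloch-McConnell evolution operator for one saturation offset
#'
#' Constructs the linear time-invariant system `dM/dt = A M + b` describing
#' CW irradiation at the given offset in the frame rotating at the saturation
#' frequency.  Each pool contributes a 3x3 block (relaxation, off-resonance
#' precession at `delta_pool - offset`, and the B1 nutation term) and
#' mass-balanced exchange terms with water on all three components.
#'
#' @param system A [pool_system()].
#' @param protocol A [saturation_protocol()]; `b1_amp` and field constants
#'   are used.
#' @param offset Saturation offset (ppm).
#' @param b1_scale Multiplicative B1 scale (used for B1-inhomogeneity
#'   simulation; default 1).
#' @return List with `A` (3n x 3n matrix), `b` (drive vector), `M0` (thermal
#'   equilibrium state: `Mz = fraction`, transverse components 0), and `z_index`
#'   (row of the water Mz component).
#' @export
bmc_generator <- function(system, protocol, offset, b1_scale = 1) {
  stopifnot(inherits(system, "pool_system"),
            inherits(protocol, "saturation_protocol"))
  if (!is.finite(offset)) stop("offset must be finite")
  np <- n_pools(system)
  n <- 3L * np
  A <- matrix(0, n, n)
  b <- numeric(n)
  M0 <- numeric(n)
  w1 <- protocol$gamma * protocol$b1_amp * 1e-6 * b1_scale  # rad/s
  fw <- numeric(np)
  for (i in seq_len(np)) {
    p <- system$pools[[i]]
    r <- 3L * (i - 1L)
    dw <- ppm_to_rad(p$delta_ppm - offset, protocol)
    R1 <- 1 / p$t1; R2 <- 1 / p$t2
    A[r + 1L, r + 1L] <- -R2; A[r + 1L, r + 2L] <- dw
    A[r + 2L, r + 1L] <- -dw; A[r + 2L, r + 2L] <- -R2
    A[r + 2L, r + 3L] <- w1
    A[r + 3L, r + 2L] <- -w1; A[r + 3L, r + 3L] <- -R1
    b[r + 3L] <- R1 * p$fraction
    M0[r + 3L] <- p$fraction
    fw[i] <- p$fraction * p$k_exch
  }
  # exchange: water block index 1
  for (i in seq.int(2L, length.out = np - 1L)) {
    p <- system$pools[[i]]
    if (p$k_exch == 0) next
    r <- 3L * (i - 1L)
    for (c in 1:3) {
      A[c, c] <- A[c, c] - fw[i]            # water loss to pool i
      A[c, r + c] <- A[c, r + c] + p$k_exch # gain from pool i
      A[r + c, c] <- A[r + c, c] + fw[i]    # pool i gain from water
      A[r + c, r + c] <- A[r + c, r + c] - p$k_exch
    }
  }
  list(A = A, b = b, M0 = M0, z_index = 3L)
}

# Propagate the affine system M' = A M + b from M0 over time t via the
# exponential of the augmented matrix [[A, b], [0, 0]]; exact for any A,
# including singular A.  Falls back to stiff ODE integration if the matrix
# exponential fails.
propagate_affine <- function(A, b, M0, t) {
  n <- length(M0)
  G <- rbind(cbind(A, b), 0)
  E <- tryCatch(as.matrix(Matrix::expm(G * t)),
                error = function(e) NULL)
  if (!is.null(E) && all(is.finite(E)))
    return(drop(E %*% c(M0, 1))[seq_len(n)])
  sol <- deSolve::lsoda(y = M0, times = c(0, t),
                        func = function(tt, y, p) list(A %*% y + b),
                        rtol = 1e-10, atol = 1e-12)
  as.numeric(sol[nrow(sol), -1L])
}

#' Simulate the normalized water Z-value for one saturation offset
#'
#' Starting from thermal equilibrium (single-shot; TR is assumed long enough
#' for full recovery), propagates the magnetization through `t_sat` seconds
#' of CW saturation using the closed-form matrix-exponential solution of the
#' affine Bloch-McConnell system and returns `Mz_water(t_sat) / Mz_eq`.
#'
#' @inheritParams bmc_generator
#' @return Normalized Z-value (unitless scalar).
#' @export
#' @examples
#' sys <- pool_system(list(pool("water", 0, 1, 0, 2, 0.05)))
#' simulate_zvalue(sys, sim_protocol(b1_amp = 0), 3)   # == 1
simulate_zvalue <- function(system, protocol, offset, b1_scale = 1) {
  g <- bmc_generator(system, protocol, offset, b1_scale = b1_scale)
  if (protocol$b1_amp * b1_scale == 0) return(1)
  M <- propagate_affine(g$A, g$b, g$M0, protocol$t_sat)
  z <- M[g$z_index]
  if (!is.finite(z))
    stop(sprintf("propagation failed at offset %.4g ppm", offset))
  z
}

#' Simulate a Z-spectrum
#'
#' One [simulate_zvalue()] per protocol offset, preserving offset order.
#'
#' @inheritParams bmc_generator
#' @param offsets Optional offsets (ppm) overriding `protocol$offsets`.
#' @return A [zspectrum()].
#' @export
simulate_zspectrum <- function(system, protocol, offsets = NULL,
                               b1_scale = 1) {
  if (is.null(offsets)) offsets <- protocol$offsets
  if (length(offsets) == 0L) stop("offsets must be non-empty")
  z <- vapply(offsets, function(o)
    simulate_zvalue(system, protocol, o, b1_scale = b1_scale), numeric(1))
  zspectrum(offsets, z)
}

#' With/without-pool contrast spectrum
#'
#' The metabolite-specific contrast of the numerical experiment: the
#' difference between the Z-spectrum simulated without the target pool and
#' the spectrum with it, `contrast(dw) = Z_without(dw) - Z_with(dw)`.  The
#' summary scalar is the contrast at the target pool's own resonance.
#'
#' @inheritParams bmc_generator
#' @param target Name of the pool to toggle (must exist; not `"water"`).
#' @param offsets Optional offsets (ppm); defaults to the protocol offsets.
#' @return List with `offsets`, `contrast` (vector), `at_resonance` (scalar
#'   contrast at the target pool center) and `target`.
#' @export
pool_contrast <- function(system, protocol, target, offsets = NULL) {
  if (target == "water") stop("target must not be the water pool")
  tp <- get_pool(system, target)
  if (is.null(offsets)) offsets <- protocol$offsets
  without <- drop_pool(system, target)
  zw <- simulate_zspectrum(system, protocol, offsets = offsets)
  zo <- simulate_zspectrum(without, protocol, offsets = offsets)
  contrast <- zo$z - zw$z
  at <- if (any(abs(offsets - tp$delta_ppm) < 1e-9)) {
    contrast[which.min(abs(offsets - tp$delta_ppm))]
  } else {
    z1 <- simulate_zvalue(system, protocol, tp$delta_ppm)
    z0 <- simulate_zvalue(without, protocol, tp$delta_ppm)
    z0 - z1
  }
  list(offsets = offsets, contrast = contrast, at_resonance = at,
       target = target)
}

#' Sweep saturation amplitude and duration for one target pool
#'
#' Evaluates the with/without-pool contrast at the target resonance over a
#' grid of B1 amplitudes and saturation durations (the protocol's TR and
#' field constants are kept).  Only the target resonance offset is simulated,
#' which makes wide sweeps cheap.
#'
#' @inheritParams pool_contrast
#' @param b1_grid Saturation amplitudes (uT).
#' @param tsat_grid Saturation durations (s).
#' @return Matrix of contrasts, rows indexed by `b1_grid`, columns by
#'   `tsat_grid` (dimnames carry the grid values).
#' @export
protocol_sweep <- function(system, protocol, b1_grid, tsat_grid, target) {
  if (length(b1_grid) == 0L || length(tsat_grid) == 0L)
    stop("grids must be non-empty")
  tp <- get_pool(system, target)
  without <- drop_pool(system, target)
  out <- matrix(NA_real_, length(b1_grid), length(tsat_grid),
                dimnames = list(b1 = format(b1_grid),
                                t_sat = format(tsat_grid)))
  for (i in seq_along(b1_grid)) for (j in seq_along(tsat_grid)) {
    pr <- saturation_protocol(b1_grid[i], tsat_grid[j],
                              max(protocol$tr, tsat_grid[j]),
                              protocol$offsets, protocol$ref_offset,
                              protocol$b0, protocol$gamma)
    z1 <- simulate_zvalue(system, pr, tp$delta_ppm)
    z0 <- simulate_zvalue(without, pr, tp$delta_ppm)
    out[i, j] <- z0 - z1
  }
  out
}

#' Closed-form CW steady-state Z for a single water pool
#'
#' Rotating-frame steady state `Zss = R1 cos^2(theta) /
#' (R1 cos^2(theta) + R2 sin^2(theta))` with `tan(theta) = w1 / dw`; used as
#' an analytic limit of the simulator for `t_sat >> T1, T2`.
#'
#' @param t1,t2 Water relaxation times (s).
#' @param b1_amp Saturation amplitude (uT).
#' @param offset Saturation offset (ppm).
#' @param b0 Static field (T).
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return Steady-state Z-value.
#' @export
cw_steady_state_z <- function(t1, t2, b1_amp, offset, b0 = 9.4,
                              gamma = GAMMA_H) {
  w1 <- gamma * b1_amp * 1e-6
  dw <- offset * 1e-6 * gamma * b0
  th <- atan2(w1, dw)
  R1 <- 1 / t1; R2 <- 1 / t2
  R1 * cos(th)^2 / (R1 * cos(th)^2 + R2 * sin(th)^2)
}
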