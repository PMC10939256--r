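#' Proton gyromagnetic ratio (rad s^-1 T^-1)
#' @keywords internal
GAMMA_H <- 267.52218744e6

#' Define an exchanging proton pool
#'
#' A pool is one class of exchangeable (or semisolid) protons taking part in
#' the Bloch-McConnell dynamics: water at 0 ppm, solute pools such as the
#' glutamate amine protons at 3 ppm or the creatine/phosphocreatine
#' guanidinium protons at 2.0/2.64 ppm, upfield NOE pools, and the broad
#' semisolid magnetization-transfer (MT) pool.
#'
#' @param name Pool label (character).
#' @param delta_ppm Chemical-shift offset from water (ppm, positive downfield).
#' @param fraction Relative proton fraction (unitless; water = 1).
#' @param k_exch Solute-to-water exchange rate (s^-1).  The reverse
#'   (water-to-solute) rate is `fraction * k_exch`, so magnetization is
#'   mass-balanced.
#' @param t1,t2 Longitudinal and transverse relaxation times (s); must be > 0.
#' @param lineshape Lineshape of the pool; only `"lorentzian"` is supported
#'   (all pools, including MT, are propagated with full 3-component dynamics).
#' @return An object of class `cest_pool`.
#' @export
#' @examples
#' pool("amine", 3.0, 3e-4, 5500, 1.3, 0.005)
pool <- function(name, delta_ppm, fraction, k_exch, t1, t2,
                 lineshape = "lorentzian") {
  stopifnot(is.character(name), length(name) == 1L)
  lineshape <- match.arg(lineshape)
  if (!is.finite(delta_ppm)) stop("delta_ppm must be finite")
  if (fraction < 0) stop("pool fraction must be >= 0")
  if (k_exch < 0) stop("exchange rate must be >= 0")
  if (!is.finite(t1) || t1 <= 0 || !is.finite(t2) || t2 <= 0)
    stop("relaxation times must be positive and finite")
  structure(list(name = name, delta_ppm = delta_ppm, fraction = fraction,
                 k_exch = k_exch, t1 = t1, t2 = t2, lineshape = lineshape),
            class = "cest_pool")
}

#' @export
print.cest_pool <- function(x, ...) {
  cat(sprintf("<pool %s>  %+.2f ppm  f=%.3g  k=%.3g /s  T1=%.3g s  T2=%.3g s\n",
              x$name, x$delta_ppm, x$fraction, x$k_exch, x$t1, x$t2))
  invisible(x)
}

#' Assemble a multi-pool system
#'
#' Orders the pools water-first and validates the semisolid MT configuration.
#' The MT pool may be centered at 0 ppm (`symmetric_0ppm`) or at -2.3 ppm
#' (`asymmetric_minus2p3ppm`); `mt_mode = "none"` means no semisolid pool.
#'
#' @param pools List of [pool()] objects; exactly one must be named `"water"`
#'   (with `delta_ppm = 0` and `fraction = 1`).
#' @param mt_mode One of `"symmetric_0ppm"`, `"asymmetric_minus2p3ppm"`,
#'   `"none"`.  Must be consistent with the center of the pool named `"mt"`
#'   (at most one such pool is allowed).
#' @return An object of class `pool_system`.
#' @export
pool_system <- function(pools, mt_mode = c("none", "symmetric_0ppm",
                                           "asymmetric_minus2p3ppm")) {
  mt_mode <- match.arg(mt_mode)
  stopifnot(is.list(pools), length(pools) >= 1L)
  ok <- vapply(pools, inherits, logical(1), "cest_pool")
  if (!all(ok)) stop("all elements must be cest_pool objects")
  nm <- vapply(pools, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("pool names must be unique")
  iw <- which(nm == "water")
  if (length(iw) != 1L) stop("exactly one pool must be named 'water'")
  w <- pools[[iw]]
  if (w$delta_ppm != 0 || w$fraction != 1)
    stop("water pool must have delta_ppm = 0 and fraction = 1")
  imt <- which(nm == "mt")
  if (length(imt) > 1L) stop("at most one semisolid MT pool")
  if (mt_mode == "none" && length(imt) > 0L)
    stop("mt_mode = 'none' but an 'mt' pool is present")
  if (mt_mode != "none") {
    if (length(imt) == 0L) stop("mt_mode set but no 'mt' pool present")
    want <- if (mt_mode == "symmetric_0ppm") 0 else -2.3
    if (abs(pools[[imt]]$delta_ppm - want) > 1e-9)
      stop(sprintf("mt pool center %.3g ppm inconsistent with mt_mode '%s'",
                   pools[[imt]]$delta_ppm, mt_mode))
  }
  pools <- c(pools[iw], pools[-iw])
  structure(list(pools = pools, mt_mode = mt_mode), class = "pool_system")
}

#' @export
print.pool_system <- function(x, ...) {
  cat(sprintf("<pool_system: %d pools, mt_mode = %s>\n",
              length(x$pools), x$mt_mode))
  for (p in x$pools) print(p)
  invisible(x)
}

#' Number of pools in a system
#' @param system A [pool_system()].
#' @return Integer count.
#' @export
n_pools <- function(system) length(system$pools)

pool_names <- function(system)
  vapply(system$pools, `[[`, character(1), "name")

get_pool <- function(system, name) {
  i <- match(name, pool_names(system))
  if (is.na(i)) stop(sprintf("no pool named '%s'", name))
  system$pools[[i]]
}

#' Remove a pool from a system
#'
#' Used for with/without-pool contrast simulation.  Removing the MT pool
#' resets `mt_mode` to `"none"`.
#'
#' @param system A [pool_system()].
#' @param name Pool name; must exist and must not be `"water"`.
#' @return A [pool_system()] without the named pool.
#' @export
drop_pool <- function(system, name) {
  if (name == "water") stop("cannot remove the water pool")
  nm <- pool_names(system)
  i <- match(name, nm)
  if (is.na(i)) stop(sprintf("no pool named '%s'", name))
  mt_mode <- if (name == "mt") "none" else system$mt_mode
  pool_system(system$pools[-i], mt_mode = mt_mode)
}

#' Scale the fraction of one pool
#' @param system A [pool_system()].
#' @param name Pool name (not water).
#' @param factor Multiplicative factor (>= 0) applied to the pool fraction.
#' @return Modified [pool_system()].
#' @export
scale_pool_fraction <- function(system, name, factor) {
  if (name == "water") stop("cannot scale the water fraction")
  if (factor < 0) stop("factor must be >= 0")
  i <- match(name, pool_names(system))
  if (is.na(i)) stop(sprintf("no pool named '%s'", name))
  p <- system$pools[[i]]
  system$pools[[i]] <- pool(p$name, p$delta_ppm, p$fraction * factor,
                            p$k_exch, p$t1, p$t2)
  pool_system(system$pools, mt_mode = system$mt_mode)
}

#' Load a pool library from YAML
#'
#' Reads a pool library file (the shipped default describes a 9-pool model of
#' brain tissue at 9.4 T: water, glutamate amine at 3 ppm, creatine and
#' phosphocreatine guanidinium at 2.0 and 2.64 ppm, amide at 3.5 ppm, the
#' GABA amine contaminant at 2.91 ppm, NOE pools at -3.5 and -1.6 ppm, and a
#' semisolid MT pool).
#' Pool parameter values are configuration with literature-typical defaults,
#' not fitted constants.
#'
#' @param path YAML file; `NULL` loads the shipped default library.
#' @param mt_mode MT configuration passed to [pool_system()]; the shipped MT
#'   entry has its center set accordingly (0 or -2.3 ppm).
#' @return A [pool_system()].
#' @export
#' @examples
#' sys <- default_pool_system()
#' n_pools(sys)
default_pool_system <- function(path = NULL,
                                mt_mode = c("symmetric_0ppm",
                                            "asymmetric_minus2p3ppm",
                                            "none")) {
  mt_mode <- match.arg(mt_mode)
  if (is.null(path))
    path <- system.file("extdata", "pool_library.yaml", package = "arexcest",
                        mustWork = TRUE)
  y <- yaml::read_yaml(path)
  pools <- lapply(y$pools, function(p) {
    if (identical(p$name, "mt")) {
      if (mt_mode == "none") return(NULL)
      p$delta_ppm <- if (mt_mode == "symmetric_0ppm") 0 else -2.3
    }
    pool(p$name, p$delta_ppm, p$fraction, p$k_exch, p$t1, p$t2)
  })
  pools <- pools[!vapply(pools, is.null, logical(1))]
  pool_system(pools, mt_mode = mt_mode)
}
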