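# B0 (WASSR), B1 (double angle) and T1 (variable-TR) field mapping.

#' Estimate the per-voxel B0 shift from a WASSR spectrum
#'
#' Locates the water direct-saturation dip of a low-power WASSR spectrum as
#' the argmin of a cubic-spline interpolant evaluated on a 0.001 ppm grid.
#' The dip must lie strictly inside the sampled range; a boundary minimum
#' signals that the true water frequency is out of range and the voxel should
#' be masked.
#'
#' @param wassr A [zspectrum()] with at least 9 offsets.
#' @return B0 shift (ppm): the water-center frequency on the nominal axis.
#' @export
#' @examples
#' offs <- seq(-1, 1, by = 0.025)
#' z <- 1 - 0.8 / (1 + 4 * ((offs - 0.125) / 0.1)^2)
#' estimate_b0_wassr(zspectrum(offs, z))
estimate_b0_wassr <- function(wassr) {
  stopifnot(inherits(wassr, "zspectrum"))
  ok <- !is.na(wassr$z)
  x <- wassr$offsets[ok]; y <- wassr$z[ok]
  if (length(x) < 9L) stop("WASSR spectrum needs at least 9 usable offsets")
  o <- order(x); x <- x[o]; y <- y[o]
  grid <- seq(x[1L], x[length(x)], by = 0.001)
  s <- stats::spline(x, y, xout = grid, method = "fmm")
  i <- which.min(s$y)
  step <- 0.001
  if (s$x[i] <= x[1L] + step / 2 || s$x[i] >= x[length(x)] - step / 2)
    stop("WASSR minimum at range boundary; water frequency out of range")
  s$x[i]
}

#' Resample a Z-spectrum onto its nominal offsets after a B0 shift
#'
#' The acquired spectrum is effectively sampled at `nominal + b0_shift`;
#' this evaluates a cubic-spline interpolant of the measured spectrum at the
#' shifted positions so downstream fitting sees the nominal offset axis.
#' The resampling is monotone-consistent: where the data run monotonically,
#' interpolated values are clamped into the bracketing-sample range (no
#' spline overshoot); at local extrema the spline value is kept, since the
#' true curve there genuinely passes beyond its bracketing samples.  Offsets
#' falling outside the measured range are returned as `NA` (flagged
#' missing), never extrapolated.
#'
#' @param zspec A [zspectrum()] on the nominal offsets.
#' @param b0_shift B0 shift (ppm), e.g. from [estimate_b0_wassr()].
#' @return A [zspectrum()] on the same nominal offsets.
#' @export
apply_b0_shift <- function(zspec, b0_shift) {
  stopifnot(inherits(zspec, "zspectrum"), is.finite(b0_shift))
  if (b0_shift == 0) return(zspec)
  ok <- !is.na(zspec$z)
  x <- zspec$offsets[ok]; y <- zspec$z[ok]
  o <- order(x); x <- x[o]; y <- y[o]
  f <- stats::splinefun(x, y, method = "fmm")
  target <- zspec$offsets + b0_shift
  inside <- target >= x[1L] & target <= x[length(x)]
  z <- rep(NA_real_, length(target))
  z[inside] <- f(target[inside])
  # no-overshoot clamp on locally monotone runs; extrema stay unclamped
  n <- length(y)
  idx <- findInterval(target[inside], x, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n - 1L)
  d_prev <- y[pmax(idx, 2L)] - y[pmax(idx - 1L, 1L)]
  d_this <- y[idx + 1L] - y[idx]
  d_next <- y[pmin(idx + 2L, n)] - y[pmin(idx + 1L, n)]
  monotone <- (d_prev >= 0 & d_this >= 0 & d_next >= 0) |
              (d_prev <= 0 & d_this <= 0 & d_next <= 0)
  lo <- pmin(y[idx], y[idx + 1L])
  hi <- pmax(y[idx], y[idx + 1L])
  zi <- z[inside]
  zi[monotone] <- pmin(pmax(zi[monotone], lo[monotone]), hi[monotone])
  z[inside] <- zi
  if (all(is.na(z))) stop("B0 correction failed: all offsets out of range")
  zspectrum(zspec$offsets, z)
}

#' B1 ratio from a double-angle image pair
#'
#' With GRE signals proportional to `sin(theta)` and `sin(2 theta)` at
#' nominal flips alpha and 2 alpha, the actual flip is
#' `theta = arccos(S_2a / (2 S_a))` and the B1 transmit ratio is
#' `theta / alpha`.  The arccos argument is clamped to [-1, 1]; clamped
#' voxels are flagged low-confidence, and voxels with non-positive `S_a`
#' are masked.
#'
#' @param img_alpha,img_2alpha Signals at flip alpha and 2 alpha (scalars or
#'   arrays of matching shape).
#' @param nominal_alpha Nominal flip angle (degrees; default 30).
#' @return List with `b1_ratio` (same shape as input), `mask` (FALSE where
#'   `img_alpha <= 0`) and `clamped` (TRUE where the ratio was clamped).
#' @export
estimate_b1_double_angle <- function(img_alpha, img_2alpha,
                                     nominal_alpha = 30) {
  if (!isTRUE(all(dim(img_alpha) == dim(img_2alpha))) &&
      length(img_alpha) != length(img_2alpha))
    stop("image geometries do not match")
  mask <- is.finite(img_alpha) & img_alpha > 0 & is.finite(img_2alpha)
  arg <- img_2alpha / (2 * img_alpha)
  clamped <- mask & (arg < -1 | arg > 1)
  arg <- pmin(pmax(arg, -1), 1)
  theta <- acos(arg) * 180 / pi
  ratio <- theta / nominal_alpha
  ratio[!mask] <- NA_real_
  if (!is.null(dim(img_alpha))) {
    dim(ratio) <- dim(img_alpha); dim(mask) <- dim(img_alpha)
    dim(clamped) <- dim(img_alpha)
  }
  list(b1_ratio = ratio, mask = mask, clamped = clamped)
}

#' Fit T1 from a variable-TR (saturation-recovery) series
#'
#' Fits `S(TR) = S0 (1 - exp(-TR / T1))` by bounded least squares.  S0 enters
#' the model linearly, so for each candidate T1 the optimal S0 is solved in
#' closed form and T1 is found by 1-D minimization on [0.05, 10] s; this is
#' deterministic and equivalent to the joint bounded fit.  A T1 estimate at
#' either bound is flagged (voxels so flagged should be excluded from the
#' analysis mask).
#'
#' @param signals Signal values (>= 0), one per TR.
#' @param tr_list Repetition times (s); at least 3 distinct values.
#' @param bounds T1 search bounds (s).
#' @return List with `t1` (s), `s0`, `residual` (residual sum of squares),
#'   `converged`, `at_bound`.
#' @export
#' @examples
#' tr <- vtr_times()
#' fit_t1_variable_tr(1 - exp(-tr / 2), tr)$t1   # 2.0
fit_t1_variable_tr <- function(signals, tr_list, bounds = c(0.05, 10)) {
  signals <- as.numeric(signals); tr_list <- as.numeric(tr_list)
  if (length(signals) != length(tr_list)) stop("length mismatch")
  if (length(unique(tr_list)) < 3L) stop("need >= 3 distinct TRs")
  if (any(signals < 0)) stop("signals must be >= 0")
  rss <- function(t1) {
    f <- 1 - exp(-tr_list / t1)
    s0 <- sum(signals * f) / sum(f * f)
    sum((signals - s0 * f)^2)
  }
  opt <- stats::optimize(rss, interval = bounds, tol = 1e-10)
  t1 <- opt$minimum
  f <- 1 - exp(-tr_list / t1)
  s0 <- sum(signals * f) / sum(f * f)
  # optimize() never returns the exact endpoints; snap within one tolerance
  at_bound <- (t1 - bounds[1L] < 1e-4) || (bounds[2L] - t1 < 1e-4)
  list(t1 = t1, s0 = s0, residual = opt$objective,
       converged = is.finite(opt$objective) && s0 > 0,
       at_bound = at_bound)
}

#' Voxel-wise field maps from WASSR, double-angle and variable-TR stacks
#'
#' Convenience wrappers applying the per-voxel estimators across image
#' stacks.  `wassr_b0_map` expects a voxel x offset matrix (or array with
#' offsets last); voxels whose dip is out of range are masked.
#' `t1_map_variable_tr` expects a voxel x TR matrix; voxels flagged at-bound
#' are masked.
#'
#' @param stack Matrix/array, offsets (or TRs) on the last dimension.
#' @param offsets WASSR offsets (ppm) / `tr_list` repetition times (s).
#' @param mask Optional logical vector/array of voxels to process.
#' @return List of per-voxel estimate and validity mask.
#' @export
wassr_b0_map <- function(stack, offsets, mask = NULL) {
  m <- flatten_stack(stack)
  if (is.null(mask)) mask <- rep(TRUE, nrow(m))
  b0 <- rep(NA_real_, nrow(m))
  ok <- as.logical(mask)
  for (v in which(ok)) {
    b0[v] <- tryCatch(estimate_b0_wassr(zspectrum(offsets, m[v, ])),
                      error = function(e) NA_real_)
  }
  list(b0_shift = restore_shape(b0, stack), mask = restore_shape(ok & !is.na(b0), stack))
}

#' @rdname wassr_b0_map
#' @export
t1_map_variable_tr <- function(stack, offsets, mask = NULL) {
  m <- flatten_stack(stack)
  if (is.null(mask)) mask <- rep(TRUE, nrow(m))
  t1 <- rep(NA_real_, nrow(m)); s0 <- rep(NA_real_, nrow(m))
  good <- rep(FALSE, nrow(m))
  for (v in which(as.logical(mask))) {
    ft <- tryCatch(fit_t1_variable_tr(m[v, ], offsets),
                   error = function(e) NULL)
    if (!is.null(ft) && ft$converged && !ft$at_bound) {
      t1[v] <- ft$t1; s0[v] <- ft$s0; good[v] <- TRUE
    }
  }
  list(t1 = restore_shape(t1, stack), s0 = restore_shape(s0, stack),
       mask = restore_shape(good, stack))
}

# stack helpers: voxel x channel matrix view of a (dims..., channel) array
flatten_stack <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (is.null(d)) stop("stack must be a matrix or array")
  matrix(stack, prod(d[-length(d)]), d[length(d)])
}

restore_shape <- function(v, stack) {
  if (is.matrix(stack) || is.null(dim(stack))) return(v)
  d <- dim(stack)
  array(v, d[-length(d)])
}
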