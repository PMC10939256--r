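# Synthetic study generation: image-domain phantoms with per-class pool
# systems, smooth B0/B1 inhomogeneity fields and Rician noise, plus
# group-structured ROI tables emulating the two-group study design.

#' Rician noise
#'
#' Magnitude of a complex Gaussian perturbation: each value `s` becomes
#' `sqrt((s + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)`.  At high SNR the
#' expected magnitude exceeds the true signal by about `sigma^2 / (2 s)`.
#'
#' @param x Signal values (>= 0 expected).
#' @param sigma Noise scale (same units as `x`); 0 returns `x` unchanged.
#' @return Noisy magnitudes, same shape as `x`.
#' @export
add_rician_noise <- function(x, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  n1 <- stats::rnorm(length(x), 0, sigma)
  n2 <- stats::rnorm(length(x), 0, sigma)
  out <- sqrt((x + n1)^2 + n2^2)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Phantom specification
#'
#' Describes a single-slice digital phantom: a square voxel grid partitioned
#' into tissue classes (each with its own pool system and T1), smooth B0 and
#' B1 inhomogeneity fields, and a Rician noise scale.  The default layout is
#' a disc of `"tissue"` containing a centered square `"hippocampus"` ROI,
#' surrounded by `"background"` (masked out).
#'
#' @param n Grid side length (voxels).
#' @param classes Named list of tissue classes; each entry is a list with
#'   `system` (a [pool_system()]) and `t1` (s).  `NULL` uses a two-class
#'   default built from [default_pool_system()].
#' @param b0_amp Peak amplitude (ppm, |.| <= 0.4) of a smooth Gaussian-blob
#'   B0 field; 0 gives a uniform 0 ppm field.
#' @param b1_amp Amplitude of the smooth multiplicative B1 field; the ratio
#'   spans `1 +/- b1_amp` (kept within 0.8..1.2); 0 gives ratio 1.
#' @param noise_sigma Rician noise scale relative to the reference signal.
#' @param seed Integer seed; the phantom and every study simulated from it
#'   are deterministic given the seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n = 16, classes = NULL, b0_amp = 0, b1_amp = 0,
                         noise_sigma = 0, seed = 1L) {
  if (abs(b0_amp) > 0.4) stop("|b0_amp| must be <= 0.4 ppm")
  if (b1_amp < 0 || b1_amp > 0.2) stop("b1_amp must be in [0, 0.2]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(classes)) {
    sys <- default_pool_system()
    classes <- list(
      tissue = list(system = sys, t1 = 2.0),
      hippocampus = list(system = scale_pool_fraction(sys, "amine", 1.2),
                         t1 = 1.9))
  }
  stopifnot(length(classes) >= 1L, !is.null(names(classes)))
  structure(list(n = as.integer(n), classes = classes, b0_amp = b0_amp,
                 b1_amp = b1_amp, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

smooth_blob <- function(n, cx, cy, width) {
  ix <- matrix(seq_len(n), n, n)
  iy <- matrix(seq_len(n), n, n, byrow = TRUE)
  exp(-(((ix - cx)^2 + (iy - cy)^2)) / (2 * width^2))
}

#' Build a labeled phantom
#'
#' Deterministic given the spec seed: assigns every voxel to one class
#' (disc-plus-centered-square layout for the default two classes; equal
#' vertical bands for other class counts), draws smooth B0 (ppm) and B1
#' (ratio) fields, and a T1 map from the per-class values.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `cest_phantom`: `class_map` (integer matrix, 0 =
#'   background), `class_names`, `classes`, `t1_map`, `b0_map`, `b1_map`,
#'   `mask`, `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  nm <- names(spec$classes)
  ix <- matrix(seq_len(n), n, n)
  iy <- matrix(seq_len(n), n, n, byrow = TRUE)
  c0 <- (n + 1) / 2
  inside <- sqrt((ix - c0)^2 + (iy - c0)^2) <= 0.45 * n
  class_map <- matrix(0L, n, n)
  if (length(nm) == 2L && identical(nm, c("tissue", "hippocampus"))) {
    class_map[inside] <- 1L
    half <- max(1L, round(n / 6))
    sq <- abs(ix - c0) <= half & abs(iy - c0) <= half
    class_map[inside & sq] <- 2L
  } else {
    band <- pmin(length(nm), 1L + (iy - 1L) %/% ceiling(n / length(nm)))
    class_map[inside] <- band[inside]
  }
  if (!any(class_map > 0L)) stop("empty class assignment")
  set.seed(spec$seed)
  if (spec$b0_amp != 0) {
    cx <- stats::runif(1, 0.3 * n, 0.7 * n)
    cy <- stats::runif(1, 0.3 * n, 0.7 * n)
    b0 <- spec$b0_amp * smooth_blob(n, cx, cy, 0.4 * n)
  } else b0 <- matrix(0, n, n)
  if (spec$b1_amp != 0) {
    cx <- stats::runif(1, 0.3 * n, 0.7 * n)
    cy <- stats::runif(1, 0.3 * n, 0.7 * n)
    b1 <- 1 + spec$b1_amp * (2 * smooth_blob(n, cx, cy, 0.5 * n) - 1)
    b1 <- pmin(pmax(b1, 0.8), 1.2)
  } else b1 <- matrix(1, n, n)
  t1 <- matrix(NA_real_, n, n)
  for (k in seq_along(nm)) t1[class_map == k] <- spec$classes[[k]]$t1
  structure(list(class_map = class_map, class_names = nm,
                 classes = spec$classes, t1_map = t1, b0_map = b0,
                 b1_map = b1, mask = class_map > 0L, spec = spec),
            class = "cest_phantom")
}

#' @export
print.cest_phantom <- function(x, ...) {
  cat(sprintf("<cest_phantom %dx%d: classes %s; %d voxels in mask>\n",
              nrow(x$class_map), ncol(x$class_map),
              paste(x$class_names, collapse = ", "), sum(x$mask)))
  invisible(x)
}

#' ROI mask of one phantom class
#' @param phantom A [make_phantom()] result.
#' @param class_name Class name.
#' @return Logical matrix.
#' @export
phantom_roi <- function(phantom, class_name) {
  k <- match(class_name, phantom$class_names)
  if (is.na(k)) stop(sprintf("no class '%s'", class_name))
  phantom$class_map == k
}

simulate_voxels <- function(phantom, protocol, offsets, b1_scale_extra = 1) {
  # per-voxel Z values; memoized over unique (class, b0, b1) keys (exact:
  # identical inputs give identical spectra)
  n <- nrow(phantom$class_map)
  vox <- which(phantom$mask)
  key <- paste(phantom$class_map[vox],
               signif(phantom$b0_map[vox], 12),
               signif(phantom$b1_map[vox], 12))
  cache <- new.env(parent = emptyenv())
  out <- matrix(NA_real_, n * n, length(offsets))
  for (i in seq_along(vox)) {
    v <- vox[i]
    if (is.null(cache[[key[i]]])) {
      sys <- phantom$classes[[phantom$class_map[v]]]$system
      shifted <- offsets - phantom$b0_map[v]
      cache[[key[i]]] <- vapply(shifted, function(o)
        simulate_zvalue(sys, protocol, o,
                        b1_scale = phantom$b1_map[v] * b1_scale_extra),
        numeric(1))
    }
    out[v, ] <- cache[[key[i]]]
  }
  array(out, c(n, n, length(offsets)))
}

#' Simulate a complete synthetic study from a phantom
#'
#' Produces the raw acquisitions of the imaging session: the high-power
#' (glutamate) and low-power (creatine) CEST stacks with their -300 ppm
#' reference images, the WASSR offset series, the double-angle image pair
#' and the variable-TR series.  Per voxel, the voxel's B0 shift is added to
#' every nominal saturation offset and B1 is scaled by the voxel's ratio;
#' Rician noise is applied to all magnitude images.  Deterministic given
#' `seed`.
#'
#' @param phantom A [make_phantom()] result.
#' @param protocols Named list with entries `glu`, `cr`, `wassr`
#'   ([saturation_protocol()]s); defaults to the shipped protocols.
#' @param which Subset of acquisitions to simulate (default all of
#'   `"glu"`, `"cr"`, `"wassr"`, `"dam"`, `"vtr"`).
#' @param seed Integer seed for the noise; defaults to the phantom seed.
#' @return Named list of [stack_bundle()]-style lists, each with `data`
#'   (array, channels last), `offsets` or acquisition parameters, and the
#'   noise-free reference where applicable.
#' @export
simulate_study <- function(phantom,
                           protocols = list(glu = glu_protocol(),
                                            cr = cr_protocol(),
                                            wassr = wassr_protocol()),
                           which = c("glu", "cr", "wassr", "dam", "vtr"),
                           seed = NULL) {
  stopifnot(inherits(phantom, "cest_phantom"))
  if (is.null(seed)) seed <- phantom$spec$seed
  sigma <- phantom$spec$noise_sigma
  n <- nrow(phantom$class_map)
  out <- list(seed = seed)
  set.seed(seed)
  ref_signal <- matrix(0, n, n); ref_signal[phantom$mask] <- 1
  for (w in which) {
    if (w %in% c("glu", "cr")) {
      pr <- protocols[[w]]
      z <- simulate_voxels(phantom, pr, pr$offsets)
      raw <- z * as.vector(ref_signal)
      ref <- add_rician_noise(ref_signal, sigma)
      raw <- add_rician_noise(raw, sigma)
      raw[!phantom$mask] <- 0
      ref[!phantom$mask] <- 0
      out[[w]] <- list(data = raw, ref = ref, offsets = pr$offsets,
                       protocol = pr, n_offsets = length(pr$offsets))
    } else if (w == "wassr") {
      pr <- protocols$wassr
      z <- simulate_voxels(phantom, pr, pr$offsets)
      raw <- add_rician_noise(z * as.vector(ref_signal), sigma)
      raw[!phantom$mask] <- 0
      out$wassr <- list(data = raw, offsets = pr$offsets, protocol = pr,
                        n_offsets = length(pr$offsets))
    } else if (w == "dam") {
      alpha <- 30 * phantom$b1_map
      s1 <- sin(alpha * pi / 180) * ref_signal
      s2 <- sin(2 * alpha * pi / 180) * ref_signal
      out$dam <- list(img_alpha = add_rician_noise(s1, sigma),
                      img_2alpha = add_rician_noise(s2, sigma),
                      nominal_alpha = 30)
      out$dam$img_alpha[!phantom$mask] <- 0
      out$dam$img_2alpha[!phantom$mask] <- 0
    } else if (w == "vtr") {
      trs <- vtr_times()
      sig <- vapply(trs, function(tr)
        ref_signal * (1 - exp(-tr / phantom$t1_map)), matrix(0, n, n))
      sig[is.na(sig)] <- 0
      out$vtr <- list(data = add_rician_noise(sig, sigma), tr = trs)
      out$vtr$data[is.na(out$vtr$data)] <- 0
    } else stop(sprintf("unknown acquisition '%s'", w))
  }
  out
}

#' Effects specification for synthetic ROI tables
#'
#' Per-measure group means and SDs for the two groups plus covariate
#' distributions.  The shipped defaults emulate the magnitude of the study's
#' group contrasts (AREX in s^-1, qT1 in ms) with WT means, WT-minus-ARTE10
#' differences and pooled SDs chosen to reproduce the published mean
#' differences and effect sizes; they are configuration, not claims.
#'
#' @param measures Named list; each entry a list with `mean_wt`,
#'   `mean_arte10`, `sd`.
#' @param covariates Named list; each entry a list with `mean`, `sd`
#'   (shared by both groups).
#' @param n_per_group Animals per group (>= 2).
#' @param seed Integer seed.
#' @return Object of class `effects_spec`.
#' @export
effects_spec <- function(measures = NULL, covariates = NULL,
                         n_per_group = 10L, seed = 1L) {
  if (n_per_group < 2L) stop("need n_per_group >= 2")
  if (is.null(measures)) {
    measures <- list(
      AREX_Glu = list(mean_wt = 0.25,  mean_arte10 = 0.19,  sd = 0.0458),
      AREX_PCr = list(mean_wt = 0.060, mean_arte10 = 0.050, sd = 0.0056),
      AREX_Cr  = list(mean_wt = 0.100, mean_arte10 = 0.090, sd = 0.0093),
      qT1      = list(mean_wt = 1850,  mean_arte10 = 1885.4, sd = 59.9))
  }
  if (is.null(covariates)) {
    covariates <- list(roi_volume = list(mean = 2.6, sd = 0.3))
  }
  for (m in measures) if (m$sd <= 0) stop("measure SDs must be > 0")
  for (cv in covariates) if (cv$sd < 0) stop("covariate SDs must be >= 0")
  structure(list(measures = measures, covariates = covariates,
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "effects_spec")
}

#' Draw a synthetic two-group ROI table
#'
#' Gaussian draws per group and measure with the specified means and SDs,
#' plus covariates drawn from their shared distribution.  Deterministic
#' given the spec seed.
#'
#' @param effects An [effects_spec()].
#' @return data.frame with `animal_id`, `group` and one column per measure
#'   and covariate.
#' @export
make_roi_table <- function(effects) {
  stopifnot(inherits(effects, "effects_spec"))
  set.seed(effects$seed)
  n <- effects$n_per_group
  out <- data.frame(
    animal_id = sprintf("A%02d", seq_len(2L * n)),
    group = rep(c("WT", "ARTE10"), each = n),
    stringsAsFactors = FALSE)
  for (mn in names(effects$measures)) {
    m <- effects$measures[[mn]]
    out[[mn]] <- c(stats::rnorm(n, m$mean_wt, m$sd),
                   stats::rnorm(n, m$mean_arte10, m$sd))
  }
  for (cn in names(effects$covariates)) {
    cv <- effects$covariates[[cn]]
    out[[cn]] <- stats::rnorm(2L * n, cv$mean, cv$sd)
  }
  validate_roi_table(out)
}
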