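# Stage-wise pipeline driver.  Each stage reads and writes NIfTI + JSON (and
# CSV for tables) inside one working directory, so a study can be processed
# as: phantom -> simulate -> b0map -> b1map -> t1map -> fitz -> arex ->
# roistats.  Every sidecar carries the config hash and seed.

#' Fit the Lorentzian background voxel-by-voxel
#'
#' Normalized Z-stack in, per-voxel fitted parameter maps out.  If a B0 map
#' is given, each voxel's spectrum is resampled onto the nominal offsets
#' with [apply_b0_shift()] before fitting.
#'
#' @param z Voxel array (grid x offsets last) of normalized Z-values.
#' @param offsets Offsets (ppm).
#' @param model A [lorentzian_model()] or label.
#' @param exclusion Solute exclusion windows (see [fit_multipool()]).
#' @param b0_map Optional per-voxel B0 shift (ppm).
#' @param mask Optional logical mask of voxels to fit.
#' @return List with `params` (array: grid x 3*ncomp, columns
#'   `<component>.<par>`), `converged` (logical), `residual_norm`.
#' @export
fit_zstack <- function(z, offsets, model = "threepool_sym",
                       exclusion = c(1.6, 4.0), b0_map = NULL, mask = NULL) {
  if (is.character(model)) model <- lorentzian_model(model)
  m <- flatten_stack(z)
  nv <- nrow(m)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  mask <- as.logical(mask)
  pv <- model_par_vectors(model)
  np <- length(pv$sv)
  params <- matrix(NA_real_, nv, np, dimnames = list(NULL, pv$names))
  converged <- rep(FALSE, nv)
  rnorm_ <- rep(NA_real_, nv)
  for (v in which(mask)) {
    zs <- tryCatch(zspectrum(offsets, m[v, ]), error = function(e) NULL)
    if (is.null(zs)) next
    if (!is.null(b0_map) && is.finite(b0_map[v]) && b0_map[v] != 0)
      zs <- tryCatch(apply_b0_shift(zs, b0_map[v]), error = function(e) NULL)
    if (is.null(zs)) next
    fit <- tryCatch(fit_multipool(zs, model, exclusion = exclusion),
                    error = function(e) NULL)
    if (is.null(fit)) next
    params[v, ] <- as.vector(t(coef(fit)))
    converged[v] <- fit$converged
    rnorm_[v] <- fit$residual_norm
  }
  list(params = params, converged = restore_shape(converged, z),
       residual_norm = restore_shape(rnorm_, z), model = model)
}

baseline_values <- function(par_row, offsets, ncomp) {
  eval_multipool(par_row, offsets, ncomp)
}

#' Voxel-wise AREX maps from a fitted Z-stack
#'
#' For each voxel: inverse subtraction of the fitted background, AREX
#' asymmetry scaled by the voxel T1, read-out at the requested targets, and
#' optional linear B1 correction.
#'
#' @param z Voxel array of (B0-corrected) normalized Z-values, offsets last.
#' @param offsets Offsets (ppm).
#' @param fit Result of [fit_zstack()] on the same stack.
#' @param t1_map Per-voxel T1 (s).
#' @param b1_ratio_map Optional per-voxel B1 ratio for
#'   [b1_linear_correct()].
#' @param b0_map Optional per-voxel B0 shift (applied as in
#'   [fit_zstack()], so measured and fitted spectra share the nominal axis).
#' @param targets Named target offsets (ppm); default [arex_targets()].
#' @param mask Optional logical mask.
#' @return List with one map per target (named `AREX_<target>`), plus
#'   `mask` of valid voxels.
#' @export
arex_maps <- function(z, offsets, fit, t1_map, b1_ratio_map = NULL,
                      b0_map = NULL, targets = arex_targets(), mask = NULL) {
  m <- flatten_stack(z)
  nv <- nrow(m)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  mask <- as.logical(mask) & as.logical(fit$converged) &
    is.finite(as.numeric(t1_map)) & as.numeric(t1_map) > 0
  ncomp <- length(fit$model$components)
  out <- lapply(targets, function(tg) rep(NA_real_, nv))
  for (v in which(mask)) {
    zs <- zspectrum(offsets, m[v, ])
    if (!is.null(b0_map) && is.finite(b0_map[v]) && b0_map[v] != 0) {
      zs <- tryCatch(apply_b0_shift(zs, b0_map[v]), error = function(e) NULL)
      if (is.null(zs)) { mask[v] <- FALSE; next }
    }
    zf <- zspectrum(offsets, baseline_values(fit$params[v, ], offsets, ncomp))
    ok <- !is.na(zs$z)
    R <- inverse_difference(zspectrum(zs$offsets[ok], zs$z[ok]),
                            zspectrum(zf$offsets[ok], zf$z[ok]))
    ax <- tryCatch(arex_asymmetry(R, as.numeric(t1_map)[v]),
                   error = function(e) NULL)
    if (is.null(ax)) { mask[v] <- FALSE; next }
    for (tn in names(targets)) {
      out[[tn]][v] <- tryCatch(as.numeric(metabolite_arex(ax, targets[[tn]])),
                               error = function(e) NA_real_)
    }
  }
  if (!is.null(b1_ratio_map)) {
    for (tn in names(targets)) {
      bc <- b1_linear_correct(out[[tn]], as.numeric(b1_ratio_map))
      out[[tn]] <- bc$corrected
      mask <- mask & bc$mask
    }
  }
  maps <- lapply(out, restore_shape, stack = z)
  names(maps) <- paste0("AREX_", names(targets))
  c(maps, list(mask = restore_shape(mask, z)))
}

pipe_log <- function(dir, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  cat(line, "\n", sep = "", file = file.path(dir, "pipeline.log"),
      append = TRUE)
  message(line)
}

need_artifact <- function(dir, name, stage_hint) {
  p <- file.path(dir, name)
  if (!file.exists(p) && !file.exists(paste0(p, ".nii.gz")))
    stop(sprintf("missing artifact '%s' in %s; run the '%s' stage first",
                 name, dir, stage_hint))
  p
}

write_map <- function(map, dir, name, cfg, seed, extra = list()) {
  write_stack(array(map, c(dim(map), 1L)), file.path(dir, name),
              offsets = 0, units = "ppm",
              extra = c(list(config_hash = attr(cfg, "config_hash"),
                             seed = seed, kind = name), extra))
}

read_map <- function(dir, name, stage_hint) {
  p <- need_artifact(dir, paste0(name, ".nii.gz"), stage_hint)
  b <- read_stack(p)
  array(b$data, dim(b$data)[1:2])
}

#' Run one pipeline stage
#'
#' Subcommands: `phantom` (build the synthetic phantom and write its truth
#' maps), `simulate` (simulate all acquisitions of the study), `b0map`
#' (WASSR), `b1map` (double angle), `t1map` (variable TR), `fitz`
#' (voxel-wise Lorentzian fits for the high- and low-power stacks), `arex`
#' (AREX metabolite maps with B1 correction) and `roistats` (ROI summary of
#' this study plus, when a multi-animal ROI table CSV is present or
#' supplied, the group-comparison table).  Stages communicate through files
#' in `dir`; every sidecar carries the seed and config hash, and a
#' `pipeline.log` records each step.
#'
#' @param subcommand One of the stage names above.
#' @param dir Working directory (created if needed).
#' @param config An `arexcest_config`, a path to one, or `NULL` for
#'   defaults.
#' @param seed Integer seed overriding the config seed.
#' @param table Optional path to a per-animal ROI table CSV for `roistats`.
#' @return Invisibly, a list of the artifacts written.
#' @export
run_pipeline <- function(subcommand, dir, config = NULL, seed = NULL,
                         table = NULL) {
  subcommand <- match.arg(subcommand,
                          c("phantom", "simulate", "b0map", "b1map", "t1map",
                            "fitz", "arex", "roistats"))
  cfg <- if (inherits(config, "arexcest_config")) config
         else load_config(config)
  if (is.null(seed)) seed <- cfg$seed
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pipe_log(dir, "stage=%s seed=%d config=%s", subcommand, seed,
           attr(cfg, "config_hash"))
  ph_spec <- phantom_spec(n = cfg$phantom$n, b0_amp = cfg$phantom$b0_amp,
                          b1_amp = cfg$phantom$b1_amp,
                          noise_sigma = cfg$phantom$noise_sigma, seed = seed)
  mk_protocols <- function() list(
    glu = glu_protocol(cfg$protocols$glu$b1_amp, cfg$protocols$glu$t_sat,
                       cfg$protocols$glu$tr, b0 = cfg$b0),
    cr = cr_protocol(cfg$protocols$cr$b1_amp, cfg$protocols$cr$t_sat,
                     cfg$protocols$cr$tr, b0 = cfg$b0),
    wassr = wassr_protocol(cfg$protocols$wassr$b1_amp,
                           cfg$protocols$wassr$t_sat,
                           cfg$protocols$wassr$tr, b0 = cfg$b0))
  arts <- character()
  if (subcommand == "phantom") {
    ph <- make_phantom(ph_spec)
    write_map(ph$class_map + 0, dir, "class_map", cfg, seed,
              list(classes = ph$class_names))
    write_map(ph$t1_map, dir, "t1_truth", cfg, seed)
    write_map(ph$b0_map, dir, "b0_truth", cfg, seed)
    write_map(ph$b1_map, dir, "b1_truth", cfg, seed)
    arts <- c("class_map", "t1_truth", "b0_truth", "b1_truth")
  } else if (subcommand == "simulate") {
    ph <- make_phantom(ph_spec)
    st <- simulate_study(ph, protocols = mk_protocols(), seed = seed)
    prov <- list(config_hash = attr(cfg, "config_hash"), seed = seed)
    write_stack(st$glu$data, file.path(dir, "glu_stack"), st$glu$offsets,
                extra = c(prov, list(b1_amp = st$glu$protocol$b1_amp,
                                     t_sat = st$glu$protocol$t_sat)))
    write_map(st$glu$ref, dir, "glu_ref", cfg, seed)
    write_stack(st$cr$data, file.path(dir, "cr_stack"), st$cr$offsets,
                extra = c(prov, list(b1_amp = st$cr$protocol$b1_amp,
                                     t_sat = st$cr$protocol$t_sat,
                                     n_offsets_printed_enumeration =
                                       length(st$cr$offsets))))
    write_map(st$cr$ref, dir, "cr_ref", cfg, seed)
    write_stack(st$wassr$data, file.path(dir, "wassr_stack"),
                st$wassr$offsets, extra = prov)
    write_map(st$dam$img_alpha, dir, "dam_alpha", cfg, seed)
    write_map(st$dam$img_2alpha, dir, "dam_2alpha", cfg, seed)
    write_stack(st$vtr$data, file.path(dir, "vtr_stack"), st$vtr$tr,
                units = "s", extra = prov)
    arts <- c("glu_stack", "cr_stack", "wassr_stack", "dam_alpha",
              "dam_2alpha", "vtr_stack")
  } else if (subcommand == "b0map") {
    b <- read_stack(need_artifact(dir, "wassr_stack.nii.gz", "simulate"))
    mask0 <- apply(b$data, 1:2, function(x) any(x > 0))
    bm <- wassr_b0_map(b$data, b$offsets, mask = mask0)
    write_map(bm$b0_shift, dir, "b0_map", cfg, seed)
    write_map(bm$mask + 0, dir, "b0_mask", cfg, seed)
    arts <- c("b0_map", "b0_mask")
  } else if (subcommand == "b1map") {
    a1 <- read_map(dir, "dam_alpha", "simulate")
    a2 <- read_map(dir, "dam_2alpha", "simulate")
    da <- estimate_b1_double_angle(a1, a2, nominal_alpha = 30)
    write_map(da$b1_ratio, dir, "b1_map", cfg, seed)
    write_map(da$mask + 0, dir, "b1_mask", cfg, seed)
    arts <- c("b1_map", "b1_mask")
  } else if (subcommand == "t1map") {
    b <- read_stack(need_artifact(dir, "vtr_stack.nii.gz", "simulate"))
    mask0 <- apply(b$data, 1:2, function(x) any(x > 0))
    tm <- t1_map_variable_tr(b$data, b$offsets, mask = mask0)
    write_map(tm$t1, dir, "t1_map", cfg, seed)
    write_map(tm$mask + 0, dir, "t1_mask", cfg, seed)
    arts <- c("t1_map", "t1_mask")
  } else if (subcommand == "fitz") {
    b0m <- read_map(dir, "b0_map", "b0map")
    for (tag in c("glu", "cr")) {
      st <- read_stack(need_artifact(dir, paste0(tag, "_stack.nii.gz"),
                                     "simulate"))
      ref <- read_map(dir, paste0(tag, "_ref"), "simulate")
      nz <- normalize_stack(st$data, ref)
      model <- if (tag == "glu") "threepool_sym" else "fourpool_asym"
      ft <- fit_zstack(nz$z, st$offsets,
                       model = lorentzian_model(model,
                                                overrides = cfg$lorentzian),
                       exclusion = cfg$exclusion, b0_map = b0m,
                       mask = nz$mask)
      utils::write.csv(
        data.frame(voxel = seq_len(nrow(ft$params)), ft$params,
                   converged = as.numeric(ft$converged),
                   check.names = FALSE),
        file.path(dir, paste0(tag, "_fit_params.csv")), row.names = FALSE)
      # B0-corrected normalized stack for the arex stage
      zc <- nz$z
      m <- flatten_stack(zc)
      for (v in which(as.logical(nz$mask))) {
        if (is.finite(b0m[v]) && b0m[v] != 0) {
          zs <- tryCatch(apply_b0_shift(zspectrum(st$offsets, m[v, ]),
                                        b0m[v]), error = function(e) NULL)
          if (!is.null(zs)) m[v, ] <- zs$z
        }
      }
      write_stack(array(m, dim(nz$z)), file.path(dir, paste0(tag, "_zcorr")),
                  st$offsets,
                  extra = list(config_hash = attr(cfg, "config_hash"),
                               seed = seed, model = model))
      write_map(ft$converged + 0, dir, paste0(tag, "_fit_converged"), cfg,
                seed)
      arts <- c(arts, paste0(tag, c("_fit_params.csv", "_zcorr")))
    }
  } else if (subcommand == "arex") {
    t1m <- read_map(dir, "t1_map", "t1map")
    b1m <- read_map(dir, "b1_map", "b1map")
    for (tag in c("glu", "cr")) {
      st <- read_stack(need_artifact(dir, paste0(tag, "_zcorr.nii.gz"),
                                     "fitz"))
      pars <- utils::read.csv(file.path(dir, paste0(tag, "_fit_params.csv")),
                              check.names = FALSE)
      model <- lorentzian_model(if (tag == "glu") "threepool_sym"
                                else "fourpool_asym",
                                overrides = cfg$lorentzian)
      ft <- list(params = as.matrix(pars[, setdiff(names(pars),
                                                   c("voxel", "converged"))]),
                 converged = pars$converged > 0, model = model)
      targets <- if (tag == "glu") arex_targets()["Glu"]
                 else arex_targets()[c("PCr", "Cr")]
      am <- arex_maps(st$data, st$offsets, ft, t1m, b1_ratio_map = b1m,
                      targets = targets)
      for (tn in setdiff(names(am), "mask"))
        write_map(am[[tn]], dir, tn, cfg, seed)
      write_map(am$mask + 0, dir, paste0(tag, "_arex_mask"), cfg, seed)
      arts <- c(arts, setdiff(names(am), "mask"))
    }
  } else if (subcommand == "roistats") {
    t1m <- read_map(dir, "t1_map", "t1map")
    ph <- make_phantom(ph_spec)
    roi <- phantom_roi(ph, ph$class_names[length(ph$class_names)])
    rows <- list(measure = character(), mean = numeric(), n = numeric())
    summ <- data.frame()
    for (tn in c("AREX_Glu", "AREX_PCr", "AREX_Cr")) {
      p <- file.path(dir, paste0(tn, ".nii.gz"))
      if (!file.exists(p)) next
      mp <- read_map(dir, tn, "arex")
      rm_ <- roi_mean(mp, roi)
      summ <- rbind(summ, data.frame(measure = tn, roi_mean = rm_$mean,
                                     n_voxels = rm_$n))
    }
    rmt <- roi_mean(t1m * 1000, roi)  # report qT1 in ms
    summ <- rbind(summ, data.frame(measure = "qT1_ms", roi_mean = rmt$mean,
                                   n_voxels = rmt$n))
    utils::write.csv(summ, file.path(dir, "roi_summary.csv"),
                     row.names = FALSE)
    arts <- "roi_summary.csv"
    tbl_path <- if (!is.null(table)) table
                else file.path(dir, "roi_table.csv")
    if (!file.exists(tbl_path)) {
      # no multi-animal table supplied: draw the default synthetic cohort
      tbl <- make_roi_table(effects_spec(seed = seed))
      utils::write.csv(tbl, file.path(dir, "roi_table.csv"),
                       row.names = FALSE)
      tbl_path <- file.path(dir, "roi_table.csv")
    }
    tbl <- utils::read.csv(tbl_path, stringsAsFactors = FALSE)
    measures <- intersect(c("AREX_Glu", "AREX_PCr", "AREX_Cr", "qT1"),
                          names(tbl))
    covs <- intersect("roi_volume", names(tbl))
    gs <- roi_group_stats(tbl, measures, covariates = covs)
    utils::write.csv(gs, file.path(dir, "group_stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = attr(cfg, "config_hash"), seed = seed,
           measures = measures, covariates = covs),
      file.path(dir, "group_stats.json"), auto_unbox = TRUE, digits = NA)
    arts <- c(arts, "roi_table.csv", "group_stats.csv")
  }
  pipe_log(dir, "stage=%s done: %s", subcommand, paste(arts, collapse = ", "))
  invisible(list(stage = subcommand, artifacts = arts, dir = dir,
                 config_hash = attr(cfg, "config_hash"), seed = seed))
}
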