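# NIfTI + JSON-sidecar IO and pipeline configuration.

#' Write / read an image stack with a JSON sidecar
#'
#' A stack bundle is a voxel grid with a channel (offset) dimension last,
#' stored as NIfTI, plus a JSON sidecar of the same basename holding the
#' offsets (ppm), protocol parameters, units and provenance (seed, config
#' hash).  The round trip is lossless for the data and the sidecar fields.
#'
#' @param data Numeric array (channels last) or matrix.
#' @param path Output path; `.nii`/`.nii.gz` suffix added if absent, sidecar
#'   written as `<basename>.json`.
#' @param offsets Channel coordinates (ppm for saturation stacks, s for
#'   variable-TR stacks); length must match the last data dimension.
#' @param units Unit of the channel axis (`"ppm"`, `"s"`, or `"hz"`; Hz
#'   offsets are converted to ppm on read when `b0` is present in `extra`).
#' @param extra Named list merged into the sidecar (protocol, seed, hashes).
#' @return `write_stack`: the paths written (invisibly).  `read_stack`: a
#'   list with `data`, `offsets`, `units` and the sidecar fields.
#' @export
write_stack <- function(data, path, offsets, units = "ppm", extra = list()) {
  d <- dim(data)
  if (is.null(d)) stop("data must be an array")
  if (d[length(d)] != length(offsets))
    stop(sprintf("stack has %d channels but sidecar lists %d offsets",
                 d[length(d)], length(offsets)))
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(data), path)
  sidecar <- c(list(offsets = as.numeric(offsets), units = units,
                    n_offsets = length(offsets)), extra)
  json_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(image = path, sidecar = json_path))
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    path <- if (file.exists(paste0(path, ".nii.gz"))) paste0(path, ".nii.gz")
            else paste0(path, ".nii")
  }
  if (!file.exists(path)) stop(sprintf("image not found: %s", path))
  json_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(json_path))
    stop(sprintf("sidecar not found: %s (required)", json_path))
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))   # strip NIfTI attributes
  sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  d <- dim(data)
  # NIfTI readers drop trailing singleton dims; restore the channel axis
  if (length(sc$offsets) == 1L && d[length(d)] != 1L) {
    dim(data) <- c(d, 1L)
    d <- dim(data)
  }
  if (length(sc$offsets) && d[length(d)] != length(sc$offsets))
    stop(sprintf("stack has %d channels but sidecar lists %d offsets",
                 d[length(d)], length(sc$offsets)))
  if (identical(sc$units, "hz")) {
    if (is.null(sc$b0)) stop("offsets in Hz need a 'b0' sidecar field")
    sc$offsets <- sc$offsets / (sc$b0 * GAMMA_H / (2 * pi) * 1e-6)
    sc$units <- "ppm"
    warning("offsets converted from Hz to ppm using sidecar b0")
  }
  c(list(data = data), sc)
}

default_config <- function() {
  list(
    b0 = 9.4,
    protocols = list(
      glu = list(b1_amp = 5.9, t_sat = 1.0, tr = 5.0),
      cr = list(b1_amp = 1.47, t_sat = 3.5, tr = 5.0),
      wassr = list(b1_amp = 0.05, t_sat = 1.0, tr = 5.0)),
    exclusion = c(1.6, 4.0),
    z_clip = 1e-6,
    b1_clamp = c(0.5, 1.5),
    t1_bounds = c(0.05, 10),
    phantom = list(n = 12, b0_amp = 0, b1_amp = 0, noise_sigma = 0),
    lorentzian = NULL,   # overrides for lorentzian_model()
    seed = 1L)
}

#' Load and validate the pipeline configuration
#'
#' YAML (or JSON) configuration with defaults for every absent field: field
#' strength, the three saturation protocols, the Lorentzian model bounds
#' (shipped defaults), solute exclusion windows, clip/clamp values, T1 fit
#' bounds, phantom parameters and seed.  Unknown top-level keys are
#' rejected.
#'
#' @param path YAML/JSON file, or `NULL` for pure defaults.
#' @return Named list of class `arexcest_config`, with a `config_hash`
#'   attribute echoed into every pipeline output.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                             simplifyVector = TRUE)
            else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(cfg$lorentzian)) {
    for (comp in cfg$lorentzian) for (par in comp) {
      if (!is.null(par$lb) && !is.null(par$ub) && par$lb > par$ub)
        stop("invalid Lorentzian override: lb > ub")
    }
  }
  if (cfg$z_clip <= 0) stop("z_clip must be > 0")
  hash <- substr(paste(
    format(unlist(cfg), digits = 15), collapse = "|"), 1L, 1e6)
  attr(cfg, "config_hash") <- sprintf("%08x",
    sum(utf8ToInt(hash) * (seq_along(utf8ToInt(hash)) %% 97 + 1)) %% .Machine$integer.max)
  class(cfg) <- "arexcest_config"
  cfg
}

#' Save a configuration back to YAML
#' @param config An `arexcest_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  attr(x, "config_hash") <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}
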