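# Run configuration: documented physiological defaults, strict validation,
# YAML/JSON loading and a provenance hash.

#' Default run configuration
#'
#' Returns the fully defaulted configuration driving every pipeline stage.
#' The physiological preset encodes the study conditions: blood density
#' 1060 kg/m^3 and viscosity 4.5e-3 Pa s; resting inlet 69.54 mmHg at
#' 66.75 mL/min; hyperemic inlet 69.87 mmHg with every downstream
#' resistance reduced to 0.21 of its resting value; Murray exponent 7/3;
#' two-point calibration states bracketing the resting means (systole
#' 90 mmHg / 80 mL/min, diastole 55 mmHg / 55 mL/min).
#'
#' @param ... named overrides, e.g. `ffr_config(stenosis = list(ds = 0.75))`;
#'   partial lists are merged over the defaults.
#' @return A nested list of class `ffr_config`.
#' @examples
#' cfg <- ffr_config()
#' cfg$fluid$mu  # 4.5e-3
#' @export
ffr_config <- function(...) {
  base <- list(
    geometry = unclass(lad_config()),
    fluid = list(rho = 1060, mu = 4.5e-3),
    murray_exponent = 7 / 3,
    resting = list(pressure_mmhg = 69.54, inflow_ml_min = 66.75),
    hyperemic = list(pressure_mmhg = 69.87, factor = 0.21),
    calibration = list(
      mode = "two_point",
      systole = list(pressure_mmhg = 90, inflow_ml_min = 80),
      diastole = list(pressure_mmhg = 55, inflow_ml_min = 55),
      p0_mmhg = 0),
    stenosis = list(Kt = 1.52, shape = "cosine",
                    ds = 0.55, length_mm = 4, location = "A"),
    numerics = list(omega = 0.5, tol_pa = 0.1, max_iters = 500,
                    newton_damping = 0.7, inlet_total_pressure = TRUE),
    sampling = list(prox_offset_mm = 5, dist_offset_mm = 10)
  )
  overrides <- list(...)
  if (length(overrides)) {
    check_config_keys(overrides, base, path = "$")
    base <- utils::modifyList(base, overrides)
  }
  validate_config(base)
  structure(base, class = "ffr_config")
}

check_config_keys <- function(x, ref, path) {
  if (!is.list(x) || !is.list(ref)) return(invisible())
  unknown <- setdiff(names(x), names(ref))
  if (length(unknown)) {
    key <- unknown[1L]
    dists <- utils::adist(key, names(ref))
    hint <- if (min(dists) <= 3) {
      sprintf(" (did you mean \"%s\"?)", names(ref)[which.min(dists)])
    } else ""
    stop(sprintf("unknown config key %s.%s%s", path, key, hint),
         call. = FALSE)
  }
  for (k in intersect(names(x), names(ref))) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      check_config_keys(x[[k]], ref[[k]], paste0(path, ".", k))
    }
  }
  invisible()
}

validate_config <- function(cfg) {
  pos <- c("fluid.rho" = cfg$fluid$rho, "fluid.mu" = cfg$fluid$mu,
           "murray_exponent" = cfg$murray_exponent,
           "resting.pressure_mmhg" = cfg$resting$pressure_mmhg,
           "resting.inflow_ml_min" = cfg$resting$inflow_ml_min,
           "hyperemic.pressure_mmhg" = cfg$hyperemic$pressure_mmhg,
           "stenosis.Kt" = cfg$stenosis$Kt)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    stop(sprintf("config value %s must be a positive number", bad[1L]),
         call. = FALSE)
  }
  if (cfg$hyperemic$factor <= 0 || cfg$hyperemic$factor > 1) {
    stop("config value hyperemic.factor must lie in (0, 1]", call. = FALSE)
  }
  if (!cfg$calibration$mode %in% c("two_point", "single_point")) {
    stop("config value calibration.mode must be \"two_point\" or \"single_point\"",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML or JSON document (by extension), checks every key against
#' the known schema (unknown keys are rejected with a spelling suggestion),
#' merges it over [ffr_config()] defaults and validates physical constants.
#' An empty file yields the full default configuration.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `ffr_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml, .yml or .json file", call. = FALSE)
  }
  if (is.null(doc)) doc <- list()
  do.call(ffr_config, doc)
}

#' @export
print.ffr_config <- function(x, ...) {
  cat("<ffr_config>\n")
  cat(sprintf("  fluid: rho = %g kg/m^3, mu = %g Pa s\n",
              x$fluid$rho, x$fluid$mu))
  cat(sprintf("  resting: %g mmHg, %g mL/min; hyperemic: %g mmHg, factor %g\n",
              x$resting$pressure_mmhg, x$resting$inflow_ml_min,
              x$hyperemic$pressure_mmhg, x$hyperemic$factor))
  cat(sprintf("  stenosis default: DS %.0f%%, %g mm, location %s (Kt = %g)\n",
              100 * x$stenosis$ds, x$stenosis$length_mm, x$stenosis$location,
              x$stenosis$Kt))
  invisible(x)
}

#' Provenance hash of a configuration
#'
#' MD5 of the canonical JSON encoding; stamped into every sweep and
#' pipeline artifact so outputs can be traced to their exact inputs.
#'
#' @param config an `ffr_config` (or any list).
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
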