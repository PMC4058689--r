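# Parametric studies: the calibrated hyperemic model solved over grids of
# stenosis severity, location and length, plus the resistance sensitivity
# study and the revascularization-threshold interpolation.

#' Build and calibrate the study model
#'
#' Constructs the LAD emulator tree, computes the Murray split, calibrates
#' the outlet boundary conditions (two-point by default) and derives the
#' hyperemic set. All downstream sweeps start from this object.
#'
#' @param config an [ffr_config()].
#' @return List of class `ffr_case`: `tree`, `split`, `bcs_rest`,
#'   `bcs_hyper`, `fluid`, `config`.
#' @export
ffr_setup <- function(config = ffr_config()) {
  fluid <- fluid_properties(config$fluid$rho, config$fluid$mu)
  tree <- build_lad_tree(do.call(lad_config, config$geometry))
  split <- tree_murray_split(tree, config$murray_exponent)
  bcs_rest <- if (config$calibration$mode == "two_point") {
    calibrate_two_point(
      tree, split,
      state_sys = calibration_state("systole",
                                    config$calibration$systole$pressure_mmhg,
                                    config$calibration$systole$inflow_ml_min),
      state_dia = calibration_state("diastole",
                                    config$calibration$diastole$pressure_mmhg,
                                    config$calibration$diastole$inflow_ml_min),
      fluid = fluid,
      inlet_total_pressure = config$numerics$inlet_total_pressure)
  } else {
    calibrate_single_point(
      tree, split,
      state = calibration_state("rest", config$resting$pressure_mmhg,
                                config$resting$inflow_ml_min),
      p0_mmhg = config$calibration$p0_mmhg, fluid = fluid,
      inlet_total_pressure = config$numerics$inlet_total_pressure)
  }
  structure(list(tree = tree, split = split, bcs_rest = bcs_rest,
                 bcs_hyper = apply_hyperemia(bcs_rest, config$hyperemic$factor),
                 fluid = fluid, config = config),
            class = "ffr_case")
}

# one hyperemic (or resting) solve of a stenosed model; spec with ds = 0
# solves the baseline geometry but keeps the spec's sampling stations
solve_case <- function(case, spec, hyperemic = TRUE, bcs = NULL) {
  cfg <- case$config
  tree <- if (spec$ds > 0) insert_stenosis(case$tree, spec) else case$tree
  if (is.null(bcs)) bcs <- if (hyperemic) case$bcs_hyper else case$bcs_rest
  p_in <- if (hyperemic) cfg$hyperemic$pressure_mmhg else
    cfg$resting$pressure_mmhg
  prob <- network_problem(
    tree, bcs, p_in, fluid = case$fluid, Kt = cfg$stenosis$Kt,
    init_inflow_ml_min = cfg$resting$inflow_ml_min,
    numerics = cfg$numerics, split = case$split)
  sol <- solve_network(prob)
  ffr <- if (sol$converged) {
    as.numeric(compute_ffr(sol, tree, spec, cfg$sampling))
  } else NA_real_
  list(solution = sol, tree = tree, ffr = ffr)
}

location_s <- function(case, location) {
  loc <- case$tree$metadata$locations
  if (is.null(loc[[location]])) {
    stop(sprintf("unknown stenosis location '%s' (tree defines: %s)",
                 location, paste(names(loc), collapse = ", ")), call. = FALSE)
  }
  as.numeric(loc[[location]])
}

sweep_rows <- function(case, specs, var_name, var_values) {
  rows <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    res <- solve_case(case, specs[[k]])
    if (!res$solution$converged) {
      stop(sprintf("sweep aborted: solve did not converge at %s = %s",
                   var_name, format(var_values[[k]])), call. = FALSE)
    }
    q <- setNames(res$solution$outlet_table$Q_ml_min,
                  paste0("flow_", res$solution$outlet_table$outlet))
    rows[[k]] <- c(list(ffr_ct = res$ffr,
                        total_outflow_ml_min = sum(q)), as.list(q))
  }
  out <- cbind(setNames(data.frame(var_values), var_name),
               do.call(rbind, lapply(rows, as.data.frame)))
  structure(out, class = c("sweep_result", "data.frame"),
            sweep_var = var_name, config_hash = config_hash(case$config))
}

#' Sweep diameter stenosis
#'
#' Solves the calibrated hyperemic model for a 4 mm stenosis at Location A
#' over a grid of diameter-stenosis fractions. FFR decreases monotonically
#' with severity.
#'
#' @param config an [ffr_config()] (or a prebuilt [ffr_setup()] case).
#' @param ds_values grid of diameter-stenosis fractions; default
#'   `c(0.45, 0.55, 0.65, 0.75)`.
#' @return A `sweep_result` data.frame: one ordered row per grid value with
#'   `ffr_ct`, `total_outflow_ml_min` and per-outlet flows; the
#'   configuration hash is attached as an attribute. Any non-converged
#'   solve aborts the sweep naming the offending value.
#' @export
sweep_ds <- function(config = ffr_config(),
                     ds_values = c(0.45, 0.55, 0.65, 0.75)) {
  if (!length(ds_values)) stop("empty ds grid", call. = FALSE)
  case <- if (inherits(config, "ffr_case")) config else ffr_setup(config)
  cfg <- case$config
  s0 <- location_s(case, cfg$stenosis$location)
  specs <- lapply(sort(ds_values), function(ds)
    stenosis_spec(ds, cfg$stenosis$length_mm, s0, cfg$stenosis$shape))
  sweep_rows(case, specs, "ds", sort(ds_values))
}

#' Sweep stenosis location
#'
#' @param config an [ffr_config()] or [ffr_setup()] case.
#' @param locations named trunk locations, proximal to distal; default
#'   `c("A", "B", "C", "D")`. Unknown tokens are rejected.
#' @return A `sweep_result` (see [sweep_ds()]); FFR is non-decreasing from
#'   proximal to distal locations.
#' @export
sweep_location <- function(config = ffr_config(),
                           locations = c("A", "B", "C", "D")) {
  if (!length(locations)) stop("empty location grid", call. = FALSE)
  case <- if (inherits(config, "ffr_case")) config else ffr_setup(config)
  cfg <- case$config
  specs <- lapply(locations, function(loc)
    stenosis_spec(cfg$stenosis$ds, cfg$stenosis$length_mm,
                  location_s(case, loc), cfg$stenosis$shape))
  sweep_rows(case, specs, "location", locations)
}

#' Sweep stenosis length
#'
#' @param config an [ffr_config()] or [ffr_setup()] case.
#' @param lengths_mm stenosis lengths (mm); default `c(4, 8, 12, 16)`.
#'   A zero length is treated as no stenosis.
#' @return A `sweep_result` (see [sweep_ds()]); FFR is non-increasing in
#'   length, with a spread across the grid smaller than the spread across
#'   the severity grid.
#' @export
sweep_length <- function(config = ffr_config(),
                         lengths_mm = c(4, 8, 12, 16)) {
  if (!length(lengths_mm)) stop("empty length grid", call. = FALSE)
  case <- if (inherits(config, "ffr_case")) config else ffr_setup(config)
  cfg <- case$config
  s0 <- location_s(case, cfg$stenosis$location)
  specs <- lapply(sort(lengths_mm), function(L) {
    if (L == 0) stenosis_spec(0, cfg$stenosis$length_mm, s0, cfg$stenosis$shape)
    else stenosis_spec(cfg$stenosis$ds, L, s0, cfg$stenosis$shape)
  })
  sweep_rows(case, specs, "length_mm", sort(lengths_mm))
}

#' Resistance sensitivity of FFR
#'
#' Rescales every hyperemic outlet resistance by each factor, re-solves the
#' fixed stenosed model and reports the maximum relative FFR change against
#' the unscaled reference.
#'
#' @param config an [ffr_config()] or [ffr_setup()] case.
#' @param factors positive scale factors; default
#'   `c(0.29, 0.5, 0.76, 1, 1.24, 1.5, 1.71)`, spanning 24--71%
#'   perturbations in both directions.
#' @param spec the fixed lesion; default the config's stenosis (DS 55%,
#'   4 mm, Location A).
#' @return List of class `sensitivity_result`: `table` (factor, ffr_ct,
#'   rel_diff_pct) and `max_rel_diff_pct`.
#' @export
resistance_sensitivity <- function(config = ffr_config(),
                                   factors = c(0.29, 0.5, 0.76, 1,
                                               1.24, 1.5, 1.71),
                                   spec = NULL) {
  if (any(factors <= 0)) stop("scale factors must be positive", call. = FALSE)
  case <- if (inherits(config, "ffr_case")) config else ffr_setup(config)
  cfg <- case$config
  if (is.null(spec)) {
    spec <- stenosis_spec(cfg$stenosis$ds, cfg$stenosis$length_mm,
                          location_s(case, cfg$stenosis$location),
                          cfg$stenosis$shape)
  }
  ref <- solve_case(case, spec)$ffr
  ffr <- vapply(factors, function(f) {
    bcs <- case$bcs_hyper
    bcs$R_pa_s_per_m3 <- bcs$R_pa_s_per_m3 * f
    solve_case(case, spec, bcs = bcs)$ffr
  }, numeric(1))
  tab <- data.frame(factor = factors, ffr_ct = ffr,
                    rel_diff_pct = 100 * abs(ffr - ref) / ref)
  structure(list(table = tab, reference_ffr = ref,
                 max_rel_diff_pct = max(tab$rel_diff_pct)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> reference FFR = %.4f, max |dFFR|/FFR = %.2f%%\n",
              x$reference_ffr, x$max_rel_diff_pct))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Diameter stenosis at an FFR threshold
#'
#' Linear interpolation of the severity sweep at the revascularization
#' threshold, reported to the nearest percent diameter stenosis.
#'
#' @param sweep a [sweep_ds()] result with a strictly decreasing FFR column
#'   bracketing the threshold.
#' @param ffr_threshold threshold; default 0.8.
#' @return Percent diameter stenosis at the crossing (integer-valued).
#' @examples
#' \dontrun{threshold_ds(sweep_ds())}
#' @export
threshold_ds <- function(sweep, ffr_threshold = 0.8) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (attr(sweep, "sweep_var") != "ds") {
    stop("threshold_ds expects a diameter-stenosis sweep", call. = FALSE)
  }
  ds <- sweep$ds; ffr <- sweep$ffr_ct
  if (any(diff(ffr) >= 0)) {
    stop("FFR column must be strictly decreasing in DS", call. = FALSE)
  }
  hit <- which(abs(ffr - ffr_threshold) < 1e-12)
  if (length(hit)) return(round(100 * ds[hit[1L]]))
  if (ffr_threshold > max(ffr) || ffr_threshold < min(ffr)) {
    stop(sprintf("threshold %.3g not bracketed by the sweep (FFR range %.3f to %.3f)",
                 ffr_threshold, min(ffr), max(ffr)), call. = FALSE)
  }
  k <- max(which(ffr > ffr_threshold))
  frac <- (ffr[k] - ffr_threshold) / (ffr[k] - ffr[k + 1L])
  round(100 * (ds[k] + frac * (ds[k + 1L] - ds[k])))
}

#' Per-outlet flow table across a severity sweep
#'
#' Reorganizes a [sweep_ds()] result into a per-outlet flow table (one row
#' per severity, one column per outlet plus the total) and evaluates the
#' characteristic redistribution properties: total outlet flow decreasing
#' with severity and flow to the first branch ("branch steal")
#' non-decreasing.
#'
#' @param sweep a `sweep_result` from [sweep_ds()].
#' @return A data.frame with attribute `checks`, a named logical vector
#'   `total_flow_decreasing` / `branch_a_nondecreasing`.
#' @export
flow_report <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  flow_cols <- grep("^flow_", names(sweep), value = TRUE)
  tab <- sweep[, c(attr(sweep, "sweep_var"), flow_cols,
                   "total_outflow_ml_min")]
  names(tab) <- sub("^flow_", "", names(tab))
  checks <- c(
    total_flow_decreasing = all(diff(tab$total_outflow_ml_min) < 0) ||
      nrow(tab) < 2,
    branch_a_nondecreasing = !("a" %in% names(tab)) || nrow(tab) < 2 ||
      all(diff(tab$a) >= -1e-9))
  attr(tab, "checks") <- checks
  tab
}
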