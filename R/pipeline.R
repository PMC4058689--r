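# End-to-end pipeline driver shared by the command-line wrapper: executes
# build -> calibrate -> (stenose) -> solve -> report and serializes the
# artifacts with provenance (config hash + package version).

pipeline_log <- function(module, level, msg, log_path = NULL) {
  line <- sprintf("[%s] %s %s: %s", format(Sys.time(), "%H:%M:%S"),
                  level, module, msg)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
}

stamp <- function(config) {
  list(config_hash = config_hash(config),
       package_version = as.character(utils::packageVersion("ffrct")))
}

#' Run a pipeline command
#'
#' Executes one of the scripted pipelines on a configuration and writes its
#' artifacts (JSON results, CSV tables, tree files) under `out_dir`. Every
#' output carries the configuration hash and package version. A
#' non-converged solve raises an error (nonzero exit under the CLI).
#'
#' @param config an [ffr_config()].
#' @param command one of `"build_tree"`, `"calibrate"`, `"solve"`,
#'   `"sweep_ds"`, `"sweep_location"`, `"sweep_length"`, `"sensitivity"`,
#'   `"report"` (report = the three sweeps plus the threshold and flow
#'   table).
#' @param out_dir output directory (created if missing; must be writable).
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (paths written) and the in-memory `results`.
#' @export
run_pipeline <- function(config = ffr_config(),
                         command = c("solve", "build_tree", "calibrate",
                                     "sweep_ds", "sweep_location",
                                     "sweep_length", "sensitivity", "report"),
                         out_dir = ".") {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ suppressWarnings(cat("", file = probe)); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop(sprintf("output directory not writable: %s", out_dir),
                call. = FALSE)
  unlink(probe)
  log_path <- file.path(out_dir, "ffrct.log")
  artifacts <- character()
  results <- list()
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(c(x, stamp(config)), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    artifacts <<- c(artifacts, path)
  }
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    artifacts <<- c(artifacts, path)
  }

  pipeline_log("pipeline", "INFO", sprintf("command '%s'", command), log_path)
  case <- NULL
  need_case <- command != "build_tree"
  if (need_case) {
    pipeline_log("calibration", "INFO", "building and calibrating the model",
                 log_path)
    case <- ffr_setup(config)
  }

  if (command == "build_tree") {
    tree <- build_lad_tree(do.call(lad_config, config$geometry))
    path <- file.path(out_dir, "tree.json")
    write_tree(tree, path)
    export_centerline(tree, file.path(out_dir, "centerline.csv"), "csv")
    artifacts <- c(artifacts, path, file.path(out_dir, "centerline.csv"))
    results$tree <- tree
  } else if (command == "calibrate") {
    write_bcs(case$bcs_rest, file.path(out_dir, "bcs_rest.json"))
    write_bcs(case$bcs_hyper, file.path(out_dir, "bcs_hyperemic.json"))
    artifacts <- c(artifacts, file.path(out_dir, "bcs_rest.json"),
                   file.path(out_dir, "bcs_hyperemic.json"))
    results$bcs <- case$bcs_hyper
  } else if (command == "solve") {
    cfg <- case$config
    spec <- stenosis_spec(cfg$stenosis$ds, cfg$stenosis$length_mm,
                          location_s(case, cfg$stenosis$location),
                          cfg$stenosis$shape)
    res <- solve_case(case, spec)
    if (!res$solution$converged) {
      stop("network solve did not converge", call. = FALSE)
    }
    pipeline_log("network", "INFO",
                 sprintf("converged in %d outer iterations, FFR = %.4f",
                         res$solution$iterations, res$ffr), log_path)
    emit_json(list(converged = res$solution$converged,
                   iterations = res$solution$iterations,
                   ffr_ct = res$ffr,
                   inlet_flow_ml_min = res$solution$q_in_m3s / M3S_PER_MLMIN,
                   outlets = res$solution$outlet_table[
                     , c("outlet", "Q_ml_min", "P_mmhg")]),
              "results.json")
    emit_csv(pressure_pullback(res$solution, res$tree, 200), "pullback.csv")
    results$solve <- res
  } else if (command %in% c("sweep_ds", "sweep_location", "sweep_length")) {
    sw <- switch(command,
                 sweep_ds = sweep_ds(case),
                 sweep_location = sweep_location(case),
                 sweep_length = sweep_length(case))
    emit_csv(as.data.frame(sw), paste0(command, ".csv"))
    emit_json(list(sweep = attr(sw, "sweep_var"),
                   ffr_ct = sw$ffr_ct), paste0(command, ".json"))
    results$sweep <- sw
  } else if (command == "sensitivity") {
    sens <- resistance_sensitivity(case)
    emit_csv(sens$table, "sensitivity.csv")
    emit_json(list(max_rel_diff_pct = sens$max_rel_diff_pct),
              "sensitivity.json")
    results$sensitivity <- sens
  } else if (command == "report") {
    sw_ds <- sweep_ds(case)
    sw_loc <- sweep_location(case)
    sw_len <- sweep_length(case)
    emit_csv(as.data.frame(sw_ds), "sweep_ds.csv")
    emit_csv(as.data.frame(sw_loc), "sweep_location.csv")
    emit_csv(as.data.frame(sw_len), "sweep_length.csv")
    emit_csv(flow_report(sw_ds), "flow_report.csv")
    emit_json(list(threshold_ds_pct = threshold_ds(sw_ds),
                   ffr_vs_ds = sw_ds$ffr_ct,
                   ffr_vs_location = sw_loc$ffr_ct,
                   ffr_vs_length = sw_len$ffr_ct), "report.json")
    results$report <- list(ds = sw_ds, location = sw_loc, length = sw_len)
  }
  pipeline_log("pipeline", "INFO",
               sprintf("wrote %d artifact(s)", length(artifacts)), log_path)
  invisible(list(status = 0L, artifacts = artifacts, results = results))
}
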