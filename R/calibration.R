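# Two-point calibration of the downstream-vasculature outlet boundary
# conditions: each outlet closure is P = R Q + P0, with (R, P0) fitted from
# two steady baseline solves under Murray-prescribed outlet flows, then
# scaled for hyperemia.

#' Define a steady calibration state
#'
#' @param label e.g. `"systole"`, `"diastole"`, `"rest"`.
#' @param pressure_mmhg inlet pressure (mmHg, > 0).
#' @param inflow_ml_min total inflow (mL/min, > 0).
#' @return List of class `calibration_state`.
#' @export
calibration_state <- function(label, pressure_mmhg, inflow_ml_min) {
  if (pressure_mmhg <= 0 || inflow_ml_min <= 0) {
    stop("calibration state requires positive pressure and inflow",
         call. = FALSE)
  }
  structure(list(label = label, pressure_mmhg = pressure_mmhg,
                 inflow_ml_min = inflow_ml_min),
            class = "calibration_state")
}

# exact 2x2 linear fit of the outlet closure through two (Q, P) states
fit_outlet_bc <- function(q1_m3s, p1_pa, q2_m3s, p2_pa) {
  if (abs(q1_m3s - q2_m3s) < 1e-18) {
    stop("degenerate calibration: the two states have identical outlet flows",
         call. = FALSE)
  }
  R <- (p1_pa - p2_pa) / (q1_m3s - q2_m3s)
  list(R = R, p0 = p1_pa - R * q1_m3s)
}

# one prescribed-flow baseline solve for a calibration state
calibration_solve <- function(net, tree, split, state, inlet_total_pressure) {
  q_out <- assign_baseline_flows(tree, split, state$inflow_ml_min) *
    M3S_PER_MLMIN
  p_in <- mmhg_to_pa(state$pressure_mmhg)
  if (inlet_total_pressure) {
    v <- sum(q_out) / net$inlet_area_m2
    p_in <- p_in - 0.5 * net$fluid$rho * v^2
  }
  solve_prescribed_flows(net, q_out, p_in)
}

#' Calibrate outlet resistances from two steady states
#'
#' Solves the baseline (stenosis-free) network once per state with
#' Murray-prescribed outlet flows and the state's inlet pressure, giving a
#' `(Q_i, P_i)` pair per outlet per state; then fits the outlet closure
#' exactly: `R_i = (P_i^1 - P_i^2) / (Q_i^1 - Q_i^2)` and
#' `P0_i = P_i^1 - R_i Q_i^1`. Re-imposing the fitted boundary conditions at
#' either state reproduces the Murray-prescribed flows.
#'
#' `P0` is an affine closure parameter and is allowed to be negative;
#' the fit is rejected only when `R <= 0` or `P0` reaches the smaller of
#' the two calibration pressures at that outlet (inconsistent states).
#'
#' @param tree the baseline [coronary_tree()] (no stenosis).
#' @param split a `flow_split` over the tree's outlets (default Murray).
#' @param state_sys,state_dia the two [calibration_state()]s; they must
#'   prescribe distinct total inflows.
#' @param fluid a [fluid_properties()].
#' @param inlet_total_pressure subtract the inlet dynamic head from the
#'   stated pressures (default TRUE, consistent with [solve_network()]).
#' @return Object of class `outlet_bcs`: data.frame with columns `outlet`,
#'   `R_pa_s_per_m3`, `p0_pa`, `p0_mmhg`; attribute `states` records the
#'   calibration inputs.
#' @export
calibrate_two_point <- function(tree, split = tree_murray_split(tree),
                                state_sys, state_dia,
                                fluid = fluid_properties(),
                                inlet_total_pressure = TRUE) {
  stopifnot(inherits(tree, "coronary_tree"),
            inherits(state_sys, "calibration_state"),
            inherits(state_dia, "calibration_state"))
  if (!is.null(tree$metadata$stenosis)) {
    stop("calibration must run on the baseline (stenosis-free) tree",
         call. = FALSE)
  }
  net <- tree_network(tree, fluid)
  s1 <- calibration_solve(net, tree, split, state_sys, inlet_total_pressure)
  s2 <- calibration_solve(net, tree, split, state_dia, inlet_total_pressure)
  rows <- lapply(tree$outlets, function(id) {
    fit <- fit_outlet_bc(s1$outlet_q[[id]], s1$outlet_p[[paste0("out:", id)]],
                         s2$outlet_q[[id]], s2$outlet_p[[paste0("out:", id)]])
    pmin_cal <- min(s1$outlet_p[[paste0("out:", id)]],
                    s2$outlet_p[[paste0("out:", id)]])
    if (fit$R <= 0) {
      stop(sprintf("calibration failure at outlet '%s': nonpositive resistance (inconsistent states)",
                   id), call. = FALSE)
    }
    if (fit$p0 >= pmin_cal) {
      stop(sprintf("calibration failure at outlet '%s': back pressure reaches the calibration pressure",
                   id), call. = FALSE)
    }
    data.frame(outlet = id, R_pa_s_per_m3 = fit$R, p0_pa = fit$p0,
               p0_mmhg = pa_to_mmhg(fit$p0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "states") <- list(state_sys, state_dia)
  class(out) <- c("outlet_bcs", "data.frame")
  out
}

#' Calibrate outlet resistances from a single state with fixed back pressure
#'
#' Alternative single-point mode: `R_i = (P_i - P0) / Q_i` with `P0` fixed
#' (0 or a configured venous pressure).
#'
#' @param tree baseline [coronary_tree()].
#' @param split a `flow_split` (default Murray).
#' @param state one [calibration_state()] (typically the resting mean).
#' @param p0_mmhg fixed back pressure (mmHg), default 0.
#' @param fluid a [fluid_properties()].
#' @param inlet_total_pressure as in [calibrate_two_point()].
#' @return An `outlet_bcs` object.
#' @export
calibrate_single_point <- function(tree, split = tree_murray_split(tree),
                                   state, p0_mmhg = 0,
                                   fluid = fluid_properties(),
                                   inlet_total_pressure = TRUE) {
  stopifnot(inherits(state, "calibration_state"))
  if (!is.null(tree$metadata$stenosis)) {
    stop("calibration must run on the baseline (stenosis-free) tree",
         call. = FALSE)
  }
  net <- tree_network(tree, fluid)
  s1 <- calibration_solve(net, tree, split, state, inlet_total_pressure)
  p0 <- mmhg_to_pa(p0_mmhg)
  rows <- lapply(tree$outlets, function(id) {
    p_i <- s1$outlet_p[[paste0("out:", id)]]
    q_i <- s1$outlet_q[[id]]
    if (p0 >= p_i) {
      stop(sprintf("calibration failure at outlet '%s': back pressure reaches the calibration pressure",
                   id), call. = FALSE)
    }
    data.frame(outlet = id, R_pa_s_per_m3 = (p_i - p0) / q_i, p0_pa = p0,
               p0_mmhg = p0_mmhg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "states") <- list(state)
  class(out) <- c("outlet_bcs", "data.frame")
  out
}

#' Apply hyperemic scaling to outlet boundary conditions
#'
#' Maximal vasodilation is modeled as a uniform reduction of every
#' downstream resistance to `factor` times its resting value; back
#' pressures are unchanged, and the input is not modified. The epicardial
#' boundary conditions themselves are stenosis-independent: those derived
#' on the baseline tree are applied unchanged to stenosed trees.
#'
#' @param bcs an `outlet_bcs` object.
#' @param factor hyperemia factor in (0, 1\]; default 0.21.
#' @return A new `outlet_bcs` with scaled resistances.
#' @examples
#' \dontrun{apply_hyperemia(bcs, 0.21)}
#' @export
apply_hyperemia <- function(bcs, factor = 0.21) {
  if (!is.numeric(factor) || factor <= 0 || factor > 1) {
    stop("hyperemia factor must lie in (0, 1]", call. = FALSE)
  }
  out <- bcs
  out$R_pa_s_per_m3 <- out$R_pa_s_per_m3 * factor
  attr(out, "hyperemia_factor") <- factor
  out
}

#' Write / read outlet boundary conditions as JSON
#'
#' @param bcs an `outlet_bcs` object.
#' @param path file path.
#' @return `read_bcs` returns an `outlet_bcs`; `write_bcs` returns `path`
#'   invisibly.
#' @export
write_bcs <- function(bcs, path) {
  doc <- lapply(seq_len(nrow(bcs)), function(k) {
    list(outlet = bcs$outlet[k], R_pa_s_per_m3 = bcs$R_pa_s_per_m3[k],
         p0_mmHg = pa_to_mmhg(bcs$p0_pa[k]))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bcs
#' @export
read_bcs <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- data.frame(outlet = doc$outlet,
                    R_pa_s_per_m3 = doc$R_pa_s_per_m3,
                    p0_pa = mmhg_to_pa(doc$p0_mmHg),
                    p0_mmhg = doc$p0_mmHg, stringsAsFactors = FALSE)
  class(out) <- c("outlet_bcs", "data.frame")
  out
}
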