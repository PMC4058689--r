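# Nonlinear flow-network assembly and the coupled steady solve: junction
# mass balance + segment pressure-drop laws inside a damped Newton loop,
# wrapped in the underrelaxed resistance-outlet fixed point
#   P_i^(n+1) = P_i^n + omega * (R_i Q_i^(n+1) + P0_i - P_i^n).

node_key <- function(seg, s) sprintf("%s@%.9g", seg, s)

# Build the network: one edge per junction-free span of each segment, each
# edge carrying its integrated Poiseuille coefficient (and the stenosis
# quadratic coefficient on the edge holding the throat), plus a cumulative
# viscous-resistance table for pullback sampling.
tree_network <- function(tree, fluid = fluid_properties(), Kt = 1.52) {
  st <- tree$metadata$stenosis
  edges <- list()
  for (id in names(tree$segments)) {
    seg <- tree$segments[[id]]
    att <- tree$junctions$s_mm[tree$junctions$parent == id]
    bp <- sort(unique(c(0, att, seg$length_mm)))
    from0 <- if (id == tree$inlet) {
      "inlet"
    } else {
      jr <- tree$junctions[tree$junctions$child == id, ]
      node_key(jr$parent, jr$s_mm)
    }
    for (k in seq_len(length(bp) - 1L)) {
      s1 <- bp[k]; s2 <- bp[k + 1L]
      from <- if (k == 1L) from0 else node_key(id, s1)
      is_end <- k == length(bp) - 1L
      to <- if (is_end && id %in% tree$outlets) paste0("out:", id)
            else node_key(id, s2)
      grid <- sort(unique(c(
        seg$profile[seg$profile[, 1L] >= s1 & seg$profile[, 1L] <= s2, 1L],
        seq(s1, s2, length.out = 200L))))
      dg <- segment_diameter(seg, grid)
      integrand <- 128 * fluid$mu / (pi * mm_to_m(dg)^4)
      cum <- c(0, cumsum(diff(mm_to_m(grid)) *
                           (head(integrand, -1) + tail(integrand, -1)) / 2))
      a_v <- cum[length(cum)]
      a_t <- 0; s_throat <- NA_real_
      if (!is.null(st) && st$ds > 0 && id == tree$inlet &&
          st$center_s_mm >= s1 - 1e-9 && st$center_s_mm <= s2 + 1e-9) {
        A_s <- pi * mm_to_m(st$throat_diameter_mm)^2 / 4
        A_0 <- pi * mm_to_m(st$normal_diameter_mm)^2 / 4
        a_t <- Kt * (fluid$rho / 2) * (1 / A_s - 1 / A_0)^2
        s_throat <- st$center_s_mm
      }
      edges[[length(edges) + 1L]] <- list(
        seg = id, s1 = s1, s2 = s2, from = from, to = to,
        law = segment_law(a_v, a_t,
                          if (a_t > 0) "stenosis_algebraic" else "poiseuille"),
        cum_s = grid, cum_av = cum, s_throat = s_throat)
    }
  }
  from <- vapply(edges, `[[`, character(1), "from")
  to <- vapply(edges, `[[`, character(1), "to")
  nodes <- unique(c("inlet", from, to))
  outlet_edge <- match(paste0("out:", tree$outlets), to)
  names(outlet_edge) <- tree$outlets
  # accumulate the set of outlets fed by each edge (reverse topological)
  downstream <- vector("list", length(edges))
  remaining <- seq_along(edges)
  while (length(remaining)) {
    done <- logical(0)
    for (e in remaining) {
      kids <- which(from == to[[e]])
      if (startsWith(to[[e]], "out:")) {
        downstream[[e]] <- sub("^out:", "", to[[e]])
        done <- c(done, e)
      } else if (all(!vapply(downstream[kids], is.null, logical(1)))) {
        downstream[[e]] <- unique(unlist(downstream[kids]))
        done <- c(done, e)
      }
    }
    if (!length(done)) stop("network is not a tree", call. = FALSE)
    remaining <- setdiff(remaining, done)
  }
  # topological edge order for pressure marching
  order <- integer(0)
  frontier <- "inlet"
  while (length(frontier)) {
    out_e <- which(from %in% frontier)
    order <- c(order, out_e)
    frontier <- setdiff(to[out_e], "")
  }
  inlet_d <- segment_diameter(tree$segments[[tree$inlet]], 0)
  structure(list(edges = edges, from = from, to = to, nodes = nodes,
                 outlets = tree$outlets, outlet_edge = outlet_edge,
                 downstream = downstream, topo = order,
                 inlet_area_m2 = pi * mm_to_m(inlet_d)^2 / 4,
                 fluid = fluid),
            class = "tree_network")
}

# Pressures under prescribed outlet flows (m^3/s, named by outlet): edge
# flows by downstream aggregation, node pressures by marching from the
# inlet static pressure. Used by the calibration solves.
solve_prescribed_flows <- function(net, outlet_flows_m3s, p_in_static_pa) {
  q <- vapply(net$downstream, function(ids) sum(outlet_flows_m3s[ids]),
              numeric(1))
  p <- setNames(rep(NA_real_, length(net$nodes)), net$nodes)
  p["inlet"] <- p_in_static_pa
  for (e in net$topo) {
    p[net$to[e]] <- p[net$from[e]] - law_dp(net$edges[[e]]$law, q[e])
  }
  list(node_p = p, edge_q = q,
       outlet_p = p[paste0("out:", net$outlets)],
       outlet_q = setNames(q[net$outlet_edge], names(net$outlet_edge)))
}

# Damped Newton on interior (junction) node pressures with inlet and outlet
# pressures held fixed. Returns edge flows and node pressures.
newton_network <- function(net, p_in_pa, p_out_pa, x0, damping = 0.7,
                           tol_rel = 1e-12, max_iter = 200L, q_ref = 1e-6) {
  interior <- setdiff(net$nodes, c("inlet", paste0("out:", net$outlets)))
  p <- setNames(rep(NA_real_, length(net$nodes)), net$nodes)
  p["inlet"] <- p_in_pa
  p[paste0("out:", net$outlets)] <- p_out_pa[net$outlets]
  p[interior] <- x0[interior]
  n <- length(interior)
  edge_q <- function(p) {
    vapply(seq_along(net$edges), function(e) {
      law_flow(net$edges[[e]]$law, p[net$from[e]] - p[net$to[e]])
    }, numeric(1))
  }
  if (n == 0L) {
    q <- edge_q(p)
    g <- vapply(seq_along(net$edges), function(e) {
      law_dq_ddp(net$edges[[e]]$law, q[e])
    }, numeric(1))
    return(list(p = p, q = q, converged = TRUE, iters = 0L,
                J = NULL, interior = interior, g = g))
  }
  in_e <- lapply(interior, function(nd) which(net$to == nd))
  out_e <- lapply(interior, function(nd) which(net$from == nd))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    q <- edge_q(p)
    r <- vapply(seq_len(n), function(k) {
      sum(q[in_e[[k]]]) - sum(q[out_e[[k]]])
    }, numeric(1))
    if (max(abs(r)) < tol_rel * q_ref) { converged <- TRUE; break }
    J <- matrix(0, n, n)
    g <- vapply(seq_along(net$edges), function(e) {
      law_dq_ddp(net$edges[[e]]$law, q[e])
    }, numeric(1))
    for (k in seq_len(n)) {
      for (e in in_e[[k]]) {   # q_e = g(p_from - p_k): d/dp_k = -g
        J[k, k] <- J[k, k] - g[e]
        m <- match(net$from[e], interior)
        if (!is.na(m)) J[k, m] <- J[k, m] + g[e]
      }
      for (e in out_e[[k]]) {  # -q_e with q_e = g(p_k - p_to)
        J[k, k] <- J[k, k] - g[e]
        m <- match(net$to[e], interior)
        if (!is.na(m)) J[k, m] <- J[k, m] + g[e]
      }
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    p[interior] <- p[interior] + damping * step
  }
  q <- edge_q(p)
  g <- vapply(seq_along(net$edges), function(e) {
    law_dq_ddp(net$edges[[e]]$law, q[e])
  }, numeric(1))
  # rebuild the Jacobian at the solution for outlet-sensitivity queries
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    for (e in in_e[[k]]) {
      J[k, k] <- J[k, k] - g[e]
      m <- match(net$from[e], interior)
      if (!is.na(m)) J[k, m] <- J[k, m] + g[e]
    }
    for (e in out_e[[k]]) {
      J[k, k] <- J[k, k] - g[e]
      m <- match(net$to[e], interior)
      if (!is.na(m)) J[k, m] <- J[k, m] + g[e]
    }
  }
  list(p = p, q = q, converged = converged, iters = it,
       J = J, interior = interior, g = g)
}

# sensitivity dQ_i/dP_i of each outlet flow to its own outlet pressure, all
# other outlet pressures and the inlet held fixed (from the network Jacobian)
outlet_sensitivity <- function(net, inner) {
  vapply(seq_along(net$outlets), function(k) {
    e <- net$outlet_edge[[k]]
    ge <- inner$g[e]
    feed <- net$from[e]
    m <- match(feed, inner$interior)
    if (is.na(m)) return(-ge)           # outlet fed straight from the inlet
    rhs <- rep(0, length(inner$interior))
    rhs[m] <- -ge                       # d r / d P_i
    v <- tryCatch(solve(inner$J, rhs), error = function(err) NULL)
    if (is.null(v)) return(-ge)
    ge * (v[m] - 1)
  }, numeric(1))
}

#' One underrelaxed outlet-pressure update
#'
#' The damped fixed-point step coupling the flow solve to the resistance
#' outlets: `p + omega * (rq_p0 - p) / (1 + omega * implicit_slope)`, where
#' `rq_p0 = R Q + P0` is the closure target. With `implicit_slope = 0` this
#' is the plain explicit update; [solve_network()] passes the outlet's flow
#' sensitivity `R |dQ/dP|` so the flow term is evaluated implicitly at the
#' new state, which keeps the same fixed point but is stable for large
#' outlet-to-network resistance ratios.
#'
#' @param p current outlet pressure (Pa).
#' @param rq_p0 closure target `R Q + P0` (Pa).
#' @param omega underrelaxation factor in (0, 1].
#' @param implicit_slope nonnegative implicit coupling slope.
#' @return Updated outlet pressure (Pa).
#' @examples
#' eq4_step(100, 90, 0.5)  # 95
#' @export
eq4_step <- function(p, rq_p0, omega, implicit_slope = 0) {
  p + omega * (rq_p0 - p) / (1 + omega * implicit_slope)
}

#' Assemble a network flow problem
#'
#' Bundles a tree, its per-edge pressure-drop laws, the inlet pressure and
#' the per-outlet resistance boundary conditions into a solvable problem.
#'
#' @param tree a [coronary_tree()] (baseline or stenosed).
#' @param bcs outlet boundary conditions from [calibrate_two_point()] /
#'   [apply_hyperemia()]: data.frame with columns `outlet`,
#'   `R_pa_s_per_m3`, `p0_pa`.
#' @param p_in_mmhg inlet pressure (mmHg). Interpreted as *total* pressure
#'   when `numerics$inlet_total_pressure` is `TRUE` (default): the dynamic
#'   head at the inlet cross-section is subtracted, using the current inlet
#'   flow, to obtain the static pressure each outer iteration.
#' @param fluid a [fluid_properties()].
#' @param Kt stenosis expansion-loss coefficient passed to the segment laws.
#' @param init_inflow_ml_min total flow used (with the Murray split) to
#'   initialize outlet flows and pressures.
#' @param numerics list overriding any of: `omega` (outlet underrelaxation,
#'   default 0.5), `tol_pa` (outer tolerance on outlet-pressure change,
#'   default 0.1 Pa), `max_iters` (default 500), `newton_damping` (default
#'   0.7), `newton_tol_rel` (default 1e-12), `inlet_total_pressure`
#'   (default TRUE).
#' @param split optional `flow_split` for the initialization (defaults to
#'   the tree's Murray split).
#' @return Object of class `network_problem`.
#' @export
network_problem <- function(tree, bcs, p_in_mmhg,
                            fluid = fluid_properties(), Kt = 1.52,
                            init_inflow_ml_min = 66.75,
                            numerics = list(), split = NULL) {
  stopifnot(inherits(tree, "coronary_tree"))
  bcs <- as.data.frame(bcs)
  if (!setequal(bcs$outlet, tree$outlets)) {
    stop("boundary conditions must cover exactly the tree's outlets",
         call. = FALSE)
  }
  num <- utils::modifyList(
    list(omega = 0.5, tol_pa = 0.1, max_iters = 500L,
         newton_damping = 0.7, newton_tol_rel = 1e-12,
         inlet_total_pressure = TRUE),
    numerics)
  if (num$omega <= 0 || num$omega > 1) {
    stop("underrelaxation factor omega must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(split)) split <- tree_murray_split(tree)
  init_q <- assign_baseline_flows(tree, split, init_inflow_ml_min) *
    M3S_PER_MLMIN
  structure(list(tree = tree, net = tree_network(tree, fluid, Kt),
                 bcs = bcs[match(tree$outlets, bcs$outlet), ],
                 p_in_pa = mmhg_to_pa(p_in_mmhg),
                 numerics = num, init_outlet_q = init_q, fluid = fluid),
            class = "network_problem")
}

#' Solve the coupled network / resistance-outlet problem
#'
#' Outer loop: with outlet pressures held fixed, the nonlinear network
#' (junction mass balance + segment laws) is solved for flows and pressures
#' by damped Newton; each outlet pressure is then relaxed toward its
#' resistance closure with factor `omega`,
#' `P_i <- P_i + omega (R_i Q_i + P0_i - P_i)`, until the largest outlet
#' pressure change falls below `tol_pa`.
#'
#' @param problem a [network_problem()].
#' @return Object of class `network_solution`: named node pressures (Pa),
#'   edge flows (m^3/s), an outlet table (id, flow, pressure, R, P0), the
#'   outlet-pressure iteration trace, `converged`, `iterations` and any
#'   `flags` (e.g. `"negative_inlet_flow"`). Non-convergence is flagged,
#'   never silently dropped.
#' @export
solve_network <- function(problem) {
  stopifnot(inherits(problem, "network_problem"))
  net <- problem$net
  num <- problem$numerics
  bcs <- problem$bcs
  R <- setNames(bcs$R_pa_s_per_m3, bcs$outlet)
  P0 <- setNames(bcs$p0_pa, bcs$outlet)
  q_out <- problem$init_outlet_q[net$outlets]
  q_in <- sum(q_out)
  q_ref <- max(abs(q_in), 1e-9)
  p_in_static <- function(qi) {
    if (num$inlet_total_pressure) {
      v <- max(qi, 0) / net$inlet_area_m2   # head correction for inflow only
      problem$p_in_pa - 0.5 * problem$fluid$rho * v^2
    } else problem$p_in_pa
  }
  marched <- solve_prescribed_flows(net, q_out, p_in_static(q_in))
  x0 <- marched$node_p
  p_out <- if (!is.null(num$init_outlet_p)) {
    num$init_outlet_p[net$outlets]
  } else marched$outlet_p
  names(p_out) <- net$outlets
  trace <- matrix(NA_real_, nrow = num$max_iters, ncol = length(net$outlets),
                  dimnames = list(NULL, net$outlets))
  converged <- FALSE
  inner <- NULL
  for (it in seq_len(num$max_iters)) {
    inner <- newton_network(net, p_in_static(q_in), p_out, x0,
                            damping = num$newton_damping,
                            tol_rel = num$newton_tol_rel, q_ref = q_ref)
    x0 <- inner$p
    q_out <- inner$q[net$outlet_edge]
    names(q_out) <- net$outlets
    q_in <- sum(inner$q[net$from == "inlet"])
    target <- R[net$outlets] * q_out + P0[net$outlets]
    slope <- R[net$outlets] * abs(outlet_sensitivity(net, inner))
    res_max <- max(abs(target - p_out))   # closure residual |R Q + P0 - P|
    p_new <- eq4_step(p_out, target, num$omega, slope)
    trace[it, ] <- p_new
    p_out <- p_new
    if (res_max < num$tol_pa && inner$converged) { converged <- TRUE; break }
  }
  flags <- character()
  if (q_in < 0) flags <- c(flags, "negative_inlet_flow")
  if (!inner$converged) flags <- c(flags, "newton_not_converged")
  if (!converged) flags <- c(flags, "outlet_coupling_not_converged")
  outlet_table <- data.frame(
    outlet = net$outlets,
    Q_m3s = unname(q_out),
    Q_ml_min = unname(q_out) / M3S_PER_MLMIN,
    P_pa = unname(inner$p[paste0("out:", net$outlets)]),
    P_mmhg = pa_to_mmhg(unname(inner$p[paste0("out:", net$outlets)])),
    R_pa_s_per_m3 = unname(R[net$outlets]),
    p0_pa = unname(P0[net$outlets]))
  structure(list(node_pressures = inner$p, edge_flows = inner$q,
                 outlet_table = outlet_table,
                 q_in_m3s = q_in,
                 p_in_static_pa = unname(inner$p["inlet"]),
                 p_in_total_pa = problem$p_in_pa,
                 trace = trace[seq_len(it), , drop = FALSE],
                 converged = converged, iterations = it, flags = flags,
                 net = net, tree = problem$tree),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf("<network_solution> %s in %d outer iteration(s)\n",
              if (x$converged) "converged" else
                paste("NOT converged:", paste(x$flags, collapse = ", ")),
              x$iterations))
  cat(sprintf("  inlet: %.2f mmHg static, %.2f mL/min\n",
              pa_to_mmhg(x$p_in_static_pa), x$q_in_m3s / M3S_PER_MLMIN))
  print(x$outlet_table[, c("outlet", "Q_ml_min", "P_mmhg")], digits = 4,
        row.names = FALSE)
  invisible(x)
}

# trunk static pressure at arclength s (vectorized): viscous drop follows
# each edge's cumulative Poiseuille integral; the expansion loss is applied
# as a localized drop at the throat.
trunk_pressure_at <- function(solution, s_mm) {
  net <- solution$net
  trunk_id <- solution$tree$inlet
  trunk_edges <- which(vapply(net$edges, function(e) e$seg == trunk_id,
                              logical(1)))
  vapply(s_mm, function(s) {
    e_idx <- NULL
    for (e in trunk_edges) {
      if (s >= net$edges[[e]]$s1 - 1e-9 && s <= net$edges[[e]]$s2 + 1e-9) {
        e_idx <- e; break
      }
    }
    if (is.null(e_idx)) {
      stop(sprintf("sampling point s = %g mm lies outside the trunk", s),
           call. = FALSE)
    }
    ed <- net$edges[[e_idx]]
    Q <- solution$edge_flows[e_idx]
    av_s <- approx(ed$cum_s, ed$cum_av, xout = s, rule = 2)$y
    p <- solution$node_pressures[ed$from] - av_s * Q
    if (ed$law$a_t > 0 && !is.na(ed$s_throat) && s >= ed$s_throat) {
      p <- p - ed$law$a_t * Q * abs(Q)
    }
    unname(p)
  }, numeric(1))
}

#' Compute FFR from a converged solution
#'
#' `FFR = P_d / P_a` with `P_a` the trunk static pressure at a configurable
#' offset proximal to the stenotic extent and `P_d` at an offset distal to
#' it. Sampling points are clipped to the trunk and never cross a junction:
#' they stop at the junction-adjacent trunk station.
#'
#' @param solution a converged [solve_network()] result.
#' @param tree the stenosed [coronary_tree()] that was solved.
#' @param spec the [stenosis_spec()] defining the lesion (used for the
#'   sampling positions; `ds = 0` gives the baseline ratio at the same
#'   stations).
#' @param sampling list with `prox_offset_mm` (default 5) and
#'   `dist_offset_mm` (default 10).
#' @return FFR (dimensionless, in (0, 1\] for forward flow), with
#'   attributes `p_a_mmhg`, `p_d_mmhg`, `s_a_mm`, `s_d_mm`.
#' @export
compute_ffr <- function(solution, tree, spec,
                        sampling = list(prox_offset_mm = 5,
                                        dist_offset_mm = 10)) {
  stopifnot(inherits(solution, "network_solution"),
            inherits(spec, "stenosis_spec"))
  if (!solution$converged) {
    stop("compute_ffr requires a converged solution", call. = FALSE)
  }
  trunk <- tree$segments[[tree$inlet]]
  ext <- stenosis_extent(spec)
  if (ext[1] < -1e-9 || ext[2] > trunk$length_mm + 1e-9) {
    stop("stenotic extent lies outside the trunk", call. = FALSE)
  }
  att <- tree$junctions$s_mm[tree$junctions$parent == tree$inlet]
  prev_j <- max(c(0, att[att <= ext[1] + 1e-9]))
  next_j <- min(c(trunk$length_mm, att[att >= ext[2] - 1e-9]))
  s_a <- max(ext[1] - sampling$prox_offset_mm, prev_j)
  s_d <- min(ext[2] + sampling$dist_offset_mm, next_j)
  p_a <- trunk_pressure_at(solution, s_a)
  p_d <- trunk_pressure_at(solution, s_d)
  ffr <- p_d / p_a
  attr(ffr, "p_a_mmhg") <- pa_to_mmhg(p_a)
  attr(ffr, "p_d_mmhg") <- pa_to_mmhg(p_d)
  attr(ffr, "s_a_mm") <- s_a
  attr(ffr, "s_d_mm") <- s_d
  ffr
}

#' Pressure pullback along the trunk
#'
#' Samples the trunk static pressure at `n_points` equally spaced
#' arclengths; monotone non-increasing for forward flow, with the steepest
#' gradient inside any stenotic extent.
#'
#' @param solution a converged [solve_network()] result.
#' @param tree the solved [coronary_tree()].
#' @param n_points number of samples (>= 2); 2 returns the trunk endpoints.
#' @return data.frame with `s_mm`, `p_mmhg` and `p_ratio` (pressure over the
#'   inlet static pressure).
#' @export
pressure_pullback <- function(solution, tree, n_points = 200) {
  stopifnot(inherits(solution, "network_solution"))
  if (!solution$converged) {
    stop("pressure_pullback requires a converged solution", call. = FALSE)
  }
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  trunk <- tree$segments[[tree$inlet]]
  s <- seq(0, trunk$length_mm, length.out = n_points)
  p <- trunk_pressure_at(solution, s)
  data.frame(s_mm = s, p_mmhg = pa_to_mmhg(p), p_ratio = p / p[1L])
}
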