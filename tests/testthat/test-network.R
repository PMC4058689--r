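test_that("a single tube matches the series-resistance closed form", {
  tube <- straight_tube(d = 3, L = 10)
  a_v <- poiseuille_law(tube$segments$tube)$a_v
  R <- 1e9; P0 <- 0; P_in <- 9270
  bcs <- data.frame(outlet = "tube", R_pa_s_per_m3 = R, p0_pa = P0)
  prob <- network_problem(tube, bcs, pa_to_mmhg(P_in),
                          numerics = list(inlet_total_pressure = FALSE,
                                          tol_pa = 1e-7),
                          init_inflow_ml_min = 10)
  sol <- solve_network(prob)
  expect_true(sol$converged)
  Q_ref <- P_in / (a_v + R)             # ~9.065e-6 m^3/s
  P_ref <- R * Q_ref                    # outlet pressure
  expect_equal(sol$outlet_table$Q_m3s, Q_ref, tolerance = 1e-9)
  expect_equal(sol$outlet_table$P_pa, P_ref, tolerance = 1e-9)
})

test_that("the underrelaxed update has the documented arithmetic and fixed point", {
  # single explicit step
  expect_equal(eq4_step(100, 90, 0.5), 95)
  # the implicit slope damps the step but preserves the fixed point
  expect_equal(eq4_step(100, 100, 0.5, implicit_slope = 250), 100)
  expect_lt(abs(eq4_step(100, 90, 0.5, implicit_slope = 250) - 100),
            abs(eq4_step(100, 90, 0.5) - 100))
})

test_that("initializing outlets at the converged pressures converges in one iteration", {
  case <- study_case()
  tree <- insert_stenosis(case$tree, stenosis_spec(0.55, 4, 20))
  prob <- network_problem(tree, case$bcs_hyper, 69.87, fluid = case$fluid,
                          split = case$split,
                          numerics = list(inlet_total_pressure = FALSE))
  sol <- solve_network(prob)
  expect_true(sol$converged)
  p_star <- setNames(sol$outlet_table$P_pa, sol$outlet_table$outlet)
  prob2 <- network_problem(tree, case$bcs_hyper, 69.87, fluid = case$fluid,
                           split = case$split,
                           numerics = list(init_outlet_p = p_star,
                                           inlet_total_pressure = FALSE))
  sol2 <- solve_network(prob2)
  expect_true(sol2$converged)
  expect_equal(sol2$iterations, 1L)
  expect_equal(sol2$outlet_table$P_pa, sol$outlet_table$P_pa,
               tolerance = 1e-6)
})

test_that("junction mass is conserved to 1e-10 of the inlet flow", {
  case <- study_case()
  for (ds in c(0, 0.55, 0.75)) {
    tree <- if (ds > 0) insert_stenosis(case$tree, stenosis_spec(ds, 4, 20))
            else case$tree
    sol <- solve_network(network_problem(tree, case$bcs_hyper, 69.87,
                                         fluid = case$fluid,
                                         split = case$split))
    expect_true(sol$converged)
    net <- sol$net
    interior <- setdiff(net$nodes, c("inlet", paste0("out:", net$outlets)))
    imb <- vapply(interior, function(nd) {
      sum(sol$edge_flows[net$to == nd]) - sum(sol$edge_flows[net$from == nd])
    }, numeric(1))
    expect_lt(max(abs(imb)) / abs(sol$q_in_m3s), 1e-10)
    # outlet closure satisfied at convergence
    ot <- sol$outlet_table
    expect_lt(max(abs(ot$P_pa - (ot$R_pa_s_per_m3 * ot$Q_m3s + ot$p0_pa))),
              0.2)  # 2 x tol_pa
  }
})

test_that("the converged solution is independent of the relaxation factor", {
  case <- study_case()
  tree <- insert_stenosis(case$tree, stenosis_spec(0.55, 4, 20))
  sols <- lapply(c(0.1, 0.5, 1.0), function(om) {
    solve_network(network_problem(tree, case$bcs_hyper, 69.87,
                                  fluid = case$fluid, split = case$split,
                                  numerics = list(omega = om)))
  })
  expect_true(all(vapply(sols, `[[`, logical(1), "converged")))
  p <- vapply(sols, function(s) s$outlet_table$P_pa, numeric(8))
  expect_lt(max(apply(p, 1, function(x) diff(range(x)))), 10 * 0.1)
  expect_error(network_problem(tree, case$bcs_hyper, 69.87,
                               numerics = list(omega = 0)), "omega")
})

test_that("non-convergence and negative inlet flow are flagged, never silent", {
  case <- study_case()
  prob <- network_problem(case$tree, case$bcs_hyper, 69.87,
                          fluid = case$fluid, split = case$split,
                          numerics = list(max_iters = 2L))
  sol <- solve_network(prob)
  expect_false(sol$converged)
  expect_true("outlet_coupling_not_converged" %in% sol$flags)
  expect_error(compute_ffr(sol, case$tree, stenosis_spec(0, 4, 20)),
               "converged")
  expect_error(pressure_pullback(sol, case$tree), "converged")

  # an outlet reservoir above the inlet pressure drives reverse flow
  tube <- straight_tube()
  bcs <- data.frame(outlet = "tube", R_pa_s_per_m3 = 1e9,
                    p0_pa = mmhg_to_pa(200))
  rev <- solve_network(network_problem(tube, bcs, 70,
                                       init_inflow_ml_min = 10))
  expect_true("negative_inlet_flow" %in% rev$flags)
})

test_that("FFR is the sampled distal/proximal pressure ratio", {
  case <- study_case()
  spec <- stenosis_spec(0.55, 4, 20)
  tree <- insert_stenosis(case$tree, spec)
  sol <- solve_network(network_problem(tree, case$bcs_hyper, 69.87,
                                       fluid = case$fluid,
                                       split = case$split))
  ffr <- compute_ffr(sol, tree, spec)
  expect_gt(as.numeric(ffr), 0)
  expect_lte(as.numeric(ffr), 1)
  expect_equal(as.numeric(ffr),
               attr(ffr, "p_d_mmhg") / attr(ffr, "p_a_mmhg"))
  # sampling points clip at the adjacent junctions (a at 10 mm, b at 30 mm)
  expect_gte(attr(ffr, "s_a_mm"), 10)
  expect_lte(attr(ffr, "s_d_mm"), 30)
  # a baseline solve sampled at the same stations stays near unity
  sol0 <- solve_network(network_problem(case$tree, case$bcs_hyper, 69.87,
                                        fluid = case$fluid,
                                        split = case$split))
  expect_gte(as.numeric(compute_ffr(sol0, case$tree,
                                    stenosis_spec(0, 4, 20))), 0.95)
  # degenerate spec: identical sampling stations give exactly 1
  zero_len <- structure(list(ds = 0, length_mm = 1e-9, center_s_mm = 20,
                             shape = "cosine"), class = "stenosis_spec")
  sampling <- list(prox_offset_mm = 0, dist_offset_mm = 0)
  expect_equal(as.numeric(compute_ffr(sol0, case$tree, zero_len, sampling)), 1)
  expect_error(compute_ffr(sol0, case$tree, stenosis_spec(0.5, 4, 150)),
               "outside the trunk")
})

test_that("the pullback is monotone, additive and steepest inside the lesion", {
  case <- study_case()
  spec <- stenosis_spec(0.65, 4, 20)
  tree <- insert_stenosis(case$tree, spec)
  sol <- solve_network(network_problem(tree, case$bcs_hyper, 69.87,
                                       fluid = case$fluid,
                                       split = case$split))
  pb <- pressure_pullback(sol, tree, 401)
  expect_true(all(diff(pb$p_mmhg) <= 1e-9))            # non-increasing
  expect_equal(pb$p_ratio, pb$p_mmhg / pb$p_mmhg[1])
  # endpoints equal the inlet and distal trunk nodal pressures
  expect_equal(mmhg_to_pa(pb$p_mmhg[1]), unname(sol$node_pressures["inlet"]))
  expect_equal(mmhg_to_pa(pb$p_mmhg[401]),
               unname(sol$node_pressures["out:trunk"]), tolerance = 1e-6)
  # steepest drop lies within the stenotic extent [18, 22] mm
  grad <- -diff(pb$p_mmhg)
  s_mid <- (pb$s_mm[-1] + pb$s_mm[-401]) / 2
  expect_true(s_mid[which.max(grad)] >= 18 && s_mid[which.max(grad)] <= 22)
  # n_points = 2 returns the trunk endpoints only
  pb2 <- pressure_pullback(sol, tree, 2)
  expect_equal(pb2$s_mm, c(0, 100))
  expect_error(pressure_pullback(sol, tree, 1), ">= 2")
})
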