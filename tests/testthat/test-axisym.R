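fl <- fluid_properties()

test_that("a straight tube reproduces the Poiseuille solution", {
  d <- 3
  Q <- flow_at_reynolds(150, d)
  f <- solve_axisym(cbind(c(0, 30), c(d, d)), Q, fl,
                    grid = list(nr = 24, nz = 160, pad_up = 0.5,
                                pad_down = 0.5))
  expect_true(f$converged)
  # centerline / mean velocity = 2 within 1%
  i_mid <- round(length(f$z_m) / 2)
  u_mean <- Q / (pi * f$radius_m[i_mid]^2)
  expect_equal(f$uz[i_mid, 1] / u_mean, 2, tolerance = 0.01)
  # pressure drop within 2% of 128 mu L Q / (pi d^4)
  L <- diff(range(f$z_m))
  dp_ref <- 128 * fl$mu * L * Q / (pi * mm_to_m(d)^4)
  expect_equal(f$dp, dp_ref, tolerance = 0.02)
  # no recirculation anywhere
  expect_equal(unname(recirculation_metrics(f)),
               c(0, 0))
  expect_true(all(f$wall_shear_pa > 0))
})

test_that("cross-sectional flux is conserved along the tube", {
  tube <- straight_tube(d = 3, L = 24)
  spec <- stenosis_spec(0.55, 4, 12)
  prof <- insert_stenosis(tube, spec)$segments$tube$profile
  Q <- flow_at_reynolds(150, (1 - 0.55) * 3)
  f <- solve_axisym(prof, Q, fl, grid = list(nr = 32, nz = 256))
  expect_true(f$converged)
  stations <- round(seq(2, length(f$z_m) - 1, length.out = 11))
  flux <- vapply(stations, function(i) ffrct:::axisym_flux(f, i), numeric(1))
  # conservation: station-to-station variation well below 0.1%
  expect_lt(diff(range(flux)) / Q, 1e-3)
  # and the streamfunction flux is exact by construction
  expect_equal(2 * pi * (f$psi[2, ncol(f$psi)] - f$psi[2, 1]), Q,
               tolerance = 1e-12)
})

test_that("recirculation grows with severity and with Reynolds number", {
  tube <- straight_tube(d = 3, L = 24)
  Q <- flow_at_reynolds(280, (1 - 0.75) * 3)   # shared flow, laminar at both
  mets <- lapply(c(0.45, 0.75), function(ds) {
    prof <- insert_stenosis(tube, stenosis_spec(ds, 4, 12))$segments$tube$profile
    f <- solve_axisym(prof, Q, fl, grid = list(nr = 32, nz = 288))
    expect_true(f$converged)
    recirculation_metrics(f)
  })
  expect_gt(mets[[2]]["reattachment_mm"], mets[[1]]["reattachment_mm"])
  expect_gt(mets[[2]]["reversed_area_mm2"], mets[[1]]["reversed_area_mm2"])

  prof <- insert_stenosis(tube, stenosis_spec(0.5, 4, 12))$segments$tube$profile
  m_re <- lapply(c(100, 200), function(re) {
    f <- solve_axisym(prof, flow_at_reynolds(re, 1.5), fl,
                      grid = list(nr = 32, nz = 288))
    expect_true(f$converged)
    recirculation_metrics(f)
  })
  expect_gt(m_re[[2]]["reattachment_mm"], m_re[[1]]["reattachment_mm"])
})

test_that("pressure drop is grid-converged for the verification matrix", {
  tube <- straight_tube(d = 3, L = 24)
  for (ds in c(0, 0.45, 0.55)) {
    prof <- if (ds > 0) {
      insert_stenosis(tube, stenosis_spec(ds, 4, 12))$segments$tube$profile
    } else tube$segments$tube$profile
    Q <- flow_at_reynolds(300, (1 - ds) * 3)
    f1 <- solve_axisym(prof, Q, fl, grid = list(nr = 24, nz = 192))
    f2 <- solve_axisym(prof, Q, fl, grid = list(nr = 48, nz = 384))
    expect_true(f1$converged && f2$converged)
    expect_lt(abs(f2$dp - f1$dp) / abs(f2$dp), 0.02)
  }
})

test_that("the algebraic stenosis law tracks the axisymmetric drop within 30%", {
  tube <- straight_tube(d = 3, L = 24)
  for (ds in c(0.45, 0.55)) {
    spec <- stenosis_spec(ds, 4, 12)
    seg <- insert_stenosis(tube, spec)$segments$tube
    law <- stenosis_law(seg, spec, fl)
    for (re in c(100, 200)) {
      Q <- flow_at_reynolds(re, (1 - ds) * 3)
      f <- solve_axisym(seg$profile, Q, fl, grid = list(nr = 32, nz = 288))
      expect_true(f$converged)
      # add the straight padding drop the PDE domain includes
      pad_len <- diff(range(f$z_m)) - mm_to_m(24)
      dp_alg <- law_dp(law, Q) + 128 * fl$mu * pad_len * Q / (pi * 0.003^4)
      expect_lt(abs(dp_alg - f$dp) / f$dp, 0.30)
    }
  }
})

test_that("the laminar Reynolds cap and convergence flag are enforced", {
  prof <- cbind(c(0, 10), c(3, 3))
  expect_error(solve_axisym(prof, flow_at_reynolds(2500, 3), fl),
               "laminar")
  f <- solve_axisym(prof, flow_at_reynolds(150, 3), fl,
                    grid = list(nr = 16, nz = 64),
                    numerics = list(max_outer = 3L))
  expect_false(f$converged)
  expect_error(recirculation_metrics(f), "converged")
})

test_that("field export writes readable VTK and wall-shear CSV", {
  f <- solve_axisym(cbind(c(0, 10), c(3, 3)), flow_at_reynolds(80, 3), fl,
                    grid = list(nr = 16, nz = 64, pad_up = 0.5,
                                pad_down = 0.5))
  vtk <- withr::local_tempfile(fileext = ".vtk")
  export_axisym_field(f, vtk, "vtk")
  lines <- readLines(vtk)
  expect_match(lines[5], "DIMENSIONS 65 17 1")
  expect_true(any(grepl("SCALARS uz", lines)))
  csv <- withr::local_tempfile(fileext = ".csv")
  export_axisym_field(f, csv, "wall_shear_csv")
  tab <- read.csv(csv)
  expect_identical(names(tab), c("z_mm", "wall_shear_pa"))
  expect_equal(nrow(tab), 65L)
})
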