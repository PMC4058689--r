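fl <- fluid_properties()

test_that("integrated Poiseuille law matches the uniform-tube closed form", {
  seg <- vessel_segment("tube", 10, c(3, 3))
  law <- poiseuille_law(seg, fl)
  a_ref <- 128 * fl$mu * 0.01 / (pi * 0.003^4)   # 2.2636e7 Pa s/m^3
  expect_equal(law$a_v, a_ref, tolerance = 1e-10)
  expect_equal(law$a_t, 0)
  # at the resting inflow the drop is ~25 Pa (~0.19 mmHg)
  dp <- law_dp(law, mlmin_to_m3s(66.75))
  expect_equal(dp, a_ref * mlmin_to_m3s(66.75), tolerance = 1e-12)
  expect_equal(pa_to_mmhg(dp), 0.189, tolerance = 0.01)
})

test_that("Poiseuille resistance scales linearly in L and as d^-4", {
  a10 <- poiseuille_law(vessel_segment("a", 10, c(3, 3)), fl)$a_v
  a20 <- poiseuille_law(vessel_segment("a", 20, c(3, 3)), fl)$a_v
  expect_equal(a20 / a10, 2, tolerance = 1e-9)
  ahalf <- poiseuille_law(vessel_segment("a", 10, c(1.5, 1.5)), fl)$a_v
  expect_equal(ahalf / a10, 16, tolerance = 1e-9)
})

test_that("stenosis law reproduces the hand-computed expansion loss", {
  # d0 = 3 mm, ds = 0.75, Kt = 1.52: throat 0.75 mm
  tube <- straight_tube(d = 3, L = 30)
  spec <- stenosis_spec(0.75, 4, 15)
  st <- insert_stenosis(tube, spec)
  law <- stenosis_law(st$segments$tube, spec, fl, Kt = 1.52)
  A_s <- pi * 0.00075^2 / 4
  A_0 <- pi * 0.003^2 / 4
  a_t_ref <- 1.52 * (fl$rho / 2) * (1 / A_s - 1 / A_0)^2
  expect_equal(law$a_t, a_t_ref, tolerance = 1e-9)
  Q <- mlmin_to_m3s(66.75)
  expect_equal(law$a_t * Q^2, 4491, tolerance = 1e-3)  # ~4.5e3 Pa (~34 mmHg)
})

test_that("stenosis law reduces to Poiseuille when ds = 0 and is odd in Q", {
  tube <- straight_tube(d = 3, L = 30)
  spec0 <- stenosis_spec(0, 4, 15)
  st0 <- insert_stenosis(tube, spec0)
  law0 <- stenosis_law(st0$segments$tube, spec0, fl)
  ref <- poiseuille_law(tube$segments$tube, fl)
  expect_equal(law0$a_t, 0)
  expect_equal(law0$a_v, ref$a_v, tolerance = 1e-9)
  expect_identical(law0$provenance, "poiseuille")

  spec <- stenosis_spec(0.55, 4, 15)
  law <- stenosis_law(insert_stenosis(tube, spec)$segments$tube, spec, fl)
  for (Q in c(1e-7, 1e-6, 5e-6)) {
    expect_equal(law_dp(law, -Q), -law_dp(law, Q))
    expect_equal(law_flow(law, law_dp(law, Q)), Q, tolerance = 1e-12)
  }
})

test_that("stenosis drop dominates the clean tube and grows with severity", {
  tube <- straight_tube(d = 3, L = 30)
  clean <- poiseuille_law(tube$segments$tube, fl)
  Qs <- mlmin_to_m3s(c(5, 30, 66.75, 150))
  prev <- law_dp(clean, Qs)
  for (ds in c(0.15, 0.35, 0.45, 0.55, 0.65, 0.75)) {
    spec <- stenosis_spec(ds, 4, 15)
    law <- stenosis_law(insert_stenosis(tube, spec)$segments$tube, spec, fl)
    dp <- law_dp(law, Qs)
    expect_true(all(dp >= prev))          # nondecreasing in ds at fixed Q
    expect_true(all(diff(dp) > 0))        # strictly increasing in Q
    prev <- dp
  }
})

test_that("law constructor enforces its invariants", {
  expect_error(segment_law(-1), "a_v")
  expect_error(segment_law(1, -1), "a_t")
  expect_error(segment_law(1, 2, "poiseuille"), "stenosis-free")
})

test_that("axisym-tabulated law recovers Poiseuille for a straight tube", {
  seg <- vessel_segment("tube", 20, c(3, 3))
  flows <- flow_at_reynolds(c(60, 120, 180), 3)
  law <- tabulate_from_axisym(seg, fl, flows,
                              grid = list(nr = 24, nz = 128, pad_up = 1,
                                          pad_down = 2))
  ref <- poiseuille_law(seg, fl)$a_v
  expect_identical(law$provenance, "axisym_tabulated")
  expect_lt(abs(law$a_v - ref) / ref, 0.02)
  expect_lt(law$a_t * max(flows)^2, 0.05 * ref * max(flows))  # a_t ~ 0
})

test_that("axisym-tabulated law fits stenosed samples within 5%", {
  tube <- straight_tube(d = 3, L = 24)
  spec <- stenosis_spec(0.55, 4, 12)
  seg <- insert_stenosis(tube, spec)$segments$tube
  flows <- flow_at_reynolds(c(60, 130, 200), (1 - 0.55) * 3)
  law <- tabulate_from_axisym(seg, fl, flows,
                              grid = list(nr = 28, nz = 224))
  expect_lt(attr(law, "residual_rel"), 0.05)
  expect_gt(law$a_t, 0)
})

test_that("underdetermined or invalid flow grids are rejected", {
  seg <- vessel_segment("tube", 20, c(3, 3))
  expect_error(tabulate_from_axisym(seg, fl, 1e-6), "underdetermined")
  expect_error(tabulate_from_axisym(seg, fl, c(1e-6, 2e-6)), "underdetermined")
  expect_error(tabulate_from_axisym(seg, fl, c(-1e-6, 1e-6, 2e-6)),
               "positive")
})
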