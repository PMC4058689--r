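# Shared fixtures, built once per test run. The calibrated study case is
# deterministic, so caching it across test files is safe.

.fixtures <- new.env(parent = emptyenv())

study_case <- function() {
  if (is.null(.fixtures$case)) .fixtures$case <- ffr_setup(ffr_config())
  .fixtures$case
}

study_sweep_ds <- function() {
  if (is.null(.fixtures$sweep_ds)) .fixtures$sweep_ds <- sweep_ds(study_case())
  .fixtures$sweep_ds
}

# single straight tube as a one-segment tree (trunk role, d mm, L mm)
straight_tube <- function(d = 3, L = 10, id = "tube") {
  coronary_tree(list(vessel_segment(id, L, c(d, d), role = "trunk")),
                NULL, inlet = id)
}

# flow at a given throat Reynolds number for a diameter in mm
flow_at_reynolds <- function(re, d_mm, fluid = fluid_properties()) {
  re * pi * fluid$mu * mm_to_m(d_mm) / (4 * fluid$rho)
}
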