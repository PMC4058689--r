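test_that("the LAD emulator satisfies its anatomical constraints", {
  tree <- build_lad_tree()
  expect_s3_class(tree, "coronary_tree")
  expect_length(tree$segments, 8L)
  expect_length(tree$outlets, 8L)
  trunk <- tree$segments$trunk
  expect_gte(min(trunk$profile[, "d_mm"]), 2)          # trunk >= 2 mm
  expect_true(all(diff(trunk$profile[, "d_mm"]) <= 0)) # monotone taper
  branch_d <- vapply(setdiff(names(tree$segments), "trunk"), function(id)
    min(tree$segments[[id]]$profile[, "d_mm"]), numeric(1))
  expect_gte(min(branch_d), 1)                          # branches >= 1 mm
  loc <- unlist(tree$metadata$locations)
  expect_named(loc, c("A", "B", "C", "D"))
  expect_true(all(diff(loc) > 0))                       # proximal -> distal
})

test_that("emulator construction is deterministic and rejects bad configs", {
  expect_identical(build_lad_tree(), build_lad_tree())
  expect_error(build_lad_tree(lad_config(trunk_d_outlet_mm = 1.8)),
               ">= 2 mm")
  expect_error(build_lad_tree(lad_config(branch_d_mm = c(2, 1.8, 1.6, 1.5,
                                                         1.3, 1.2, 0.9))),
               ">= 1 mm")
  expect_error(build_lad_tree(lad_config(trunk_d_inlet_mm = 2.0,
                                         trunk_d_outlet_mm = 3.5)),
               "monotone")
})

test_that("a zero-branch config yields a single-tube tree", {
  cfg <- lad_config(branch_s_mm = numeric(), branch_d_mm = numeric(),
                    locations = c(A = 50))
  tree <- build_lad_tree(cfg)
  expect_length(tree$segments, 1L)
  expect_identical(tree$outlets, "trunk")
})

test_that("tree invariants are enforced", {
  seg <- function(id, L = 10) vessel_segment(id, L, c(2, 2))
  expect_error(vessel_segment("x", -1, c(2, 2)), "length")
  expect_error(vessel_segment("x", 10, cbind(c(0, 5, 5, 10), c(2, 2, 2, 2))),
               "strictly increasing")
  expect_error(vessel_segment("x", 10, cbind(c(0, 10), c(2, -1))), "> 0")
  expect_error(coronary_tree(list(seg("a"), seg("a")), NULL, "a"),
               "duplicate")
  expect_error(
    coronary_tree(list(seg("t"), seg("a")),
                  data.frame(parent = "t", s_mm = 40, child = "a"), "t"),
    "outside parent")
  expect_error(
    coronary_tree(list(seg("t"), seg("a"), seg("b")),
                  data.frame(parent = c("a", "b"), s_mm = c(5, 5),
                             child = c("b", "a")), "t"),
    "cycle")
})

test_that("stenosis insertion narrows by exactly (1 - ds) at the throat", {
  tree <- build_lad_tree()
  trunk <- tree$segments$trunk
  for (ds in c(0.05, 0.25, 0.45, 0.55, 0.75, 0.99)) {
    st <- insert_stenosis(tree, stenosis_spec(ds, 4, 20))
    d_norm <- segment_diameter(trunk, 20)
    expect_equal(segment_diameter(st$segments$trunk, 20), (1 - ds) * d_norm,
                 tolerance = 1e-12)
    expect_equal(st$metadata$stenosis$throat_diameter_mm, (1 - ds) * d_norm,
                 tolerance = 1e-12)
  }
})

test_that("the narrowing window is continuous and confined to its extent", {
  tree <- build_lad_tree()
  for (shape in c("cosine", "trapezoid")) {
    for (len in c(4, 8)) {
      st <- insert_stenosis(tree, stenosis_spec(0.55, len, 20, shape))
      trunk0 <- tree$segments$trunk
      trunk1 <- st$segments$trunk
      ext <- c(20 - len / 2, 20 + len / 2)
      # unchanged at and outside the extent endpoints
      for (s in c(0, ext[1], ext[2], 30, 100)) {
        expect_equal(segment_diameter(trunk1, s), segment_diameter(trunk0, s),
                     tolerance = 1e-9)
      }
      # narrowed inside
      s_in <- seq(ext[1] + 0.2, ext[2] - 0.2, length.out = 21)
      expect_true(all(segment_diameter(trunk1, s_in) <
                        segment_diameter(trunk0, s_in) + 1e-12))
      # profile continuity: no jumps on a dense resampling
      s_dense <- seq(0, 100, by = 0.05)
      expect_lt(max(abs(diff(segment_diameter(trunk1, s_dense)))), 0.1)
    }
  }
})

test_that("ds = 0 insertion leaves the geometry identical", {
  tree <- build_lad_tree()
  st <- insert_stenosis(tree, stenosis_spec(0, 4, 20))
  s_chk <- seq(0, 100, by = 0.5)
  expect_equal(segment_diameter(st$segments$trunk, s_chk),
               segment_diameter(tree$segments$trunk, s_chk),
               tolerance = 1e-12)
})

test_that("stenosis insertion preserves lengths, junctions and the input", {
  tree <- build_lad_tree()
  before <- jsonlite::serializeJSON(tree)
  st <- insert_stenosis(tree, stenosis_spec(0.75, 4, 20))
  expect_identical(jsonlite::serializeJSON(tree), before)  # no mutation
  expect_equal(st$segments$trunk$length_mm, tree$segments$trunk$length_mm)
  expect_equal(st$junctions, tree$junctions)
})

test_that("stenoses overlapping a junction or the trunk end are rejected", {
  tree <- build_lad_tree()
  err <- expect_error(insert_stenosis(tree, stenosis_spec(0.5, 6, 11)),
                      "junction")
  expect_match(conditionMessage(err), "'a'")   # names the junction
  expect_error(insert_stenosis(tree, stenosis_spec(0.5, 8, 2)),
               "outside the trunk")
  st <- insert_stenosis(tree, stenosis_spec(0.5, 4, 20))
  expect_error(insert_stenosis(st, stenosis_spec(0.5, 4, 60)),
               "already")
})

test_that("stenosis specs validate their parameters", {
  expect_error(stenosis_spec(1, 4, 20), "fraction")
  expect_error(stenosis_spec(-0.1, 4, 20), "fraction")
  expect_error(stenosis_spec(0.5, 0, 20), "length")
})
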