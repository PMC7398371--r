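test_that("diameter profile and apposition gaps match analytic expectations", {
  st <- fix_straight()
  cfg <- deployment_config()
  t0 <- init_simplex_tube(st$truth$centerline, cfg)
  # unexpanded: constant initial diameter, mean gap ~ 2.25 - 0.5
  expect_true(all(diameter_profile(t0) == 2 * cfg$initial_radius))
  g0 <- apposition_gap(t0, st$mesh)
  expect_lt(abs(g0$mean - 1.75), 0.02)

  dep <- fix_deployed()
  g1 <- apposition_gap(dep$tube, dep$vessel)
  expect_lte(g1$max, cfg$contact_tolerance + 1e-9)
  expect_gte(g1$mean, 0)

  st6 <- fix_straight6()
  t6 <- expand(init_simplex_tube(st6$truth$centerline, cfg), st6$mesh, cfg)
  g6 <- apposition_gap(t6, st6$mesh)
  expect_lt(abs(g6$max - 0.75), 0.02)              # cap gap 3.0 - 2.25
  expect_true(all(diameter_profile(t6) <= 4.5 + 1e-6))
})

test_that("axial length equals the configured length and ignores expansion", {
  st <- fix_straight()
  cfg <- deployment_config()
  t0 <- init_simplex_tube(st$truth$centerline, cfg)
  expect_identical(axial_length(t0), 23)
  expect_identical(axial_length(fix_deployed()$tube), 23)
  cfg10 <- deployment_config(stent_length = 10)
  expect_identical(axial_length(init_simplex_tube(st$truth$centerline,
                                                  cfg10)), 10)
})

test_that("metal coverage matches strip geometry and the Monte-Carlo oracle", {
  dep <- fix_deployed()
  turns <- braid_angle_design(4.5, 23, 60)

  # zero wires
  empty <- structure(list(wires = list(),
                          device = list(wire_diameter = 0.06)),
                     class = "stent_model")
  expect_identical(metal_coverage(empty, dep$tube), 0)

  # one straight generator wire: strip fraction w / W within one cell
  w1 <- generate_wire_paths(dep$tube, 2, 0, wire_diameter = 0.3)[1]
  m1 <- structure(list(wires = w1, device = list(wire_diameter = 0.3)),
                  class = "stent_model")
  W <- 2 * pi * mean(dep$tube$radius)
  cov1 <- metal_coverage(m1, dep$tube, raster_cells = 1e5)
  expect_lt(abs(cov1 - 0.3 / W), 1 / sqrt(1e5) * 3 + 1 / 300)

  # full braid vs an independent analytic-line Monte-Carlo oracle
  sm <- fix_stent_model()
  cov <- metal_coverage(sm$model, dep$tube, raster_cells = 1e5)
  set.seed(7)
  L <- axial_length(dep$tube)
  n_mc <- 3e4   # MC sd ~0.002, well under the 1% band
  px <- runif(n_mc, 0, L)
  py <- runif(n_mc, 0, W)
  hit <- vapply(seq_len(n_mc), function(i)
    braid_line_distance_oracle(px[i], py[i], sm$model$wires, L, W) <=
      0.06 / 2, logical(1))
  expect_lt(abs(cov - mean(hit)), 0.01)

  expect_warning(metal_coverage(sm$model, dep$tube, raster_cells = 5e3),
                 "coarse")
})

test_that("coverage grows with wire diameter and wire count", {
  dep <- fix_deployed()
  turns <- braid_angle_design(4.5, 23, 60)
  cov_d <- vapply(c(0.03, 0.06, 0.12), function(wd) {
    m <- sweep_wires(generate_wire_paths(dep$tube, 16, turns,
                                         wire_diameter = wd),
                     wire_diameter = wd)
    metal_coverage(m, dep$tube)
  }, numeric(1))
  expect_true(all(diff(cov_d) > 0))
  cov_n <- vapply(c(8L, 16L, 32L), function(n) {
    m <- sweep_wires(generate_wire_paths(dep$tube, n, turns))
    metal_coverage(m, dep$tube)
  }, numeric(1))
  expect_true(all(diff(cov_n) > 0))
})

test_that("measured braid angle matches the design and is symmetric", {
  dep <- fix_deployed()
  turns45 <- braid_angle_design(4.5, 23, 45)
  # design inversion at the as-deployed diameter (slightly under the free
  # diameter because of the contact gap), measured against the centerline
  deployed_d <- 2 * mean(dep$tube$radius)
  expected <- braid_angle_from_turns(deployed_d, 23, turns45)
  m45 <- sweep_wires(generate_wire_paths(dep$tube, 16, turns45),
                     device = list(turns = turns45))
  got <- measure_braid_angle(m45, dep$cl)
  expect_lt(abs(got - expected), 0.5)
  both <- measure_braid_angle(m45, dep$cl, by_handedness = TRUE)
  expect_lt(abs(both[["cw"]] - both[["ccw"]]), 0.5)
  # validation mode: no turns, no angle
  m0 <- sweep_wires(generate_wire_paths(dep$tube, 16, 0),
                    device = list(turns = 0))
  expect_lt(measure_braid_angle(m0, dep$cl), 0.1)
})

test_that("pore density scales with the crossing count", {
  dep <- fix_deployed()
  sm <- fix_stent_model()
  pd <- pore_density(sm$model, dep$tube, sm$turns)
  L <- axial_length(dep$tube)
  W <- 2 * pi * mean(dep$tube$radius)
  approx_pores <- 8 * 8 * 2 * sm$turns
  expect_gt(pd, 0)
  expect_lt(abs(pd - approx_pores / (L * W)) / (approx_pores / (L * W)),
            0.25)
})

test_that("morphometrics are exact on a hemisphere and stable on the phantom", {
  sph <- uv_sphere(radius = 3, n_lat = 24, n_lon = 32)
  mm <- morphometrics(sph, list(point = c(0, 0, 0), normal = c(0, 0, 1)))
  expect_equal(mm$dome_height, 3, tolerance = 1e-12)
  expect_lte(mm$neck_width, 6 + 1e-9)
  expect_gt(mm$neck_width, 6 * cos(pi / 24))
  expect_error(morphometrics(sph, list(point = c(0, 0, 10),
                                       normal = c(0, 0, 1))), "misses")
  # determinism / purity
  ph <- fix_aneurysm()
  before <- ph$mesh
  a <- morphometrics(ph$mesh, ph$truth$neck_plane)
  b <- morphometrics(ph$mesh, ph$truth$neck_plane)
  expect_identical(a, b)
  expect_identical(ph$mesh, before)
})

test_that("the combined metrics report serializes", {
  dep <- fix_deployed()
  sm <- fix_stent_model()
  met <- deployment_metrics(dep$tube, sm$model, dep$vessel, dep$cl,
                            sm$turns)
  expect_s3_class(met, "deployment_metrics")
  expect_identical(met$stent_length_axial, 23)
  expect_true(met$metal_coverage > 0 && met$metal_coverage < 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(met, path)
  j <- jsonlite::read_json(path)
  expect_identical(j$schema, "fvstent-metrics-1")
  expect_equal(j$mean_diameter, met$mean_diameter)
})
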