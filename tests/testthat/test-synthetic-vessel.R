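test_that("straight tube puts lateral vertices exactly on radius and is watertight", {
  st <- fix_straight()
  expect_true(validate_mesh(st$mesh)$watertight)
  v <- st$mesh$vertices
  lateral <- abs(v[, 3]) > 1e-9 & abs(v[, 3] - 30) > 1e-9 |
    sqrt(v[, 1]^2 + v[, 2]^2) > 1e-9
  rad <- sqrt(v[lateral, 1]^2 + v[lateral, 2]^2)
  expect_lt(max(abs(rad - 2.25)), 1e-9)
  # analytic truth
  expect_equal(total_arclength(st$truth$centerline), 30)
  expect_true(all(st$truth$nominal_radius_profile$radius == 2.25))
  expect_lt(max(abs(st$truth$centerline$points[, 1:2])), 1e-12)
})

test_that("finer mesh resolution reduces radial chord error", {
  chord_err <- function(res) {
    st <- make_straight_tube(phantom_spec(tube_diameter = 4.5,
                                          tube_length = 10,
                                          mesh_resolution = res))
    # wall distance sampled densely so mid-chord sagitta is hit for any
    # ring count
    ang <- seq(0.0005, 2 * pi, length.out = 720)
    d <- vapply(ang, function(a)
      wall_distance(c(0, 0, 5), c(cos(a), sin(a), 0), st$mesh), numeric(1))
    2.25 - min(d)
  }
  e_fine <- chord_err(0.2)
  e_coarse <- chord_err(0.4)
  expect_lt(e_fine, e_coarse)
  # chord-sagitta bound: sagitta <= c^2 / (8 r)
  expect_lt(e_coarse, 0.4^2 / (8 * 2.25) + 1e-6)
})

test_that("curved tube matches the analytic arc", {
  ct <- fix_curved()
  expect_true(validate_mesh(ct$mesh)$watertight)
  expect_lt(abs(total_arclength(ct$truth$centerline) - pi * 10 / 2), 1e-6)
  # every truth point sits on the bend circle
  p <- ct$truth$centerline$points
  expect_lt(max(abs(sqrt(p[, 1]^2 + p[, 2]^2) - 10)), 1e-9)
})

test_that("degenerate curved-tube parameters are rejected", {
  expect_error(phantom_spec(tube_diameter = 4.5, bend_radius = 10,
                            bend_angle = 2), "bend_angle")
  expect_error(phantom_spec(tube_diameter = 4.5, bend_radius = 2,
                            bend_angle = 90), "bend_radius")
})

test_that("reference preset phantom reproduces its stated morphometrics", {
  ph <- fix_aneurysm()
  expect_true(validate_mesh(ph$mesh)$watertight)
  mm <- morphometrics(ph$mesh, ph$truth$neck_plane)
  expect_lt(abs(mm$neck_width - 12.27) / 12.27, 0.02)
  expect_lt(abs(mm$dome_height - 9.35) / 9.35, 0.02)
})

test_that("aneurysm generator degenerates to the curved tube without a dome", {
  spec <- phantom_spec(tube_diameter = 4.5, bend_radius = 10,
                       bend_angle = 90, mesh_resolution = 0.3)
  a <- make_sidewall_aneurysm(spec)
  b <- make_curved_tube(spec)
  expect_identical_mesh(a$mesh, b$mesh)
})

test_that("doubling the aneurysm grid resolution moves dome height <1%", {
  spec_c <- reference_phantom_preset()
  spec_c$mesh_resolution <- 0.5
  spec_f <- reference_phantom_preset()
  spec_f$mesh_resolution <- 0.25
  h <- vapply(list(spec_c, spec_f), function(s) {
    ph <- make_sidewall_aneurysm(s)
    morphometrics(ph$mesh, ph$truth$neck_plane)$dome_height
  }, numeric(1))
  expect_lt(abs(h[2] - h[1]) / h[1], 0.01)
})

test_that("dome parameters that swallow the tube are rejected", {
  expect_error(phantom_spec(tube_diameter = 4.5, bend_radius = 20,
                            bend_angle = 100,
                            aneurysm = list(neck_width = 30,
                                            dome_height = 30,
                                            dome_width = 30)),
               "swallow")
})

test_that("the reference preset is deterministic and carries the device facts", {
  a <- reference_phantom_preset()
  b <- reference_phantom_preset()
  expect_identical(a, b)
  expect_identical(a$tube_diameter, 4.5)
  expect_identical(a$aneurysm$neck_width, 12.27)
  expect_identical(a$aneurysm$dome_height, 9.35)
  # generator determinism: identical meshes across calls
  m1 <- make_curved_tube(phantom_spec(tube_diameter = 4.5, bend_radius = 10,
                                      bend_angle = 90))
  m2 <- make_curved_tube(phantom_spec(tube_diameter = 4.5, bend_radius = 10,
                                      bend_angle = 90))
  expect_identical_mesh(m1$mesh, m2$mesh)
})

test_that("all generator outputs are watertight", {
  specs <- list(
    phantom_spec(tube_diameter = 3, tube_length = 12,
                 mesh_resolution = 0.4),
    phantom_spec(tube_diameter = 4.5, bend_radius = 8, bend_angle = 60,
                 mesh_resolution = 0.4),
    phantom_spec(tube_diameter = 4, bend_radius = 15, bend_angle = 120,
                 aneurysm = list(neck_width = 5, dome_height = 6,
                                 dome_width = 7),
                 mesh_resolution = 0.4))
  for (s in specs)
    expect_true(validate_mesh(make_phantom(s)$mesh)$watertight)
})
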