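test_that("braid angle design inverts exactly", {
  expect_equal(braid_angle_design(4.5, 23, 45), 23 / (pi * 4.5),
               tolerance = 1e-12)
  for (a in c(30, 45, 60)) {
    turns <- braid_angle_design(4.5, 23, a)
    expect_equal(braid_angle_from_turns(4.5, 23, turns), a,
                 tolerance = 1e-9)
  }
  expect_error(braid_angle_design(4.5, 23, 0), "between")
  expect_error(braid_angle_design(4.5, 23, 95), "between")
})

test_that("wire paths come in two equal-handed families on the surface", {
  dep <- fix_deployed()
  turns <- braid_angle_design(4.5, 23, 60)
  wires <- generate_wire_paths(dep$tube, 16, turns)
  expect_length(wires, 16L)
  hand <- vapply(wires, function(w) w$handedness, character(1))
  expect_identical(sum(hand == "cw"), 8L)
  expect_identical(sum(hand == "ccw"), 8L)
  # distinct curves
  starts <- t(vapply(wires, function(w) w$points[1, ], numeric(3)))
  expect_identical(nrow(unique(round(starts, 9))), 16L)
  # endpoints at the two end stations
  L <- axial_length(dep$tube)
  for (w in wires) {
    expect_identical(w$sfrac[1], 0)
    expect_identical(w$sfrac[length(w$sfrac)], 1)
  }
  # surface adherence: pre-offset points on the deployed surface
  ds <- deployed_surface(dep$tube)
  pts <- do.call(rbind, lapply(wires, function(w) w$points))
  d <- fvstent:::point_mesh_distance(pts, ds)
  expect_lt(max(d), 1e-3)
  expect_error(generate_wire_paths(dep$tube, 15, turns), "even")
  expect_error(generate_wire_paths(dep$tube, 16, -1), "non-negative")
})

test_that("wire lengths follow the helix closed form in a uniform tube", {
  dep <- fix_deployed_hi()
  for (turns in c(1.5, braid_angle_design(4.5, 23, 60))) {
    wires <- generate_wire_paths(dep$tube, 16, turns)
    wl <- vapply(wires, function(w)
      sum(sqrt(rowSums(diff(w$points)^2))), numeric(1))
    r_mean <- mean(dep$tube$radius)
    closed_form <- sqrt(23^2 + (2 * pi * r_mean * turns)^2)
    expect_lt(max(abs(wl - closed_form)) / closed_form, 0.002)
    # wire-length conservation across the braid
    expect_lt((max(wl) - min(wl)) / mean(wl), 0.001)
  }
  # degenerate validation mode: straight generators of length L
  wires0 <- generate_wire_paths(dep$tube, 16, 0)
  wl0 <- vapply(wires0, function(w)
    sum(sqrt(rowSums(diff(w$points)^2))), numeric(1))
  expect_lt(max(abs(wl0 - 23)) / 23, 1e-6)
})

test_that("parameter-space crossing counts match 2*turns per wire pair", {
  for (turns in c(1.5, 2.817903, 4)) {
    wires <- generate_wire_paths(fix_deployed()$tube, 8, turns)
    hand <- vapply(wires, function(w) w$handedness, character(1))
    cw <- wires[hand == "cw"]
    ccw <- wires[hand == "ccw"]
    for (a in cw) for (b in ccw) {
      combinat <- count_pair_crossings(turns, a$theta[1], b$theta[1])
      # numeric oracle: sign changes of the wrapped angular difference
      tg <- seq(0, 1, length.out = 20000)
      d <- (a$theta[1] + 2 * pi * turns * tg) -
        (b$theta[1] - 2 * pi * turns * tg)
      wrapped <- ((d + pi) %% (2 * pi)) - pi
      numeric_count <- sum(abs(diff(sign(wrapped))) > 0 &
                             abs(diff(wrapped)) < pi)
      expect_identical(combinat, as.integer(numeric_count))
      expect_lte(abs(combinat - 2 * turns), 1)
    }
  }
})

test_that("sweeping a straight wire yields the exact triangle budget", {
  pts <- cbind(0, 0, seq(0, 10, length.out = 21))
  m <- fvstent:::sweep_tube_mesh(pts, 0.03, 8)
  expect_equal(nrow(m$faces), 8 * 20 * 2 + 2 * 8)
  expect_true(validate_mesh(m)$watertight)
})

test_that("swept wire volume matches the tube formula", {
  dep <- fix_deployed()
  turns <- braid_angle_design(4.5, 23, 60)
  wires <- generate_wire_paths(dep$tube, 2, turns)
  model <- sweep_wires(wires[1], wire_diameter = 0.3, n_sides = 32)
  len <- sum(sqrt(rowSums(diff(model$wires[[1]]$points_offset)^2)))
  vol <- mesh_volume(model$swept)
  expect_lt(abs(vol - pi * 0.15^2 * len) / (pi * 0.15^2 * len), 0.02)
})

test_that("the merged stent splits into n_wires watertight components", {
  model <- fix_stent_model()$model
  expect_length(model$wires, 16L)
  path <- withr::local_tempfile(fileext = ".stl")
  write_surface_mesh(model$swept, path)
  comps <- mesh_components(read_surface_mesh(path))
  expect_length(comps, 16L)
  expect_true(all(vapply(comps, function(m)
    validate_mesh(m)$watertight, logical(1))))
})

test_that("kinked wire polylines are rejected with wire and vertex named", {
  kinked <- structure(list(wire_index = 3L, handedness = "cw",
                           points = rbind(c(0, 0, 0), c(0, 0, 5),
                                          c(0, 4.9, 4)),
                           wire_diameter = 0.06),
                      class = "wire_curve")
  expect_error(sweep_wires(list(kinked)), "wire 3 kinked at vertex")
})
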