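# Shared fixtures and independent oracles.  All fixtures are generated in
# code; the cache avoids regenerating the heavier phantoms across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fix_straight <- function() fixture("straight", function() {
  make_straight_tube(phantom_spec(tube_diameter = 4.5, tube_length = 30,
                                  mesh_resolution = 0.3))
})

fix_straight6 <- function() fixture("straight6", function() {
  make_straight_tube(phantom_spec(tube_diameter = 6, tube_length = 30,
                                  mesh_resolution = 0.3))
})

fix_curved <- function() fixture("curved", function() {
  make_curved_tube(phantom_spec(tube_diameter = 4.5, bend_radius = 10,
                                bend_angle = 90, mesh_resolution = 0.3))
})

fix_aneurysm <- function() fixture("aneurysm", function() {
  make_sidewall_aneurysm(reference_phantom_preset())
})

# matched-calibre deployment used by deployment/braid/metrics/acceptance
fix_deployed <- function() fixture("deployed", function() {
  st <- fix_straight()
  cfg <- deployment_config()
  tube <- init_simplex_tube(st$truth$centerline, cfg)
  list(tube = expand(tube, st$mesh, cfg), cfg = cfg, vessel = st$mesh,
       cl = st$truth$centerline)
})

# finer ring discretization for closed-form helix-length comparisons,
# where the 32-ring default's chordal radius deficit (~0.3%) would
# dominate the 0.2% tolerance
fix_deployed_hi <- function() fixture("deployed_hi", function() {
  st <- fix_straight()
  cfg <- deployment_config(rings = 96L)
  tube <- expand(init_simplex_tube(st$truth$centerline, cfg), st$mesh, cfg)
  list(tube = tube, cfg = cfg, vessel = st$mesh,
       cl = st$truth$centerline)
})

# deployed device braided at the default 60-degree design angle
fix_stent_model <- function() fixture("stent_model", function() {
  dep <- fix_deployed()
  turns <- braid_angle_design(4.5, 23, 60)
  model <- sweep_wires(generate_wire_paths(dep$tube, 16, turns),
                       device = list(free_diameter = 4.5, length = 23,
                                     turns = turns))
  list(model = model, turns = turns)
})

# --- simple constructed meshes --------------------------------------------

unit_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(v, f, provenance = "unit tetrahedron")
}

icosahedron <- function(radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2) * radius
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  surface_mesh(v, f, provenance = "icosahedron")
}

# UV sphere with explicit pole vertices (height test needs a pole).
uv_sphere <- function(radius = 1, n_lat = 16, n_lon = 24) {
  lat <- seq(0, pi, length.out = n_lat + 1)
  inner <- lat[-c(1, n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  verts <- rbind(c(0, 0, radius))
  for (la in inner) {
    ring <- cbind(radius * sin(la) * cos(lon), radius * sin(la) * sin(lon),
                  radius * cos(la))
    verts <- rbind(verts, ring)
  }
  verts <- rbind(verts, c(0, 0, -radius))
  np <- 1L
  vid <- function(i, j) np + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  south <- nrow(verts)
  faces <- list()
  j <- seq_len(n_lon)
  faces[[1]] <- cbind(rep(1L, n_lon), vid(1L, j), vid(1L, j + 1L))
  for (i in seq_len(length(inner) - 1L)) {
    faces[[i + 1L]] <- rbind(
      cbind(vid(i, j), vid(i + 1L, j), vid(i, j + 1L)),
      cbind(vid(i, j + 1L), vid(i + 1L, j), vid(i + 1L, j + 1L)))
  }
  faces[[length(inner) + 1L]] <- cbind(rep(south, n_lon),
                                       vid(length(inner), j + 1L),
                                       vid(length(inner), j))
  m <- surface_mesh(verts, do.call(rbind, faces), provenance = "uv sphere")
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# --- independent oracles ---------------------------------------------------

# Brute-force first-hit ray cast in plain R (Moller-Trumbore over every
# triangle); oracle for the compiled wall_distance path.
ray_first_hit_oracle <- function(origin, dir, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c3 - a
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  tv <- sweep(a, 2, origin, "-") * -1
  u <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  vv <- (qv %*% dir) / det
  tt <- rowSums(e2 * qv) / det
  ok <- abs(det) > 1e-12 & u >= -1e-10 & u <= 1 + 1e-10 &
    vv >= -1e-10 & (u + vv) <= 1 + 1e-10 & tt > 1e-9
  if (!any(ok)) Inf else min(tt[ok])
}

# Distance from a point of the unrolled plane to the analytic braid lines
# (straight lines in parameter space, periodic in y); oracle for the
# rasterized metal-coverage path.
braid_line_distance_oracle <- function(x, y, wires, L, W) {
  best <- Inf
  for (w in wires) {
    # parameter-space line through (0, y0) with slope dy/dx
    y0 <- w$theta[1] * W / (2 * pi)
    dth <- (w$theta[length(w$theta)] - w$theta[1])
    slope <- dth * W / (2 * pi) / L
    for (k in -ceiling(abs(dth) / (2 * pi) + 2):ceiling(abs(dth) / (2 * pi) + 2)) {
      # line y = y0 + k W + slope x restricted to x in [0, L]
      # distance from (x, y) to the segment
      x1 <- 0; y1 <- y0 + k * W
      x2 <- L; y2 <- y1 + slope * L
      dx <- x2 - x1; dy <- y2 - y1
      t <- ((x - x1) * dx + (y - y1) * dy) / (dx^2 + dy^2)
      t <- min(max(t, 0), 1)
      d <- sqrt((x1 + t * dx - x)^2 + (y1 + t * dy - y)^2)
      if (d < best) best <- d
    }
  }
  best
}

expect_identical_mesh <- function(a, b, tol = 0) {
  expect_equal(nrow(a$vertices), nrow(b$vertices))
  expect_identical(a$faces, b$faces)
  if (tol == 0) expect_identical(a$vertices, b$vertices)
  else expect_lt(max(abs(a$vertices - b$vertices)), tol)
}
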