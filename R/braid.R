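# Braid pattern mapping: helical wire paths in the (station, angle)
# parameter grid of the deployed tube, mapped to 3D on the deployed
# surface, then swept into watertight wire solids.
#
# "Overlaying" wires are taken literally: all wire centerlines live on one
# offset surface, half clockwise and half counter-clockwise, with no
# over/under weave.

#' Convert a nominal braid angle to helix turns
#'
#' `turns = length * tan(angle) / (pi * free_diameter)`, the number of full
#' revolutions a wire makes over the stent length when the braid angle
#' (wire vs. stent axis) is realized at the free diameter.
#'
#' @param free_diameter device free diameter (mm).
#' @param length device length (mm).
#' @param target_angle braid angle in degrees, strictly between 0 and 90.
#' @return turns (dimensionless).
#' @export
braid_angle_design <- function(free_diameter, length, target_angle) {
  if (!is.numeric(target_angle) || target_angle <= 0 || target_angle >= 90)
    stop("target_angle must be strictly between 0 and 90 degrees")
  if (free_diameter <= 0 || length <= 0)
    stop("free_diameter and length must be positive")
  length * tan(target_angle * pi / 180) / (pi * free_diameter)
}

#' Inverse of [braid_angle_design()]
#'
#' @param free_diameter device free diameter (mm).
#' @param length device length (mm).
#' @param turns helix turns over the device length.
#' @return braid angle in degrees.
#' @export
braid_angle_from_turns <- function(free_diameter, length, turns) {
  atan(turns * pi * free_diameter / length) * 180 / pi
}

#' Generate braided wire paths on a deployed tube
#'
#' In the `(station fraction t, angle theta)` parameter grid, wire `j` of
#' the clockwise family follows `theta(t) = theta0_j + 2*pi*turns*t` and
#' the counter-clockwise family uses `-turns`; start angles are uniform at
#' `2*pi/(n_wires/2)` spacing plus `phase`.  Parameter points are mapped
#' to 3D by bilinear interpolation of the deployed radius over the
#' (station, ring) grid, so wire points lie on the deployed surface.  Each
#' wire is sampled at every station, refined by `samples_per_station`
#' intermediate samples.
#'
#' @param tube an expanded `simplex_tube`.
#' @param n_wires even wire count >= 2 (16 for the modelled device).
#' @param turns helix turns (> 0) over the stent length; see
#'   [braid_angle_design()].
#' @param phase global start-angle offset in degrees.
#' @param wire_diameter wire diameter (mm), carried on each curve.
#' @param samples_per_station samples per station interval (>= 1).
#' @return A list of `wire_curve` objects, each with fields `wire_index`,
#'   `handedness`, `points`, `wire_diameter`, and the parameter
#'   coordinates `sfrac`, `theta` plus interpolated `centers` used for
#'   radial offsetting.
#' @export
generate_wire_paths <- function(tube, n_wires = 16L, turns,
                                phase = 0, wire_diameter = 0.06,
                                samples_per_station = 4L) {
  stopifnot(inherits(tube, "simplex_tube"))
  if (n_wires < 2L || n_wires %% 2L != 0L)
    stop("n_wires must be even and at least 2")
  if (!is.numeric(turns) || turns < 0)
    stop("turns must be non-negative")
  S <- tube$stations
  m <- (S - 1L) * as.integer(samples_per_station) + 1L
  tfrac <- seq(0, 1, length.out = m)
  half <- n_wires / 2L
  theta0 <- phase * pi / 180 + 2 * pi * (seq_len(half) - 1L) / half
  # stagger the ccw family by half a carrier spacing so the two families
  # never start at coincident points (as on a real braiding machine)
  stagger <- pi / half
  wires <- vector("list", n_wires)
  for (j in seq_len(n_wires)) {
    cw <- j <= half
    t0 <- theta0[((j - 1L) %% half) + 1L] + if (cw) 0 else stagger
    sgn <- if (cw) 1 else -1
    theta <- t0 + sgn * 2 * pi * turns * tfrac
    pts <- tube_surface_points(tube, tfrac, theta)
    wires[[j]] <- structure(
      list(wire_index = j - 1L,
           handedness = if (cw) "cw" else "ccw",
           points = pts$points, wire_diameter = wire_diameter,
           sfrac = tfrac, theta = theta, centers = pts$centers,
           radius = pts$radius),
      class = "wire_curve")
  }
  wires
}

# Map parameter coordinates (station fraction, angle) to 3D points on the
# deployed surface by bilinear interpolation of the four surrounding grid
# vertex positions, so mapped points lie on the triangulated deployed
# surface (exactly, for the planar quads of a uniform tube).
tube_surface_points <- function(tube, tfrac, theta) {
  S <- tube$stations
  K <- tube$rings
  scoord <- tfrac * (S - 1)
  s0 <- pmin(floor(scoord), S - 2) + 1L
  fs <- scoord - (s0 - 1L)
  dtheta <- 2 * pi / K
  th <- theta %% (2 * pi)
  k0 <- floor(th / dtheta)              # 0-based ring cell
  fk <- th / dtheta - k0
  k0 <- as.integer(k0 %% K) + 1L
  k1 <- (k0 %% K) + 1L
  vert <- function(s, k) {
    dir <- cos(tube$theta[k]) * tube$normal[s, , drop = FALSE] +
      sin(tube$theta[k]) * tube$binormal[s, , drop = FALSE]
    tube$centers[s, , drop = FALSE] + tube$radius[cbind(s, k)] * dir
  }
  p <- (1 - fs) * ((1 - fk) * vert(s0, k0) + fk * vert(s0, k1)) +
    fs * ((1 - fk) * vert(s0 + 1L, k0) + fk * vert(s0 + 1L, k1))
  centers <- (1 - fs) * tube$centers[s0, , drop = FALSE] +
    fs * tube$centers[s0 + 1L, , drop = FALSE]
  list(points = p, centers = centers,
       radius = sqrt(rowSums((p - centers)^2)))
}

#' Sweep wire curves into 3D wire solids
#'
#' Each wire centerline is first offset radially inward by half the wire
#' diameter (so the swept tube is tangent to the wall from inside), then
#' swept with a circular cross-section of `n_sides` segments along
#' rotation-minimizing frames and closed with flat end caps.  Per-wire
#' meshes are watertight; the merged mesh is their concatenation (no
#' Boolean union), so its connected components are the individual wires.
#'
#' @param wires list of `wire_curve` from [generate_wire_paths()].
#' @param wire_diameter wire diameter (mm); defaults to the diameter
#'   carried on the first wire.
#' @param n_sides polygon sides of the cross-section (>= 6).
#' @param device optional named list of device metadata to carry along.
#' @return An object of class `stent_model`: fields `wires` (offset
#'   centerlines), `swept` (merged [surface_mesh()]), `device`.
#' @export
sweep_wires <- function(wires, wire_diameter = NULL, n_sides = 8L,
                        device = list()) {
  if (length(wires) == 0L) stop("no wires to sweep")
  if (is.null(wire_diameter)) wire_diameter <- wires[[1]]$wire_diameter
  if (n_sides < 6L) stop("n_sides must be at least 6")
  meshes <- vector("list", length(wires))
  for (i in seq_along(wires)) {
    w <- wires[[i]]
    pts <- offset_wire_points(w, wire_diameter / 2)
    seg <- diff(pts)
    seg <- normalize_rows(seg)
    if (nrow(seg) > 1L) {
      dots <- rowSums(seg[-nrow(seg), , drop = FALSE] *
                        seg[-1, , drop = FALSE])
      kink <- which(dots < cos(60 * pi / 180))
      if (length(kink) > 0L)
        stop(sprintf("sweep error: wire %d kinked at vertex %d (angle %.1f deg)",
                     w$wire_index, kink[1] + 1L,
                     acos(max(-1, min(1, dots[kink[1]]))) * 180 / pi))
    }
    meshes[[i]] <- sweep_tube_mesh(pts, wire_diameter / 2, n_sides)
    w$points_offset <- pts
    wires[[i]] <- w
  }
  merged <- concatenate_meshes(meshes, provenance = "braided stent wires")
  dev <- utils::modifyList(
    list(n_wires = length(wires), wire_diameter = wire_diameter), device)
  structure(list(wires = wires, swept = merged, device = dev),
            class = "stent_model")
}

#' @export
print.stent_model <- function(x, ...) {
  cat(sprintf("stent_model: %d wires, %d swept faces\n",
              length(x$wires), nrow(x$swept$faces)))
  invisible(x)
}

# Offset wire points radially inward (toward the interpolated centerline
# center recorded at path generation) by `off` mm.
offset_wire_points <- function(wire, off) {
  if (is.null(wire$centers)) return(wire$points)
  dirs <- normalize_rows(wire$points - wire$centers)
  wire$points - off * dirs
}

# Sweep a circular cross-section along a polyline with RMF frames.
sweep_tube_mesh <- function(pts, radius, n_sides) {
  cl <- centerline(pts)
  m <- nrow(pts)
  ang <- seq(0, 2 * pi, length.out = n_sides + 1L)[-(n_sides + 1L)]
  verts <- matrix(0, m * n_sides + 2L, 3L)
  for (i in seq_len(m)) {
    ring <- pts[rep(i, n_sides), , drop = FALSE] +
      outer(radius * cos(ang), cl$normal[i, ]) +
      outer(radius * sin(ang), cl$binormal[i, ])
    verts[((i - 1) * n_sides + 1):(i * n_sides), ] <- ring
  }
  c_start <- m * n_sides + 1L
  c_end <- m * n_sides + 2L
  verts[c_start, ] <- pts[1, ]
  verts[c_end, ] <- pts[m, ]
  vid <- function(i, j) (i - 1L) * n_sides + ((j - 1L) %% n_sides) + 1L
  faces <- vector("list", m + 1L)
  for (i in seq_len(m - 1L)) {
    j <- seq_len(n_sides)
    faces[[i]] <- rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
                        cbind(vid(i + 1L, j), vid(i, j + 1L),
                              vid(i + 1L, j + 1L)))
  }
  j <- seq_len(n_sides)
  faces[[m]] <- cbind(rep(c_start, n_sides), vid(1L, j + 1L), vid(1L, j))
  faces[[m + 1L]] <- cbind(rep(c_end, n_sides), vid(m, j), vid(m, j + 1L))
  ensure_outward(surface_mesh(verts, do.call(rbind, faces),
                              provenance = "swept wire"))
}

concatenate_meshes <- function(meshes, provenance = "merged") {
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  off <- cumsum(c(0L, nv[-length(nv)]))
  verts <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, meshes, off))
  surface_mesh(verts, faces, provenance = provenance)
}

#' Count parameter-space wire crossings
#'
#' Counts, for one clockwise/counter-clockwise wire pair, how often their
#' parameter-space paths cross over the stent length (combinatorially, on
#' the unrolled periodic plane).
#'
#' @param turns helix turns.
#' @param theta0_cw,theta0_ccw start angles (radians).
#' @return integer crossing count.
#' @export
count_pair_crossings <- function(turns, theta0_cw, theta0_ccw) {
  # theta_cw(t) = a + w t, theta_ccw(t) = b - w t, w = 2 pi turns;
  # crossings at t = (b - a + 2 pi m) / (2 w) in [0, 1]
  w <- 2 * pi * turns
  if (w == 0) return(0L)
  d <- theta0_ccw - theta0_cw
  mlo <- ceiling((0 - d) / (2 * pi) - 1e-12)
  mhi <- floor((2 * w - d) / (2 * pi) + 1e-12)
  max(0L, as.integer(mhi - mlo + 1L))
}
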