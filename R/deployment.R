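# Simplex-tube deployment: initialize a cylindrical deformable mesh along
# the centerline and expand it adaptively until it apposes the vessel wall.
#
# The expansion is kinematic, not force-based: phase 1 grows all radii
# multiplicatively (adaptive expansion, geometric iteration bound), phase 2
# advances each vertex individually with hard contact freezing plus a
# tangential Laplacian regularization over the simplex neighbors.  This
# reproduces the expand-until-apposition behaviour deterministically.

#' Deployment configuration
#'
#' @param stent_length device labelled length (mm).
#' @param free_diameter device labelled free diameter (mm); a braided
#'   stent opens no further than this even in an oversized vessel.
#' @param initial_radius crimped tube radius at initiation (mm).
#' @param growth_factor multiplicative radius growth per phase-1 step (>1).
#' @param contact_tolerance wall gap below which a vertex counts as
#'   apposed and freezes (mm).
#' @param smoothing_weight Laplacian weight in `[0, 1]` for the phase-2
#'   regularization pass.
#' @param max_iterations iteration cap for the expansion loop.
#' @param rings vertices per cross-section ring.
#' @param stations_per_mm axial stations per mm of stent length.
#' @return A validated list of class `deployment_config`.
#' @export
deployment_config <- function(stent_length = 23, free_diameter = 4.5,
                              initial_radius = 0.5, growth_factor = 1.3,
                              contact_tolerance = 0.05,
                              smoothing_weight = 0.3,
                              max_iterations = 500L, rings = 32L,
                              stations_per_mm = 2) {
  if (initial_radius >= free_diameter / 2)
    stop("initial_radius must be below free_diameter/2")
  if (contact_tolerance <= 0) stop("contact_tolerance must be positive")
  if (growth_factor <= 1) stop("growth_factor must exceed 1")
  if (smoothing_weight < 0 || smoothing_weight > 1)
    stop("smoothing_weight must be in [0, 1]")
  if (stent_length <= 0 || rings < 3L || stations_per_mm <= 0)
    stop("invalid deployment geometry parameters")
  structure(list(stent_length = stent_length, free_diameter = free_diameter,
                 initial_radius = initial_radius,
                 growth_factor = growth_factor,
                 contact_tolerance = contact_tolerance,
                 smoothing_weight = smoothing_weight,
                 max_iterations = as.integer(max_iterations),
                 rings = as.integer(rings),
                 stations_per_mm = stations_per_mm),
            class = "deployment_config")
}

#' Initialize a cylindrical simplex tube along a centerline
#'
#' Sweeps a tube of radius `initial_radius` along the rotation-minimizing
#' frames of the centerline, centered at `center_arclength`, with
#' `ceil(stent_length * stations_per_mm) + 1` axial stations.  The tube is
#' held in cylindrical coordinates: per-station centers and frames, fixed
#' ring angles, and a per-vertex radius that the expansion updates.
#' Interior vertices have the simplex property of exactly three
#' topological neighbors (ring left, ring right, one axial neighbor
#' alternating with parity).
#'
#' @param cl a [centerline()] long enough to host the stent.
#' @param cfg a [deployment_config()].
#' @param center_arclength landing-zone center along the centerline (mm);
#'   default is the centerline midpoint.
#' @return An object of class `simplex_tube`.
#' @export
init_simplex_tube <- function(cl, cfg, center_arclength = NULL) {
  stopifnot(inherits(cl, "centerline"), inherits(cfg, "deployment_config"))
  L <- cfg$stent_length
  total <- total_arclength(cl)
  if (is.null(center_arclength)) center_arclength <- total / 2
  s0 <- center_arclength - L / 2
  s1 <- center_arclength + L / 2
  if (s0 < -1e-9 || s1 > total + 1e-9)
    stop("stent placement error: stent length ", L,
         " mm does not fit on the centerline at center ", center_arclength)
  stations <- as.integer(ceiling(L * cfg$stations_per_mm)) + 1L
  s <- seq(s0, s1, length.out = stations)
  it <- interp_centerline(cl, pmin(pmax(s, 0), total))
  scl <- centerline(it$points)   # rotation-minimizing frames per station
  theta <- seq(0, 2 * pi, length.out = cfg$rings + 1L)[-(cfg$rings + 1L)]
  structure(list(stations = stations, rings = cfg$rings,
                 centers = scl$points, tangent = scl$tangent,
                 normal = scl$normal, binormal = scl$binormal,
                 station_arclength = s, theta = theta,
                 radius = matrix(cfg$initial_radius, stations, cfg$rings),
                 state = matrix("active", stations, cfg$rings),
                 cap_radius = cfg$free_diameter / 2,
                 expanded = FALSE, converged = NA,
                 iterations = 0L, phase1_iterations = 0L),
            class = "simplex_tube")
}

#' @export
print.simplex_tube <- function(x, ...) {
  cat(sprintf(
    "simplex_tube: %d stations x %d rings, %s, mean diameter %.3f mm\n",
    x$stations, x$rings,
    if (x$expanded) "expanded" else "initial",
    mean(2 * x$radius)))
  invisible(x)
}

#' Cartesian vertex positions of a simplex tube
#'
#' @param tube a `simplex_tube`.
#' @return A `(stations * rings) x 3` matrix, station-major order.
#' @export
tube_vertices <- function(tube) {
  ct <- cos(tube$theta)
  st <- sin(tube$theta)
  out <- matrix(0, tube$stations * tube$rings, 3L)
  for (s in seq_len(tube$stations)) {
    dirs <- outer(ct, tube$normal[s, ]) + outer(st, tube$binormal[s, ])
    out[((s - 1) * tube$rings + 1):(s * tube$rings), ] <-
      tube$centers[rep(s, tube$rings), , drop = FALSE] +
      tube$radius[s, ] * dirs
  }
  out
}

# Radial unit directions per vertex, station-major.
tube_radial_dirs <- function(tube) {
  ct <- cos(tube$theta)
  st <- sin(tube$theta)
  out <- matrix(0, tube$stations * tube$rings, 3L)
  for (s in seq_len(tube$stations)) {
    out[((s - 1) * tube$rings + 1):(s * tube$rings), ] <-
      outer(ct, tube$normal[s, ]) + outer(st, tube$binormal[s, ])
  }
  out
}

# Simplex adjacency on the cylindrical grid: ring left, ring right, and a
# single axial neighbor chosen by parity of (station + ring).  Returns the
# mean neighbor radius matrix used by the regularization pass.
simplex_neighbor_mean <- function(radius) {
  S <- nrow(radius)
  K <- ncol(radius)
  left <- radius[, c(K, seq_len(K - 1L)), drop = FALSE]
  right <- radius[, c(2:K, 1L), drop = FALSE]
  par <- outer(seq_len(S), seq_len(K), function(s, k) (s + k) %% 2L)
  up <- radius[c(2:S, S), , drop = FALSE]     # clamped at the far end
  down <- radius[c(1L, 1:(S - 1L)), , drop = FALSE]
  axial <- ifelse(par == 0L, up, down)
  (left + right + axial) / 3
}

# Per-vertex radial wall coordinate: first ray hit from each station
# center along the vertex's radial direction.
wall_radii <- function(tube, vessel) {
  origins <- tube$centers[rep(seq_len(tube$stations), each = tube$rings), ,
                          drop = FALSE]
  dirs <- matrix(0, tube$stations * tube$rings, 3L)
  ct <- cos(tube$theta)
  st <- sin(tube$theta)
  for (s in seq_len(tube$stations)) {
    dirs[((s - 1) * tube$rings + 1):(s * tube$rings), ] <-
      outer(ct, tube$normal[s, ]) + outer(st, tube$binormal[s, ])
  }
  hit <- cpp_ray_first_hit(origins, dirs, vessel$vertices, vessel$faces)
  matrix(hit, tube$stations, tube$rings, byrow = TRUE)
}

#' Expand a simplex tube until wall apposition
#'
#' Two-phase adaptive expansion.  Phase 1 grows every active vertex radius
#' by `growth_factor` per step while the whole tube is far from the wall,
#' so the number of uniform steps is bounded by
#' `ceil(log(wall_radius / initial_radius) / log(growth_factor))`.  Phase 2
#' moves each active vertex radially outward by
#' `min(remaining wall distance - contact_tolerance / 2, step)` (the
#' half-tolerance target keeps the realized gap strictly within the
#' contact tolerance against a chordally discretized wall) and then
#' applies a tangential (radius-space) Laplacian pass over non-contacted
#' vertices.  A vertex freezes when its wall gap falls to
#' `contact_tolerance`; the radius is capped at `free_diameter / 2`.
#' Per-vertex radius is non-decreasing across iterations and never
#' penetrates the wall.
#'
#' @param tube a `simplex_tube` from [init_simplex_tube()].
#' @param vessel the watertight lumen [surface_mesh()].
#' @param cfg the [deployment_config()] used at initiation.
#' @return The expanded `simplex_tube`; `converged` is `FALSE` (with a
#'   warning) if fewer than 95\% of vertices settled within
#'   `max_iterations`.
#' @export
expand <- function(tube, vessel, cfg) {
  stopifnot(inherits(tube, "simplex_tube"),
            inherits(cfg, "deployment_config"))
  if (!validate_mesh(vessel)$watertight)
    stop("expand requires a watertight vessel mesh")
  Rwall <- wall_radii(tube, vessel)
  if (any(!is.finite(Rwall)))
    stop("wall query escaped the vessel; is the tube inside the lumen?")
  if (any(Rwall <= tube$radius))
    stop("initial tube penetrates the vessel wall")
  g <- cfg$growth_factor
  tol <- cfg$contact_tolerance
  cap <- tube$cap_radius
  r <- tube$radius
  contacted <- matrix(FALSE, tube$stations, tube$rings)
  capped <- matrix(FALSE, tube$stations, tube$rings)
  iter <- 0L
  phase1 <- 0L
  # phase 1: uniform multiplicative growth while no vertex would land
  # within one growth step of its wall (or the device cap)
  repeat {
    if (iter >= cfg$max_iterations) break
    nxt <- r * g
    if (any(nxt >= Rwall - tol) || any(nxt >= cap)) break
    r <- nxt
    iter <- iter + 1L
    phase1 <- phase1 + 1L
  }
  # phase 2: per-vertex advance with contact freezing + regularization
  while (iter < cfg$max_iterations) {
    active <- !contacted & !capped
    if (!any(active)) break
    # approach to half the contact tolerance so the realized gap stays
    # strictly within tolerance even against a chordally discretized wall
    step <- (g - 1) * r
    target <- pmin(r + step, Rwall - tol / 2, cap)
    r_new <- ifelse(active, pmax(r, target), r)
    # tangential regularization in radius space; monotone and clamped
    if (cfg$smoothing_weight > 0) {
      nb <- simplex_neighbor_mean(r_new)
      sm <- (1 - cfg$smoothing_weight) * r_new + cfg$smoothing_weight * nb
      r_new <- ifelse(active, pmin(pmax(r_new, sm), Rwall - tol / 2, cap),
                      r_new)
    }
    r <- r_new
    contacted <- contacted | (Rwall - r <= tol + 1e-12)
    capped <- capped | (r >= cap - 1e-12)
    iter <- iter + 1L
  }
  settled <- mean(contacted | capped)
  tube$radius <- r
  tube$state[] <- "active"
  tube$state[contacted] <- "contacted"
  tube$state[capped & !contacted] <- "capped"
  tube$expanded <- TRUE
  tube$iterations <- iter
  tube$phase1_iterations <- phase1
  tube$converged <- settled >= 0.95
  if (!tube$converged)
    warning(sprintf(
      "expansion reached max_iterations with only %.1f%% vertices settled",
      100 * settled))
  tube
}

#' Distance to the vessel wall along a ray
#'
#' First ray-mesh intersection distance from a point inside the lumen.
#'
#' @param point 3D point strictly inside the lumen (mm).
#' @param direction unit direction vector.
#' @param vessel a watertight [surface_mesh()].
#' @return distance in mm (`Inf` if the ray misses, impossible for a
#'   watertight lumen).
#' @export
wall_distance <- function(point, direction, vessel) {
  point <- as.numeric(point)
  direction <- as.numeric(direction)
  if (!inside_mesh(point, vessel))
    stop("wall_distance: point is outside the lumen")
  direction <- direction / sqrt(sum(direction^2))
  as.numeric(cpp_ray_first_hit(rbind(point), rbind(direction),
                               vessel$vertices, vessel$faces))
}

#' Triangulate the deployed simplex tube
#'
#' Open tube (no end caps), two triangles per quad cell, outward
#' orientation; surface vertices coincide with the tube vertices.
#'
#' @param tube an expanded `simplex_tube`.
#' @return A [surface_mesh()] with `2 * rings * (stations - 1)` triangles
#'   and `2 * rings` boundary edges (the two open ends).
#' @export
deployed_surface <- function(tube) {
  v <- tube_vertices(tube)
  S <- tube$stations
  K <- tube$rings
  vid <- function(s, k) (s - 1L) * K + ((k - 1L) %% K) + 1L
  faces <- vector("list", S - 1L)
  for (s in seq_len(S - 1L)) {
    k <- seq_len(K)
    faces[[s]] <- rbind(cbind(vid(s, k), vid(s, k + 1L), vid(s + 1L, k)),
                        cbind(vid(s + 1L, k), vid(s, k + 1L),
                              vid(s + 1L, k + 1L)))
  }
  surface_mesh(v, do.call(rbind, faces), provenance = "deployed stent tube")
}

#' Serialize a deployed tube to JSON
#'
#' Stores the cylindrical representation (centers, frames, radii) so a
#' deployment can be reloaded without re-running the expansion.
#'
#' @param tube a `simplex_tube`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_simplex_tube <- function(tube, path) {
  out <- unclass(tube)
  out$state <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a deployed tube written by [write_simplex_tube()]
#'
#' @param path JSON file.
#' @return A `simplex_tube`.
#' @export
read_simplex_tube <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tube <- list(stations = as.integer(x$stations),
               rings = as.integer(x$rings),
               centers = matrix(unlist(x$centers), ncol = 3),
               tangent = matrix(unlist(x$tangent), ncol = 3),
               normal = matrix(unlist(x$normal), ncol = 3),
               binormal = matrix(unlist(x$binormal), ncol = 3),
               station_arclength = as.numeric(x$station_arclength),
               theta = as.numeric(x$theta),
               radius = matrix(unlist(x$radius), nrow = as.integer(x$stations)),
               state = matrix("unknown", as.integer(x$stations),
                              as.integer(x$rings)),
               cap_radius = as.numeric(x$cap_radius),
               expanded = isTRUE(x$expanded), converged = x$converged,
               iterations = as.integer(x$iterations),
               phase1_iterations = as.integer(x$phase1_iterations))
  class(tube) <- "simplex_tube"
  tube
}
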