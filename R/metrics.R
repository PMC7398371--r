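# Deployment-quality and device-geometry metrics: the measurable surface
# of the pipeline (diameter, apposition, wire lengths, braid angle, metal
# coverage, phantom morphometrics).

#' Per-station deployed diameter profile
#'
#' Twice the mean radial distance of the ring vertices to the centerline
#' point of each station.
#'
#' @param tube a `simplex_tube`.
#' @return numeric vector, one diameter (mm) per station.
#' @export
diameter_profile <- function(tube) {
  stopifnot(inherits(tube, "simplex_tube"))
  2 * rowMeans(tube$radius)
}

#' Apposition gap statistics
#'
#' Residual gap between each stent vertex and the vessel wall along the
#' outward radial direction.
#'
#' @param tube a `simplex_tube`.
#' @param vessel the lumen [surface_mesh()].
#' @return `list(mean, max)` in mm.
#' @export
apposition_gap <- function(tube, vessel) {
  Rwall <- wall_radii(tube, vessel)
  gap <- Rwall - tube$radius
  if (any(gap < -1e-9))
    stop("integrity error: stent vertex outside the lumen (penetration)")
  list(mean = mean(gap), max = max(gap))
}

#' Axial length of the deployed stent
#'
#' Arclength span between the first and last stations along the
#' centerline.  Braided-stent foreshortening is deliberately neglected in
#' this model, so the deployed length equals the configured length.
#'
#' @param tube a `simplex_tube`.
#' @return length in mm.
#' @export
axial_length <- function(tube) {
  stopifnot(inherits(tube, "simplex_tube"))
  diff(range(tube$station_arclength))
}

#' Wire lengths
#'
#' @param model a `stent_model`.
#' @return numeric vector of polyline lengths (mm), one per wire.
#' @export
wire_lengths <- function(model) {
  vapply(model$wires, function(w)
    sum(sqrt(rowSums(diff(w$points)^2))), numeric(1))
}

#' Metal coverage of the braid
#'
#' Unrolls the deployed surface to the (arclength, circumference) plane,
#' rasterizes every wire as a strip of width `wire_diameter` along its
#' parameter-space path (periodic in the circumferential direction), and
#' reports the covered cell fraction.  Crossing wires count once, matching
#' physical projection.
#'
#' @param model a `stent_model`.
#' @param tube the `simplex_tube` the braid was mapped on.
#' @param raster_cells total raster cell budget (warns below 1e4).
#' @return coverage fraction in `[0, 1]`.
#' @export
metal_coverage <- function(model, tube, raster_cells = 4e4) {
  if (raster_cells < 1e4)
    warning("raster_cells below 1e4: coverage resolution is coarse")
  if (length(model$wires) == 0L) return(0)
  L <- axial_length(tube)
  W <- 2 * pi * mean(tube$radius)
  wd <- model$device$wire_diameter
  segs <- do.call(rbind, lapply(model$wires, function(w) {
    x <- w$sfrac * L
    y <- w$theta * W / (2 * pi)      # unwrapped; wrap handled in distance
    cbind(x[-length(x)], y[-length(y)], x[-1], y[-1])
  }))
  # wrap segment anchors into [0, W) while keeping each segment contiguous
  shift <- floor(segs[, 2] / W) * W
  segs[, 2] <- segs[, 2] - shift
  segs[, 4] <- segs[, 4] - shift
  ny <- max(10L, round(sqrt(raster_cells * W / L)))
  nx <- max(10L, round(raster_cells / ny))
  cx <- (seq_len(nx) - 0.5) * L / nx
  cy <- (seq_len(ny) - 0.5) * W / ny
  cells <- as.matrix(expand.grid(x = cx, y = cy))
  d <- cpp_min_dist_segments_2d(cells, segs, W)
  mean(d <= wd / 2)
}

#' Measured braid angle
#'
#' Mean over all wire segments of the angle between the segment and the
#' local centerline tangent.
#'
#' @param model a `stent_model`.
#' @param cl the deployment [centerline()] (station centers suffice).
#' @param by_handedness if `TRUE`, return a named vector with the cw and
#'   ccw means instead of the global mean.
#' @return angle in degrees.
#' @export
measure_braid_angle <- function(model, cl, by_handedness = FALSE) {
  angles <- lapply(model$wires, function(w) {
    p <- w$points
    seg <- normalize_rows(diff(p))
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
    # nearest centerline point's tangent
    idx <- vapply(seq_len(nrow(mid)), function(i) {
      d2 <- rowSums(sweep(cl$points, 2, mid[i, ])^2)
      which.min(d2)
    }, integer(1))
    tg <- cl$tangent[idx, , drop = FALSE]
    ct <- pmin(1, abs(rowSums(seg * tg)))
    acos(ct) * 180 / pi
  })
  hand <- vapply(model$wires, function(w) w$handedness, character(1))
  if (by_handedness) {
    c(cw = mean(unlist(angles[hand == "cw"])),
      ccw = mean(unlist(angles[hand == "ccw"])))
  } else {
    mean(unlist(angles))
  }
}

#' Pore density of the braid
#'
#' Counts parameter-space wire crossings (each clockwise wire crosses each
#' counter-clockwise wire `~2 * turns` times) as a surrogate for the pore
#' count of the diamond-cell arrangement and divides by the unrolled
#' surface area.  Convention-dependent near the ends; treat as an
#' order-of-magnitude figure.
#'
#' @param model a `stent_model`.
#' @param tube the `simplex_tube`.
#' @param turns helix turns used for the braid.
#' @return pores per mm^2.
#' @export
pore_density <- function(model, tube, turns) {
  hand <- vapply(model$wires, function(w) w$handedness, character(1))
  cw <- model$wires[hand == "cw"]
  ccw <- model$wires[hand == "ccw"]
  n <- 0L
  for (a in cw) for (b in ccw)
    n <- n + count_pair_crossings(turns, a$theta[1], b$theta[1])
  L <- axial_length(tube)
  W <- 2 * pi * mean(tube$radius)
  n / (L * W)
}

#' Aneurysm morphometrics
#'
#' Dome height is the maximum distance of sac-side vertices from the neck
#' plane along its normal; neck width is the largest sac extent parallel
#' to the plane (diameter of the projected sac point set).
#'
#' @param mesh a watertight aneurysm phantom [surface_mesh()].
#' @param neck_plane `list(point, normal)` ground-truth neck plane.
#' @return `list(neck_width, dome_height)` in mm.
#' @export
morphometrics <- function(mesh, neck_plane) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- as.numeric(neck_plane$normal)
  n <- n / sqrt(sum(n^2))
  p0 <- as.numeric(neck_plane$point)
  h <- as.numeric(sweep(mesh$vertices, 2, p0) %*% n)
  sac <- h > 1e-6
  if (!any(sac))
    stop("neck plane misses the mesh: no vertices on the sac side")
  dome_height <- max(h[sac])
  u <- perp_vector(n)
  v <- pracma_cross(n, u)
  q <- sweep(mesh$vertices[sac, , drop = FALSE], 2, p0)
  xy <- cbind(q %*% u, q %*% v)
  hull <- grDevices::chull(xy)
  hx <- xy[hull, , drop = FALSE]
  d2 <- as.matrix(stats::dist(hx))
  list(neck_width = max(d2), dome_height = dome_height)
}

#' Full deployment metrics report
#'
#' @param tube a deployed `simplex_tube`.
#' @param model a `stent_model` (or `NULL` to skip wire metrics).
#' @param vessel the lumen [surface_mesh()].
#' @param cl deployment centerline (for the braid angle).
#' @param turns helix turns used for the braid (for pore density).
#' @return A list of class `deployment_metrics`.
#' @export
deployment_metrics <- function(tube, model = NULL, vessel = NULL,
                               cl = NULL, turns = NULL) {
  prof <- diameter_profile(tube)
  out <- list(diameter_profile = prof,
              mean_diameter = mean(prof),
              max_diameter = max(prof),
              stent_length_axial = axial_length(tube))
  if (!is.null(vessel)) out$apposition_gap <- apposition_gap(tube, vessel)
  if (!is.null(model)) {
    out$wire_lengths <- wire_lengths(model)
    out$metal_coverage <- metal_coverage(model, tube)
    if (!is.null(cl)) out$braid_angle_measured <-
        measure_braid_angle(model, cl)
    if (!is.null(turns)) out$pore_density <-
        pore_density(model, tube, turns)
  }
  class(out) <- "deployment_metrics"
  out
}

#' Serialize a metrics report to JSON
#'
#' @param metrics a `deployment_metrics`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(c(list(schema = "fvstent-metrics-1"),
                         unclass(metrics)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
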