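# Parametric vessel and sidewall-aneurysm phantoms with analytic ground
# truth.  The reference phantom emulates a wide-necked sidewall aneurysm
# on a curved internal-carotid-like parent artery so the whole deployment
# pipeline is testable without patient data.

#' Phantom specification
#'
#' @param tube_diameter parent-vessel inner diameter (mm).
#' @param tube_length tube length (mm); for curved tubes this is derived
#'   from `bend_radius * bend_angle` and may be left `NULL`.
#' @param bend_radius centerline bend radius (mm) or `NULL` for straight.
#' @param bend_angle bend angle in degrees (5..170 supported).
#' @param aneurysm `NULL` or a list with `neck_width`, `dome_height`,
#'   `dome_width` (mm) and `azimuth` (degrees; 0 = outer side of the bend).
#' @param mesh_resolution target edge length / iso-surface grid spacing (mm).
#' @param jitter optional radial surface jitter sd (mm), default 0 (off).
#' @param seed integer seed used only when `jitter > 0`.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(tube_diameter = 4.5, tube_length = 30,
                         bend_radius = NULL, bend_angle = NULL,
                         aneurysm = NULL, mesh_resolution = 0.35,
                         jitter = 0, seed = 1L) {
  if (!is.numeric(tube_diameter) || tube_diameter <= 0)
    stop("tube_diameter must be positive")
  if (!is.null(bend_radius)) {
    if (bend_radius <= tube_diameter / 2)
      stop("bend_radius must exceed the tube radius")
    if (is.null(bend_angle) || bend_angle < 5 || bend_angle > 170)
      stop("bend_angle must be between 5 and 170 degrees")
    tube_length <- bend_radius * bend_angle * pi / 180
  }
  if (!is.numeric(tube_length) || tube_length <= 0)
    stop("tube_length must be positive")
  if (!is.null(aneurysm)) {
    need <- c("neck_width", "dome_height", "dome_width")
    if (!all(need %in% names(aneurysm)))
      stop("aneurysm needs neck_width, dome_height, dome_width")
    if (is.null(aneurysm$azimuth)) aneurysm$azimuth <- 0
    if (aneurysm$neck_width > aneurysm$dome_width)
      stop("neck_width must not exceed dome_width")
    if (aneurysm$dome_height <= 0) stop("dome_height must be positive")
    if (aneurysm$dome_width >= 6 * tube_diameter)
      stop("dome parameters would swallow the tube")
  }
  if (mesh_resolution <= 0) stop("mesh_resolution must be positive")
  structure(list(tube_diameter = tube_diameter, tube_length = tube_length,
                 bend_radius = bend_radius, bend_angle = bend_angle,
                 aneurysm = aneurysm, mesh_resolution = mesh_resolution,
                 jitter = jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Reference phantom preset
#'
#' The study configuration: a 4.5 mm curved parent artery (bend radius
#' 20 mm, 100 degrees, giving a 34.9 mm segment able to host a 23 mm
#' device) carrying a wide-necked sidewall aneurysm of neck width
#' 12.27 mm and dome height 9.35 mm on the outer side of the bend.
#' Deterministic: two calls return identical specs.
#'
#' @return A [phantom_spec()].
#' @export
reference_phantom_preset <- function() {
  phantom_spec(tube_diameter = 4.5,
               bend_radius = 20, bend_angle = 100,
               aneurysm = list(neck_width = 12.27, dome_height = 9.35,
                               dome_width = 12.27, azimuth = 0),
               mesh_resolution = 0.35)
}

ensure_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

# Build a capped tube from rings of cross-section circles.
# centers: n_ax x 3; nvec/bvec: cross-section frame per station.
tube_from_rings <- function(centers, nvec, bvec, radius, n_circ,
                            provenance, jitter = 0, seed = 1L) {
  n_ax <- nrow(centers)
  theta <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  verts <- matrix(0, n_ax * n_circ + 2L, 3L)
  rr <- matrix(radius, n_ax, n_circ)
  if (jitter > 0) {
    set.seed(seed)
    rr <- rr + matrix(stats::rnorm(n_ax * n_circ, 0, jitter), n_ax, n_circ)
  }
  for (i in seq_len(n_ax)) {
    ring <- centers[rep(i, n_circ), , drop = FALSE] +
      outer(rr[i, ] * cos(theta), nvec[i, ]) +
      outer(rr[i, ] * sin(theta), bvec[i, ])
    verts[((i - 1) * n_circ + 1):(i * n_circ), ] <- ring
  }
  c_bot <- n_ax * n_circ + 1L
  c_top <- n_ax * n_circ + 2L
  verts[c_bot, ] <- centers[1, ]
  verts[c_top, ] <- centers[n_ax, ]
  vid <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  faces <- vector("list", n_ax)
  for (i in seq_len(n_ax - 1L)) {
    j <- seq_len(n_circ)
    faces[[i]] <- rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
                        cbind(vid(i + 1L, j), vid(i, j + 1L),
                              vid(i + 1L, j + 1L)))
  }
  j <- seq_len(n_circ)
  cap_bot <- cbind(rep(c_bot, n_circ), vid(1L, j + 1L), vid(1L, j))
  cap_top <- cbind(rep(c_top, n_circ), vid(n_ax, j), vid(n_ax, j + 1L))
  f <- do.call(rbind, c(faces[seq_len(n_ax - 1L)], list(cap_bot, cap_top)))
  ensure_outward(surface_mesh(verts, f, provenance = provenance))
}

phantom_truth <- function(centerline, neck_plane, radius_profile) {
  structure(list(centerline = centerline, neck_plane = neck_plane,
                 nominal_radius_profile = radius_profile),
            class = "phantom_truth")
}

#' Generate a straight tube phantom
#'
#' A watertight capped cylinder along the z axis, lateral vertices exactly
#' on the nominal radius.  Ground truth is the analytic axis centerline.
#'
#' @param spec a [phantom_spec()] without a bend.
#' @return `list(mesh, truth)` with a [surface_mesh()] and a
#'   `phantom_truth` (fields `centerline`, `neck_plane`,
#'   `nominal_radius_profile`).
#' @export
make_straight_tube <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$bend_radius))
    stop("spec has a bend; use make_curved_tube")
  r <- spec$tube_diameter / 2
  L <- spec$tube_length
  res <- spec$mesh_resolution
  n_circ <- max(16L, ceiling(2 * pi * r / res))
  n_ax <- max(2L, ceiling(L / res) + 1L)
  z <- seq(0, L, length.out = n_ax)
  centers <- cbind(0, 0, z)
  nvec <- matrix(rep(c(1, 0, 0), n_ax), ncol = 3, byrow = TRUE)
  bvec <- matrix(rep(c(0, 1, 0), n_ax), ncol = 3, byrow = TRUE)
  mesh <- tube_from_rings(centers, nvec, bvec, r, n_circ,
                          "synthetic straight tube",
                          jitter = spec$jitter, seed = spec$seed)
  cl <- centerline(centers, radius = rep(r, n_ax))
  truth <- phantom_truth(cl, NULL,
                         data.frame(arclength = z, radius = r))
  list(mesh = mesh, truth = truth)
}

# Arc helpers: centerline c(phi) = R (cos phi, sin phi, 0), phi in [0, Phi].
arc_point <- function(R, phi) cbind(R * cos(phi), R * sin(phi), 0)
arc_tangent <- function(phi) cbind(-sin(phi), cos(phi), 0)
arc_outward <- function(phi) cbind(cos(phi), sin(phi), 0)

#' Generate a curved (torus-segment) tube phantom
#'
#' The centerline is a circular arc of radius `bend_radius` spanning
#' `bend_angle` degrees in the xy plane; ends are closed with planar caps.
#'
#' @param spec a [phantom_spec()] with `bend_radius` set.
#' @return `list(mesh, truth)` as in [make_straight_tube()].
#' @export
make_curved_tube <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(spec$bend_radius))
    stop("spec has no bend; use make_straight_tube")
  r <- spec$tube_diameter / 2
  R <- spec$bend_radius
  Phi <- spec$bend_angle * pi / 180
  res <- spec$mesh_resolution
  arc_len <- R * Phi
  n_circ <- max(16L, ceiling(2 * pi * r / res))
  n_ax <- max(2L, ceiling(arc_len / res) + 1L)
  phi <- seq(0, Phi, length.out = n_ax)
  centers <- arc_point(R, phi)
  nvec <- arc_outward(phi)
  bvec <- matrix(rep(c(0, 0, 1), n_ax), ncol = 3, byrow = TRUE)
  mesh <- tube_from_rings(centers, nvec, bvec, r, n_circ,
                          "synthetic curved tube",
                          jitter = spec$jitter, seed = spec$seed)
  truth <- curved_truth(spec)
  list(mesh = mesh, truth = truth)
}

curved_truth <- function(spec, n_pts = 4001L) {
  R <- spec$bend_radius
  Phi <- spec$bend_angle * pi / 180
  phi <- seq(0, Phi, length.out = n_pts)
  cl <- centerline(arc_point(R, phi),
                   radius = rep(spec$tube_diameter / 2, n_pts))
  phantom_truth(cl, NULL,
                data.frame(arclength = R * phi,
                           radius = spec$tube_diameter / 2))
}

# Smooth minimum (polynomial, blend width k).
smooth_min <- function(a, b, k) {
  h <- pmin(pmax(0.5 + 0.5 * (b - a) / k, 0), 1)
  b + h * (a - b) - k * h * (1 - h)
}

# Depth of the ostium plane below the tube surface, as a fraction of the
# tube radius: the neck plane sits at (2/3) r above the centerline, giving
# a finite aperture into the sac while keeping the parent lumen calibre.
OSTIUM_DEPTH_FRACTION <- 2 / 3

aneurysm_geometry <- function(spec) {
  r <- spec$tube_diameter / 2
  an <- spec$aneurysm
  a_semi <- an$dome_width / 2
  beta <- sqrt(max(0, 1 - (an$neck_width / an$dome_width)^2))
  c_semi <- an$dome_height / (1 + beta)
  z0 <- beta * c_semi
  R <- spec$bend_radius
  Phi <- spec$bend_angle * pi / 180
  phim <- Phi / 2
  t_m <- as.numeric(arc_tangent(phim))
  n_out <- as.numeric(arc_outward(phim))
  az <- an$azimuth * pi / 180
  w <- cos(az) * n_out + sin(az) * c(0, 0, 1)
  anchor <- as.numeric(arc_point(R, phim))
  h0 <- OSTIUM_DEPTH_FRACTION * r
  p0 <- anchor + h0 * w             # neck-plane point
  c0 <- p0 + z0 * w                 # ellipsoid center
  e1 <- t_m
  e2 <- pracma_cross(w, e1)
  list(a_semi = a_semi, c_semi = c_semi, z0 = z0, w = w, p0 = p0, c0 = c0,
       e1 = e1, e2 = e2, blend_k = 0.3)
}

# Implicit field of the curved tube (with planar end caps) blended with
# the plane-clipped dome ellipsoid; negative inside.
aneurysm_field <- function(P, spec, geo) {
  r <- spec$tube_diameter / 2
  R <- spec$bend_radius
  Phi <- spec$bend_angle * pi / 180
  phi <- pmin(pmax(atan2(P[, 2], P[, 1]), 0), Phi)
  ax <- R * cos(phi)
  ay <- R * sin(phi)
  d_arc <- sqrt((P[, 1] - ax)^2 + (P[, 2] - ay)^2 + P[, 3]^2)
  f_tube <- d_arc - r
  # end-cap half spaces: outside beyond phi = 0 (plane y = 0) and phi = Phi
  f_cap0 <- -P[, 2]
  cP <- as.numeric(arc_point(R, Phi))
  tP <- as.numeric(arc_tangent(Phi))
  f_cap1 <- (P[, 1] - cP[1]) * tP[1] + (P[, 2] - cP[2]) * tP[2]
  f_vessel <- pmax(f_tube, f_cap0, f_cap1)
  q <- sweep(P, 2, geo$c0)
  q1 <- q %*% geo$e1
  q2 <- q %*% geo$e2
  qn <- q %*% geo$w
  nv <- sqrt((q1 / geo$a_semi)^2 + (q2 / geo$a_semi)^2 +
             (qn / geo$c_semi)^2)
  f_ell <- (nv - 1) * min(geo$a_semi, geo$c_semi)
  # clip the ellipsoid to the sac side of the neck plane
  below <- -(sweep(P, 2, geo$p0) %*% geo$w)
  f_dome <- pmax(as.numeric(f_ell), as.numeric(below))
  smooth_min(f_vessel, f_dome, geo$blend_k)
}

#' Generate a sidewall-aneurysm phantom
#'
#' Blends an ellipsoidal dome onto a curved parent tube with a smooth-min
#' implicit union and extracts the iso-surface by marching tetrahedra on a
#' uniform grid at `mesh_resolution` spacing.  The ellipsoid is clipped to
#' the sac side of the neck plane, which sits 2/3 of the tube radius above
#' the centerline so the sac communicates with the lumen through a finite
#' ostium.  Ground truth records the analytic arc centerline and the neck
#' plane.  With `aneurysm = NULL` the output is identical to
#' [make_curved_tube()].
#'
#' @param spec a [phantom_spec()] with `bend_radius` and `aneurysm` set.
#' @return `list(mesh, truth)`; `truth$neck_plane` is
#'   `list(point, normal)`.
#' @export
make_sidewall_aneurysm <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(spec$aneurysm)) return(make_curved_tube(spec))
  if (is.null(spec$bend_radius))
    stop("sidewall aneurysm phantom requires a curved parent tube")
  geo <- aneurysm_geometry(spec)
  res <- spec$mesh_resolution
  r <- spec$tube_diameter / 2
  R <- spec$bend_radius
  Phi <- spec$bend_angle * pi / 180
  phi_s <- seq(0, Phi, length.out = 200)
  arc <- arc_point(R, phi_s)
  margin <- r + 3 * res + geo$blend_k
  dome_reach <- max(geo$a_semi, geo$c_semi) + 3 * res + geo$blend_k
  lo <- pmin(apply(arc, 2, min) - margin, geo$c0 - dome_reach)
  hi <- pmax(apply(arc, 2, max) + margin, geo$c0 + dome_reach)
  xs <- seq(lo[1], hi[1], by = res)
  ys <- seq(lo[2], hi[2], by = res)
  zs <- seq(lo[3], hi[3], by = res)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  f <- aneurysm_field(grid, spec, geo)
  # keep the iso-surface strictly off grid vertices (sign-preserving snap,
  # so inside/outside classification is unchanged) to avoid sliver faces
  near <- abs(f) < 1e-4
  f[near] <- ifelse(f[near] >= 0, 1e-4, -1e-4)
  mt <- cpp_marching_tetrahedra(f, xs, ys, zs, 0)
  mesh <- ensure_outward(surface_mesh(mt$vertices, mt$faces,
                                      provenance = "synthetic sidewall aneurysm"))
  truth <- curved_truth(spec)
  truth$neck_plane <- list(point = geo$p0, normal = geo$w)
  list(mesh = mesh, truth = truth)
}

#' Generate a phantom from a spec
#'
#' Dispatch helper: straight tube, curved tube, or sidewall aneurysm
#' depending on which spec blocks are set.
#'
#' @param spec a [phantom_spec()].
#' @return `list(mesh, truth)`.
#' @export
make_phantom <- function(spec) {
  if (!is.null(spec$aneurysm)) make_sidewall_aneurysm(spec)
  else if (!is.null(spec$bend_radius)) make_curved_tube(spec)
  else make_straight_tube(spec)
}

#' Serialize phantom ground truth to JSON
#'
#' @param truth a `phantom_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phantom_truth <- function(truth, path) {
  out <- list(
    centerline = list(points = unname(truth$centerline$points),
                      radius = truth$centerline$radius),
    neck_plane = if (is.null(truth$neck_plane)) NULL else
      list(point = truth$neck_plane$point,
           normal = truth$neck_plane$normal),
    nominal_radius_profile = truth$nominal_radius_profile)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
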