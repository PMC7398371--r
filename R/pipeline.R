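# End-to-end orchestration: phantom/vessel -> validation -> centerline ->
# deployment -> braid -> metrics, with a reproducibility manifest.

# One flat table of defaults; unknown keys are rejected everywhere.
default_run_config <- function() {
  list(
    # phantom
    preset = "reference",            # reference | straight | curved
    tube_diameter = 4.5, tube_length = 30,
    bend_radius = 20, bend_angle = 100,
    neck_width = 12.27, dome_height = 9.35, dome_width = 12.27,
    azimuth = 0, mesh_resolution = 0.35,
    # deployment
    stent_length = 23, free_diameter = 4.5, initial_radius = 0.5,
    growth_factor = 1.3, contact_tolerance = 0.05, smoothing_weight = 0.3,
    max_iterations = 500, rings = 32, stations_per_mm = 2,
    center_arclength = NA,
    # braid
    n_wires = 16, braid_angle = 60, wire_diameter = 0.06, phase = 0,
    n_sides = 8, samples_per_station = 4,
    # misc
    seed = 1, log_level = "info")
}

#' Build a run configuration
#'
#' Merges overrides into the documented defaults; unknown keys are
#' rejected.
#'
#' @param ... named overrides of the default keys (see
#'   [write_config_reference()] for the full list).
#' @param file optional flat `key = value` config file applied before
#'   `...`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- default_run_config()
  apply_kv <- function(cfg, kv) {
    unknown <- setdiff(names(kv), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(cfg, kv)
  }
  if (!is.null(file)) cfg <- apply_kv(cfg, parse_config_file(file))
  kv <- list(...)
  if (length(kv) > 0L) cfg <- apply_kv(cfg, kv)
  structure(cfg, class = "run_config")
}

# Flat "key = value" text; '#' comments; numbers auto-coerced.
parse_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("bad config line: ", ln)
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num else val
  }
  kv
}

#' Write the configuration reference page
#'
#' One generated page documenting every config key and its default.
#'
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_config_reference <- function(path) {
  cfg <- default_run_config()
  writeLines(c("# fvstent run configuration keys and defaults",
               sprintf("%s = %s", names(cfg),
                       vapply(cfg, function(v) format(v), character(1)))),
             path)
  invisible(path)
}

# Polynomial rolling hash over the deparsed config (stable manifest id).
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

phantom_spec_from_config <- function(cfg) {
  if (cfg$preset == "straight") {
    phantom_spec(tube_diameter = cfg$tube_diameter,
                 tube_length = cfg$tube_length,
                 mesh_resolution = cfg$mesh_resolution, seed = cfg$seed)
  } else if (cfg$preset == "curved") {
    phantom_spec(tube_diameter = cfg$tube_diameter,
                 bend_radius = cfg$bend_radius, bend_angle = cfg$bend_angle,
                 mesh_resolution = cfg$mesh_resolution, seed = cfg$seed)
  } else if (cfg$preset == "reference") {
    phantom_spec(tube_diameter = cfg$tube_diameter,
                 bend_radius = cfg$bend_radius, bend_angle = cfg$bend_angle,
                 aneurysm = list(neck_width = cfg$neck_width,
                                 dome_height = cfg$dome_height,
                                 dome_width = cfg$dome_width,
                                 azimuth = cfg$azimuth),
                 mesh_resolution = cfg$mesh_resolution, seed = cfg$seed)
  } else stop("unknown preset: ", cfg$preset)
}

log_stage <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message("[fvstent] ", ...)
  invisible(NULL)
}

#' Run the full virtual stenting pipeline
#'
#' Executes vessel validation, centerline extraction, simplex-tube
#' expansion, braid mapping, wire sweeping and metrics, writing all
#' artifacts plus a manifest into `out_dir`.  Reruns with the same config
#' and inputs reproduce the geometry bit-identically.
#'
#' @param config a [run_config()].
#' @param vessel path to a lumen STL, or `NULL` to synthesize the phantom
#'   named by `config$preset`.
#' @param out_dir output directory (created if needed).
#' @param centerline_csv optional precomputed centerline CSV; when given,
#'   extraction is skipped.
#' @param seeds optional `list(a, b)` of centerline seed points (required
#'   for a user-supplied vessel without `centerline_csv`).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), vessel = NULL,
                         out_dir = ".", centerline_csv = NULL,
                         seeds = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function() proc.time()[["elapsed"]]

  # stage: vessel geometry (synthesize or load)
  t0 <- tick()
  truth <- NULL
  if (is.null(vessel)) {
    log_stage(config, "stage: synthetic phantom (", config$preset, ")")
    ph <- make_phantom(phantom_spec_from_config(config))
    mesh <- ph$mesh
    truth <- ph$truth
  } else {
    log_stage(config, "stage: load vessel ", vessel)
    mesh <- read_surface_mesh(vessel)
  }
  timings$vessel <- tick() - t0

  # stage: validation
  t0 <- tick()
  log_stage(config, "stage: vessel validation")
  rep <- validate_mesh(mesh)
  report_path <- file.path(out_dir, "validation.json")
  write_validation_report(rep, report_path)
  if (!rep$watertight)
    stop("pipeline failed at validation: vessel mesh is not watertight")
  timings$validation <- tick() - t0

  # stage: centerline (extract, or load from CSV)
  t0 <- tick()
  if (!is.null(centerline_csv)) {
    log_stage(config, "stage: centerline from file")
    if (!file.exists(centerline_csv))
      stop("missing centerline input: ", centerline_csv)
    cl <- read_polyline(centerline_csv)
  } else {
    log_stage(config, "stage: centerline extraction")
    if (is.null(seeds)) {
      if (is.null(truth))
        stop("user-supplied vessel needs seeds or a centerline CSV")
      tc <- truth$centerline
      L <- total_arclength(tc)
      ends <- interp_centerline(tc, c(min(1, L / 20), L - min(1, L / 20)))
      seeds <- list(a = ends$points[1, ], b = ends$points[2, ])
    }
    cl <- extract_centerline(mesh, seeds$a, seeds$b)
  }
  cl_path <- file.path(out_dir, "centerline.csv")
  write_polyline(cl, cl_path)
  timings$centerline <- tick() - t0

  # stage: deployment
  t0 <- tick()
  log_stage(config, "stage: simplex tube initiation and expansion")
  dcfg <- deployment_config(
    stent_length = config$stent_length, free_diameter = config$free_diameter,
    initial_radius = config$initial_radius,
    growth_factor = config$growth_factor,
    contact_tolerance = config$contact_tolerance,
    smoothing_weight = config$smoothing_weight,
    max_iterations = config$max_iterations, rings = config$rings,
    stations_per_mm = config$stations_per_mm)
  center <- if (is.na(config$center_arclength)) NULL
            else config$center_arclength
  tube <- init_simplex_tube(cl, dcfg, center)
  tube <- expand(tube, mesh, dcfg)
  dep_path <- file.path(out_dir, "deployed.stl")
  write_surface_mesh(deployed_surface(tube), dep_path)
  timings$deployment <- tick() - t0

  # stage: braid mapping and sweep
  t0 <- tick()
  log_stage(config, "stage: braid pattern mapping")
  turns <- braid_angle_design(config$free_diameter, config$stent_length,
                              config$braid_angle)
  wires <- generate_wire_paths(tube, n_wires = config$n_wires,
                               turns = turns, phase = config$phase,
                               wire_diameter = config$wire_diameter,
                               samples_per_station = config$samples_per_station)
  model <- sweep_wires(wires, wire_diameter = config$wire_diameter,
                       n_sides = config$n_sides,
                       device = list(free_diameter = config$free_diameter,
                                     length = config$stent_length,
                                     n_wires = config$n_wires,
                                     turns = turns,
                                     wire_diameter = config$wire_diameter))
  stent_path <- file.path(out_dir, "stent.stl")
  write_surface_mesh(model$swept, stent_path)
  timings$braid <- tick() - t0

  # stage: metrics
  t0 <- tick()
  log_stage(config, "stage: metrics")
  met <- deployment_metrics(tube, model, mesh, cl, turns)
  met_path <- file.path(out_dir, "metrics.json")
  write_metrics(met, met_path)
  timings$metrics <- tick() - t0

  manifest <- list(
    tool = "fvstent",
    version = as.character(utils::packageVersion("fvstent")),
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    artifacts = list(validation = "validation.json",
                     centerline = "centerline.csv",
                     deployed = "deployed.stl",
                     stent = "stent.stl",
                     metrics = "metrics.json"),
    timings_s = lapply(timings, function(x) round(x, 3)),
    total_s = round(tick() - t_start, 3))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
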