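# Configuration files, test fixtures, exporters and run manifests.
#
# Configs are YAML key trees; unspecified keys fall back to the package
# defaults (the published cell/tissue parameter set). All lengths in
# config files are mm, forces N, rates in their printed units.

#' Load a scenario configuration from YAML
#'
#' Missing keys take the package defaults, so an empty file yields the
#' full default parameter set. Recognized top-level keys: `scenario`,
#' `domain` (arguments of [healing_domain()]), `materials` (list of
#' `region: [E, nu]`), `ec`, `ovsc`, and the scalar run controls of
#' [scenario_config()]. Validation failures name the offending fields.
#'
#' @param path YAML file path.
#' @return `scenario_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  dom_args <- raw$domain %||% list()
  domain <- do.call(healing_domain, dom_args)
  materials <- default_material_table()
  if (!is.null(raw$materials)) {
    for (nm in names(raw$materials)) {
      i <- match(nm, materials$region)
      if (is.na(i)) stop("unknown region in materials: ", nm)
      v <- raw$materials[[nm]]
      materials$E[i] <- v[[1]]
      if (length(v) > 1) materials$nu[i] <- v[[2]]
    }
  }
  args <- list(
    scenario = raw$scenario %||% "baseline-rigid",
    domain = domain, materials = materials,
    ec = raw$ec %||% list(), ovsc = raw$ovsc %||% list()
  )
  for (nm in c("iteration_minutes", "horizon_days", "replicates", "seed",
               "target_gap_strain", "bc_amplitude", "asymmetry",
               "update_order", "shared_occupancy", "durotaxis_exact"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(scenario_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a scenario configuration to YAML
#'
#' Round-trips through [load_config()]: `load_config(save_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config `scenario_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  mat <- config$materials
  out <- list(
    scenario = config$scenario,
    domain = config$domain[names(config$domain)],
    materials = stats::setNames(
      lapply(seq_len(nrow(mat)), function(i) c(mat$E[i], mat$nu[i])),
      mat$region),
    ec = config$ec, ovsc = config$ovsc,
    iteration_minutes = config$iteration_minutes,
    horizon_days = config$horizon_days,
    replicates = config$replicates, seed = config$seed,
    target_gap_strain = config$target_gap_strain,
    asymmetry = config$asymmetry, update_order = config$update_order,
    shared_occupancy = config$shared_occupancy,
    durotaxis_exact = config$durotaxis_exact
  )
  if (!is.null(config$bc_amplitude)) out$bc_amplitude <- config$bc_amplitude
  class(out$domain) <- NULL
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Build small test fixtures
#'
#' Ready-made configurations for unit testing the behavioural rules:
#' * `"uniform-strain"`: an all-granulation square domain with an imposed
#'   uniform strain field (`ep`, `theta`), bypassing the FE solve;
#' * `"two-stiffness"`: a square domain whose left half is soft
#'   granulation (0.2 MPa) and right half stiff marrow-like tissue
#'   (2 MPa), the durotaxis test harness;
#' * `"tiny-osteotomy"`: a scaled-down full geometry that runs a complete
#'   7-day simulation in seconds.
#'
#' @param kind Fixture kind.
#' @param size Elements per side for the square fixtures (>= 4).
#' @param pitch Lattice pitch in mm.
#' @param ep,theta Imposed strain magnitude/direction for
#'   `"uniform-strain"`.
#' @param ... Further arguments passed to [scenario_config()].
#' @return `scenario_config` (with `$fixture_mesh` attached for the
#'   square fixtures).
#' @export
make_fixture <- function(kind = c("uniform-strain", "two-stiffness",
                                  "tiny-osteotomy"),
                         size = 40, pitch = 0.01, ep = 0, theta = 90, ...) {
  kind <- match.arg(kind)
  stopifnot(size >= 4)
  if (kind == "tiny-osteotomy") {
    dom <- healing_domain(gap_width = 0.3, cortex_thickness = 0.1,
                          marrow_width = 0.2, domain_width = 0.8,
                          domain_height = 1.0, callus_radius = 0.45,
                          pitch = 0.02)
    return(scenario_config(domain = dom, ...))
  }
  side <- size * pitch
  # dummy region extents, snapped to the lattice (regions are overwritten)
  dom <- healing_domain(gap_width = floor(size / 2) * pitch,
                        cortex_thickness = floor(size / 4) * pitch,
                        marrow_width = floor(size / 4) * pitch,
                        domain_width = side, domain_height = side,
                        callus_radius = 2 * side, pitch = pitch)
  extra <- list(...)
  # rule harnesses start empty; agents are placed with seed_tip()/seed_cell()
  ec0 <- utils::modifyList(list(seed_frac_periosteum = 0, seed_frac_marrow = 0,
                                ingrowth_prob = 0, branch_coeff = 0),
                           extra$ec %||% list())
  ov0 <- utils::modifyList(list(seed_frac = 0), extra$ovsc %||% list())
  extra$ec <- ec0; extra$ovsc <- ov0
  cfg <- do.call(scenario_config,
                 c(list(scenario = "unloaded", domain = dom), extra))
  if (kind == "uniform-strain") cfg$fixed_strain <- list(ep = ep, theta = theta)
  cfg$fixture <- kind
  cfg$fixture_size <- size
  cfg$fixture_pitch <- pitch
  cfg
}

#' Place a single tip cell or stromal cell in a simulation state
#'
#' Manual agent placement for rule-level experiments on fixture domains.
#'
#' @param state `sim_state`.
#' @param node Lattice node id (must be free).
#' @param direction Initial growth direction code 1..8 (or `NA`).
#' @return Invisibly, the new sprout/cell index.
#' @export
seed_tip <- function(state, node, direction = NA_integer_) {
  stopifnot(ec_free(state, node))
  idx <- add_sprouts(state, node, prev_dir = as.integer(direction))
  invisible(idx)
}

#' @rdname seed_tip
#' @param orient Stromal orientation code 1..4.
#' @export
seed_cell <- function(state, node, orient) {
  stopifnot(ov_free(state, node), orient %in% 1:4)
  state$ov_node <- c(state$ov_node, as.integer(node))
  state$ov_orient <- c(state$ov_orient, as.integer(orient))
  state$ov_alive <- c(state$ov_alive, TRUE)
  state$ov_occ[node] <- TRUE
  invisible(length(state$ov_node))
}

#' Build an all-granulation square mesh
#'
#' A homogeneous test mesh with every element labelled gap granulation;
#' for `two_stiffness = TRUE` the right half is marrow-stiff (2 MPa).
#'
#' @param size Elements per side.
#' @param pitch Pitch (mm).
#' @param two_stiffness Stiffen the right half.
#' @return `fe_mesh` with materials assigned.
#' @export
square_mesh <- function(size = 40, pitch = 0.01, two_stiffness = FALSE) {
  side <- size * pitch
  # dummy region extents, snapped to the lattice (regions are overwritten)
  dom <- healing_domain(gap_width = floor(size / 2) * pitch,
                        cortex_thickness = floor(size / 4) * pitch,
                        marrow_width = floor(size / 4) * pitch,
                        domain_width = side, domain_height = side,
                        callus_radius = 2 * side, pitch = pitch)
  mesh <- build_mesh(dom)
  mesh$region[] <- 3L   # all gap granulation
  if (two_stiffness) {
    xc <- element_centroids(mesh)[, 1]
    mesh$region[xc > side / 2] <- 2L   # marrow-stiff right half
  }
  mesh$node_region <- node_regions(mesh)
  assign_materials(mesh)
}

# ---- exporters ----------------------------------------------------------

#' Export mesh, fields and agents as CSV
#'
#' `write_mesh_csv` writes nodes (id, x, y) and elements (id, four nodes,
#' region, E, nu); `write_strain_csv` writes per-element strain tensors
#' and principal values; `write_vessels_csv` writes per-sprout polylines
#' (sprout id, vertex order, x, y); `write_ovsc_csv` writes stromal
#' positions and orientations.
#'
#' @param mesh,field,result Objects to export.
#' @param path Output file (for `write_mesh_csv`, a stem producing
#'   `<stem>_nodes.csv` and `<stem>_elements.csv`).
#' @return The written path(s), invisibly.
#' @export
write_mesh_csv <- function(mesh, path) {
  xy <- node_coords(mesh)
  nodes <- data.frame(node = seq_len(mesh$nn), x = xy[, 1], y = xy[, 2])
  els <- data.frame(element = seq_len(mesh$ne),
                    n1 = mesh$enodes[, 1], n2 = mesh$enodes[, 2],
                    n3 = mesh$enodes[, 3], n4 = mesh$enodes[, 4],
                    region = REGION_LEVELS[mesh$region])
  if (!is.null(mesh$E)) { els$E <- mesh$E; els$nu <- mesh$nu }
  p1 <- paste0(path, "_nodes.csv"); p2 <- paste0(path, "_elements.csv")
  utils::write.csv(nodes, p1, row.names = FALSE)
  utils::write.csv(els, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_mesh_csv
#' @export
write_strain_csv <- function(field, path) {
  utils::write.csv(data.frame(element = seq_along(field$exx),
                              exx = field$exx, eyy = field$eyy,
                              gxy = field$gxy, ep_max_abs = field$ep,
                              theta = field$theta),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mesh_csv
#' @export
write_vessels_csv <- function(result, path) {
  rows <- lapply(seq_along(result$path), function(s) {
    p <- result$path[[s]]
    xy <- node_coords(result$mesh, p)
    data.frame(sprout = s, vertex = seq_along(p), x = xy[, 1], y = xy[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mesh_csv
#' @export
write_ovsc_csv <- function(result, path) {
  xy <- node_coords(result$mesh, result$ov_node)
  utils::write.csv(data.frame(x = xy[, 1], y = xy[, 2],
                              orientation = c("horizontal", "diagonal_right",
                                              "vertical", "diagonal_left")[result$ov_orient]),
                   path, row.names = FALSE)
  invisible(path)
}

# node-lattice raster (ny+1 rows, nx+1 cols, row 1 = top) from a value per node
node_raster <- function(mesh, values) {
  m <- matrix(values, nrow = mesh$nx + 1L)
  t(m)[(mesh$ny + 1L):1, , drop = FALSE]
}

#' Export raster maps as PNG
#'
#' `write_region_png` colours the tissue regions; `write_strain_png` maps
#' |EP_max_abs| to a heat scale; `write_vessel_png` writes the binary
#' vessel mask at lattice resolution; `write_frame_png` overlays vessels
#' (red) and stromal cells (orientation-coded) on the region map — a
#' sequence of frames over the iterations yields a movie of the healing
#' simulation.
#'
#' @param mesh,field,result Objects to render.
#' @param path Output PNG path.
#' @param strain_cap Strain magnitude mapped to full heat (default 0.3).
#' @return `path`, invisibly.
#' @export
write_region_png <- function(mesh, path) {
  cols <- c("#9e9e9e", "#ffe082", "#ef9a9a", "#a5d6a7", "#eeeeee")
  rgbv <- grDevices::col2rgb(cols[mesh$node_region]) / 255
  img <- array(0, c(mesh$ny + 1L, mesh$nx + 1L, 3))
  for (k in 1:3) img[, , k] <- node_raster(mesh, rgbv[k, ])
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_region_png
#' @export
write_strain_png <- function(field, mesh, path, strain_cap = 0.3) {
  v <- pmin(abs(field$ep) / strain_cap, 1)
  m <- matrix(v, nrow = mesh$nx)
  img <- array(0, c(mesh$ny, mesh$nx, 3))
  mm <- t(m)[mesh$ny:1, , drop = FALSE]
  img[, , 1] <- mm
  img[, , 3] <- 1 - mm
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_region_png
#' @export
write_vessel_png <- function(result, path) {
  png::writePNG(node_raster(result$mesh, as.numeric(result$ec_occ)), path)
  invisible(path)
}

#' @rdname write_region_png
#' @export
write_frame_png <- function(result, path) {
  mesh <- result$mesh
  base <- c("#bdbdbd", "#fff3cd", "#f5c6c6", "#d8f0d8", "#f5f5f5")
  col <- base[mesh$node_region]
  col[result$ec_occ] <- "#c62828"
  ocol <- c("#1565c0", "#6a1b9a", "#2e7d32", "#ef6c00")
  col[result$ov_node] <- ocol[result$ov_orient]
  rgbv <- grDevices::col2rgb(col) / 255
  img <- array(0, c(mesh$ny + 1L, mesh$nx + 1L, 3))
  for (k in 1:3) img[, , k] <- node_raster(mesh, rgbv[k, ])
  png::writePNG(img, path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run with the same build: config
#' fingerprint, scenario, seeds, iteration count, wall time and the
#' inventory of exported files.
#'
#' @param result `sim_result` (or `replicate_set`).
#' @param path Output JSON path.
#' @param files Character vector of exported file paths.
#' @param elapsed Optional elapsed seconds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path, files = character(), elapsed = NA) {
  cfg <- if (inherits(result, "sim_result")) result$config else NULL
  manifest <- list(
    package = "sproutmech",
    version = as.character(utils::packageVersion("sproutmech")),
    scenario = if (!is.null(cfg)) cfg$scenario else NA,
    config_hash = if (!is.null(cfg)) fnv1a(yaml::as.yaml(unclass(cfg))) else NA,
    seed = if (inherits(result, "sim_result")) result$seed else result$seeds,
    iterations = if (inherits(result, "sim_result")) result$iterations else NA,
    elapsed_s = elapsed,
    files = as.list(files),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_region_png
#' @param spacing Quiver arrow spacing in elements (default 8).
#' @export
write_direction_png <- function(field, mesh, path, spacing = 8L,
                                strain_cap = 0.3) {
  xy <- element_centroids(mesh)
  keep <- which((seq_len(mesh$ne) - 1L) %% mesh$nx %% spacing == 0L &
                  (seq_len(mesh$ne) - 1L) %/% mesh$nx %% spacing == 0L)
  th <- field$theta[keep] * pi / 180
  len <- pmin(abs(field$ep[keep]) / strain_cap, 1) * spacing * mesh$pitch / 2
  grDevices::png(path, width = 4 * mesh$nx, height = 4 * mesh$ny, res = 300)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot(NA, xlim = c(0, mesh$nx * mesh$pitch),
                 ylim = c(0, mesh$ny * mesh$pitch), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::segments(xy[keep, 1] - len * cos(th), xy[keep, 2] - len * sin(th),
                     xy[keep, 1] + len * cos(th), xy[keep, 2] + len * sin(th),
                     col = "#00000088")
  invisible(path)
}
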