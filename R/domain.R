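#' Region labels of the healing-domain mesh
#'
#' Integer-coded tissue regions used throughout the package. Cortical bone
#' elements are structural only: their nodes are never available as lattice
#' positions for migrating cells.
#'
#' @format Character vector of the five region names, in code order.
#' @export
REGION_LEVELS <- c("CORTICAL_BONE", "BONE_MARROW", "GAP_GRANULATION",
                   "PERIOSTEAL_GRANULATION", "OUTSIDE_CALLUS")

#' Describe the mid-longitudinal healing-region geometry
#'
#' Defines the 2D mid-longitudinal section of a stabilized mouse femoral
#' osteotomy: two cortical walls enclosing the marrow cavity, a transverse
#' osteotomy gap filled with granulation tissue, and a circular periosteal
#' callus centred on the gap midpoint. All lengths are millimetres. The
#' defaults describe a 0.7 mm osteotomy with a 4 mm diameter callus; the
#' remaining extents are configuration values whose defaults visually match
#' the healing region of a mouse femur.
#'
#' @param gap_width Osteotomy gap height along the bone axis (mm).
#' @param cortex_thickness Thickness of each cortical wall (mm).
#' @param marrow_width Width of the marrow cavity (mm).
#' @param domain_width,domain_height Extent of the modelled domain (mm).
#'   `x` is the medio-lateral direction, `y` the bone long axis.
#' @param callus_radius Initial radius of the circular callus front (mm);
#'   the default 2.0 corresponds to a 4 mm callus diameter.
#' @param pitch Lattice/mesh pitch (mm). Finite-element node coordinates
#'   double as the cell lattice, so the pitch is both the element size and
#'   the cell diameter (default 0.01 mm).
#' @return An object of class `healing_domain`.
#' @seealso [build_mesh()], [define_rois()]
#' @export
healing_domain <- function(gap_width = 0.7, cortex_thickness = 0.2,
                           marrow_width = 1.0, domain_width = 4,
                           domain_height = 5, callus_radius = 2.0,
                           pitch = 0.01) {
  lens <- c(gap_width = gap_width, cortex_thickness = cortex_thickness,
            marrow_width = marrow_width, domain_width = domain_width,
            domain_height = domain_height, callus_radius = callus_radius,
            pitch = pitch)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all healing_domain lengths must be positive and finite")
  if (marrow_width + 2 * cortex_thickness > domain_width)
    stop("bone (marrow + two cortices) wider than the domain")
  if (gap_width >= domain_height)
    stop("gap_width must be smaller than domain_height")
  # every region boundary must land on a lattice line exactly
  for (nm in c("gap_width", "cortex_thickness", "marrow_width",
               "domain_width", "domain_height")) {
    r <- lens[[nm]] / pitch
    if (abs(r - round(r)) > 1e-6)
      stop(sprintf("%s (%g mm) is not divisible by the lattice pitch (%g mm)",
                   nm, lens[[nm]], pitch))
  }
  structure(as.list(lens), class = "healing_domain")
}

#' @export
print.healing_domain <- function(x, ...) {
  cat("Healing domain (mm):",
      sprintf("%g x %g, gap %g, cortex %g, marrow %g, callus radius %g, pitch %g\n",
              x$domain_width, x$domain_height, x$gap_width,
              x$cortex_thickness, x$marrow_width, x$callus_radius, x$pitch))
  invisible(x)
}

#' Build the regular quadrilateral mesh of a healing domain
#'
#' Meshes the domain on a regular grid of square 4-node plane-strain
#' elements whose node spacing equals the lattice pitch, and labels every
#' element with its tissue region. The osteotomy gap band spans the full
#' bone width (both cortical walls and the marrow column); tissue outside
#' the bone but inside the callus circle is periosteal granulation;
#' elements whose centroid lies beyond the callus radius are labelled
#' `OUTSIDE_CALLUS` (mechanically they carry granulation-tissue
#' properties).
#'
#' Node numbering is row-major from the lower-left corner; element `e`
#' connects its four corner nodes counter-clockwise. Node coordinates are
#' exactly the lattice points available to cell agents.
#'
#' @param domain A [healing_domain()].
#' @return An object of class `fe_mesh`: a list with grid sizes `nx`, `ny`
#'   (elements per direction), node count `nn`, element count `ne`,
#'   integer `region` per element (see [REGION_LEVELS]), the element
#'   connectivity matrix `enodes` (`ne x 4`), and node/element coordinate
#'   accessors used by the solver.
#' @export
build_mesh <- function(domain) {
  stopifnot(inherits(domain, "healing_domain"))
  p <- domain$pitch
  nx <- as.integer(round(domain$domain_width / p))
  ny <- as.integer(round(domain$domain_height / p))
  nn <- (nx + 1L) * (ny + 1L)
  ne <- nx * ny
  cx <- domain$domain_width / 2
  cy <- domain$domain_height / 2

  ex <- rep.int(seq_len(nx) - 1L, ny)          # element column, 0-based
  ey <- rep(seq_len(ny) - 1L, each = nx)       # element row, 0-based
  xc <- (ex + 0.5) * p
  yc <- (ey + 0.5) * p

  dxc <- abs(xc - cx)
  half_marrow <- domain$marrow_width / 2
  half_bone <- half_marrow + domain$cortex_thickness
  in_marrow_col <- dxc < half_marrow
  in_cortex_col <- !in_marrow_col & dxc < half_bone
  in_gap_band <- abs(yc - cy) < domain$gap_width / 2
  r2 <- (xc - cx)^2 + (yc - cy)^2

  region <- integer(ne)
  region[in_cortex_col & !in_gap_band] <- 1L              # CORTICAL_BONE
  region[in_marrow_col & !in_gap_band] <- 2L              # BONE_MARROW
  region[(in_cortex_col | in_marrow_col) & in_gap_band] <- 3L  # GAP
  outer <- !(in_cortex_col | in_marrow_col)
  region[outer & r2 <= domain$callus_radius^2] <- 4L      # PERIOSTEAL
  region[outer & r2 > domain$callus_radius^2] <- 5L       # OUTSIDE_CALLUS

  # ccw connectivity: lower-left, lower-right, upper-right, upper-left
  n1 <- ex + (nx + 1L) * ey + 1L
  enodes <- cbind(n1, n1 + 1L, n1 + nx + 2L, n1 + nx + 1L, deparse.level = 0)

  mesh <- list(nx = nx, ny = ny, pitch = p, nn = nn, ne = ne,
               cx = cx, cy = cy, region = region, enodes = enodes,
               E = NULL, nu = NULL, domain = domain)
  class(mesh) <- "fe_mesh"
  mesh$inc <- incident_elements(mesh)
  mesh$node_region <- node_regions(mesh)
  mesh
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("fe_mesh: %d x %d elements (%d nodes), pitch %g mm\n",
              x$nx, x$ny, x$nn, x$pitch))
  tab <- table(factor(REGION_LEVELS[x$region], levels = REGION_LEVELS))
  print(tab)
  if (!is.null(x$E)) cat("materials assigned\n")
  invisible(x)
}

#' Node coordinates of a mesh
#'
#' @param mesh An `fe_mesh`.
#' @param nodes Optional node ids; default all nodes.
#' @return Two-column matrix of (x, y) in mm.
#' @export
node_coords <- function(mesh, nodes = seq_len(mesh$nn)) {
  ix <- (nodes - 1L) %% (mesh$nx + 1L)
  iy <- (nodes - 1L) %/% (mesh$nx + 1L)
  cbind(x = ix * mesh$pitch, y = iy * mesh$pitch)
}

#' Element centroid coordinates
#' @param mesh An `fe_mesh`.
#' @return Two-column matrix of centroid (x, y) in mm.
#' @export
element_centroids <- function(mesh) {
  ex <- (seq_len(mesh$ne) - 1L) %% mesh$nx
  ey <- (seq_len(mesh$ne) - 1L) %/% mesh$nx
  cbind(x = (ex + 0.5) * mesh$pitch, y = (ey + 0.5) * mesh$pitch)
}

# Incident elements of each node as an nn x 4 matrix (NA off-grid).
# Order: SW, SE, NW, NE element relative to the node.
incident_elements <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  nodes <- seq_len(mesh$nn)
  ix <- (nodes - 1L) %% (nx + 1L)
  iy <- (nodes - 1L) %/% (nx + 1L)
  eid <- function(ex, ey) {
    ok <- ex >= 0L & ex < nx & ey >= 0L & ey < ny
    out <- ifelse(ok, ex + nx * ey + 1L, NA_integer_)
    out
  }
  cbind(eid(ix - 1L, iy - 1L), eid(ix, iy - 1L),
        eid(ix - 1L, iy), eid(ix, iy))
}

# Label nodes by their incident elements. A node touching any cortical
# element is cortical (blocked for agents); otherwise gap, marrow and
# periosteal labels take priority over outside-callus.
node_regions <- function(mesh) {
  inc <- if (!is.null(mesh$inc)) mesh$inc else incident_elements(mesh)
  reg <- matrix(mesh$region[inc], nrow = mesh$nn)
  out <- integer(mesh$nn)
  has <- function(code) {
    rowSums(reg == code, na.rm = TRUE) > 0
  }
  out[has(5L)] <- 5L
  out[has(4L)] <- 4L
  out[has(2L)] <- 2L
  out[has(3L)] <- 3L
  out[has(1L)] <- 1L   # cortical wins
  out
}

#' Default material table
#'
#' Young's modulus (MPa) and Poisson's ratio per tissue region. Granulation
#' tissue 0.2 MPa / 0.167, bone marrow 2 MPa / 0.167, cortical bone
#' 5000 MPa / 0.3. Tissue outside the callus circle carries granulation
#' properties.
#'
#' @return data.frame with columns `region`, `E`, `nu`.
#' @export
default_material_table <- function() {
  data.frame(
    region = REGION_LEVELS,
    E = c(5000, 2, 0.2, 0.2, 0.2),
    nu = c(0.3, 0.167, 0.167, 0.167, 0.167),
    stringsAsFactors = FALSE
  )
}

#' Assign linear-elastic materials to a mesh
#'
#' @param mesh An `fe_mesh`.
#' @param table data.frame with columns `region` (names from
#'   [REGION_LEVELS]), `E` (MPa) and `nu`. Defaults to
#'   [default_material_table()].
#' @return The mesh with per-element `E` and `nu` filled in.
#' @export
assign_materials <- function(mesh, table = default_material_table()) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (!all(c("region", "E", "nu") %in% names(table)))
    stop("material table needs columns region, E, nu")
  present <- REGION_LEVELS[sort(unique(mesh$region))]
  missing <- setdiff(present, table$region)
  if (length(missing))
    stop("material table misses regions present in the mesh: ",
         paste(missing, collapse = ", "))
  idx <- match(REGION_LEVELS[mesh$region], table$region)
  if (any(table$nu >= 0.5))
    stop("Poisson's ratio must be < 0.5 under plane strain")
  if (any(table$E <= 0)) stop("Young's modulus must be positive")
  mesh$E <- table$E[idx]
  mesh$nu <- table$nu[idx]
  mesh
}

#' Define regions of interest
#'
#' Returns the quantification ROIs (endosteal gap, marrow, periosteal) and
#' the three strain-reporting boxes on the medial side: periosteal (PS),
#' intracortical (I) and endosteal (ES). Default rectangles are placed from
#' the domain geometry; a custom `roi_spec` (data.frame with `id`, `xmin`,
#' `ymin`, `xmax`, `ymax`) replaces them.
#'
#' @param domain A [healing_domain()].
#' @param roi_spec Optional replacement rectangles.
#' @return data.frame of class `roi_set` with one row per ROI.
#' @export
define_rois <- function(domain, roi_spec = NULL) {
  stopifnot(inherits(domain, "healing_domain"))
  W <- domain$domain_width; H <- domain$domain_height
  cx <- W / 2; cy <- H / 2
  hm <- domain$marrow_width / 2
  hb <- hm + domain$cortex_thickness
  hg <- domain$gap_width / 2
  if (is.null(roi_spec)) {
    marrow_h <- min(1.0, cy - hg)      # marrow ROI height above the gap
    peri_w <- min(0.3, cx - hb)        # periosteal strip width
    # the periosteal ROI runs along the cortex over the callus extent
    peri_h <- min(0.8 * domain$callus_radius, cy)
    roi_spec <- data.frame(
      id = c("ROI1_gap", "ROI2_marrow", "ROI3_periosteum", "PS", "I", "ES"),
      xmin = c(cx - hm, cx - hm, cx + hb, cx - hb - peri_w, cx - hb, cx - hm / 2),
      ymin = c(cy - hg, cy + hg, cy - peri_h, cy - hg, cy - hg, cy - hg),
      xmax = c(cx + hm, cx + hm, cx + hb + peri_w, cx - hb, cx - hm, cx + hm / 2),
      ymax = c(cy + hg, cy + hg + marrow_h, cy + peri_h,
               cy + hg, cy + hg, cy + hg),
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(roi_spec$id))
    stop("duplicate ROI ids: ",
         paste(unique(roi_spec$id[duplicated(roi_spec$id)]), collapse = ", "))
  bad <- roi_spec$xmin < -1e-9 | roi_spec$ymin < -1e-9 |
    roi_spec$xmax > W + 1e-9 | roi_spec$ymax > H + 1e-9 |
    roi_spec$xmin >= roi_spec$xmax | roi_spec$ymin >= roi_spec$ymax
  if (any(bad))
    stop("ROI outside the domain or degenerate: ",
         paste(roi_spec$id[bad], collapse = ", "))
  class(roi_spec) <- c("roi_set", "data.frame")
  roi_spec
}

# Logical mask of nodes inside an ROI rectangle (closed box).
nodes_in_roi <- function(mesh, roi) {
  xy <- node_coords(mesh)
  xy[, 1] >= roi$xmin - 1e-9 & xy[, 1] <= roi$xmax + 1e-9 &
    xy[, 2] >= roi$ymin - 1e-9 & xy[, 2] <= roi$ymax + 1e-9
}

# Logical mask of elements whose centroid lies inside an ROI rectangle.
elements_in_roi <- function(mesh, roi) {
  xy <- element_centroids(mesh)
  xy[, 1] >= roi$xmin - 1e-9 & xy[, 1] <= roi$xmax + 1e-9 &
    xy[, 2] >= roi$ymin - 1e-9 & xy[, 2] <= roi$ymax + 1e-9
}

roi_by_id <- function(rois, id) {
  i <- match(id, rois$id)
  if (is.na(i)) stop("no ROI named ", id)
  rois[i, , drop = FALSE]
}

#' Desk-scale study geometry
#'
#' The reference geometry used by the packaged study runs: the full bone
#' cross-section (1.0 mm marrow cavity, 0.2 mm cortices, 0.7 mm osteotomy
#' gap) at the 0.01 mm lattice pitch, with a complete (unclipped) callus
#' circle of 0.9 mm radius inside a 1.9 x 1.9 mm domain. Compared to the
#' full-size geometry this scales down only the surrounding callus extent;
#' all cell-scale physics (pitch, gap, cortical thickness) is unchanged.
#'
#' @param pitch Lattice pitch in mm (default 0.01).
#' @return A [healing_domain()].
#' @export
study_domain <- function(pitch = 0.01) {
  healing_domain(gap_width = 0.7, cortex_thickness = 0.2, marrow_width = 1.0,
                 domain_width = 1.9, domain_height = 1.9,
                 callus_radius = 0.9, pitch = pitch)
}
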