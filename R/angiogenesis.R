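# Agent-based model of sprouting angiogenesis on the node lattice.
#
# Microvessels are ordered sequences of endothelial cells (ECs) occupying
# lattice points. Each active sprout has one leading TIP cell; cells left
# behind are STALK cells. Tip migration direction mixes persistence (P1),
# randomness (P2) and a principal-strain rule (P3). Tips act as contractile
# force dipoles along the growth direction; stalk cells exert no traction.
#
# Simulation state is a mutable environment created by the scheduler; the
# functions here operate on that environment (fields documented in
# scheduler.R).

#' Default endothelial-cell growth-rule parameters
#'
#' The probabilistic migration mix (`p1` persistence, `p2` random, `p3`
#' strain rule), the strain thresholds of the guidance rule (parallel up
#' to 5%, fully perpendicular from 10%, migration halt above 30%), the
#' vessel growth rate (15 um/h) and the tip traction-dipole magnitude
#' (total 20 uN). `branch_coeff` is the per-um per-iteration branching
#' probability density; `oop_prob = 10/17` is the out-of-plane departure
#' probability applied every `oop_period` iterations to tips that last
#' moved in a random direction.
#'
#' @return Named list of parameters.
#' @export
ec_params <- function() {
  list(p1 = 0.4, p2 = 0.4, p3 = 0.2,
       strain_parallel_max = 0.05, strain_perpendicular_min = 0.10,
       strain_halt = 0.30,
       growth_rate_um_h = 15,
       ec_force_total = 20e-6,
       branch_coeff = 1e-5,
       oop_period = 15L, oop_prob = 10 / 17,
       ingrowth_prob = 0.005, ingrowth_density_cap = 0.10,
       seed_frac_periosteum = 0.10, seed_frac_marrow = 0.01,
       periosteum_layer_mm = 0.03)
}

# ---- sprout bookkeeping -------------------------------------------------

# append new single-cell sprouts at `nodes` (assumed free); marks occupancy
add_sprouts <- function(state, nodes, prev_dir = rep(NA_integer_, length(nodes))) {
  if (!length(nodes)) return(invisible(NULL))
  n0 <- state$n_sprouts
  idx <- n0 + seq_along(nodes)
  state$tip[idx] <- nodes
  state$active[idx] <- TRUE
  state$loop[idx] <- FALSE
  state$halted[idx] <- FALSE
  state$prev_dir[idx] <- prev_dir
  state$last_branch[idx] <- NA_integer_
  state$accum[idx] <- 0
  state$len_um[idx] <- 0
  for (k in seq_along(nodes)) state$path[[n0 + k]] <- nodes[k]
  state$ec_occ[nodes] <- TRUE
  state$n_sprouts <- n0 + length(nodes)
  invisible(idx)
}

#' Seed the initial endothelial cells
#'
#' Occupies 10% of the lattice points of the periosteum — the thin
#' vascularized membrane lining the outer cortex surface
#' (`periosteum_layer_mm` thick) — and 1% of the bone marrow points with
#' single-cell sprouts, and seeds every free lattice point on the callus
#' circumference (the entry front of vessels invading from the
#' surrounding soft tissue). The callus granulation itself starts
#' avascular and is vascularized by ingrowth.
#'
#' @param state Simulation state environment (see [sim_init()]).
#' @return Invisibly, the number of sprouts seeded.
#' @export
seed_initial_ecs <- function(state) {
  mesh <- state$mesh
  par <- state$config$ec
  eligible_p <- which(periosteum_layer(state) & ec_free(state))
  eligible_m <- which(mesh$node_region == 2L & ec_free(state))
  sel_p <- eligible_p[stats::runif(length(eligible_p)) < par$seed_frac_periosteum]
  sel_m <- eligible_m[stats::runif(length(eligible_m)) < par$seed_frac_marrow]
  add_sprouts(state, c(sel_p, sel_m))
  # callus circumference: the pre-existing vasculature surrounding the
  # callus enters as connected arcs of endothelial cells along the
  # circle of the initial front radius (clipped at the domain boundary)
  xy <- node_coords(mesh)
  d <- sqrt((xy[, 1] - mesh$cx)^2 + (xy[, 2] - mesh$cy)^2)
  ring <- which(abs(d - state$front_radius) <= mesh$pitch / 2 & ec_free(state))
  if (length(ring)) {
    ang <- atan2(xy[ring, 2] - mesh$cy, xy[ring, 1] - mesh$cx)
    ring <- ring[order(ang)]
    # split into 8-connected arcs
    rx <- (ring - 1L) %% (mesh$nx + 1L)
    ry <- (ring - 1L) %/% (mesh$nx + 1L)
    brk <- c(1L, which(pmax(abs(diff(rx)), abs(diff(ry))) > 1L) + 1L,
             length(ring) + 1L)
    for (k in seq_len(length(brk) - 1L)) {
      arc <- ring[brk[k]:(brk[k + 1L] - 1L)]
      add_vessel_path(state, arc)
    }
  }
  invisible(state$n_sprouts)
}

# add a pre-formed, inactive vessel path (no tip); serves as a fusion
# target and a branching source
add_vessel_path <- function(state, nodes) {
  n0 <- state$n_sprouts
  idx <- n0 + 1L
  state$tip[idx] <- nodes[length(nodes)]
  state$active[idx] <- FALSE
  state$loop[idx] <- FALSE
  state$halted[idx] <- FALSE
  state$prev_dir[idx] <- NA_integer_
  state$last_branch[idx] <- NA_integer_
  state$accum[idx] <- 0
  state$len_um[idx] <- path_length_um(state$mesh, nodes)
  state$path[[idx]] <- nodes
  state$ec_occ[nodes] <- TRUE
  state$n_sprouts <- idx
  invisible(idx)
}

# periosteal membrane: periosteal-granulation nodes within a thin layer
# of the outer cortex surface
periosteum_layer <- function(state) {
  mesh <- state$mesh
  layer <- state$config$ec$periosteum_layer_mm
  if (!is.finite(layer)) return(mesh$node_region == 4L)
  dom <- mesh$domain
  hb <- dom$marrow_width / 2 + dom$cortex_thickness
  xy <- node_coords(mesh)
  dx <- abs(xy[, 1] - mesh$cx)
  mesh$node_region == 4L & dx <= hb + layer + 1e-9
}

# ---- direction choice ---------------------------------------------------

#' Strain-rule target axis
#'
#' The guidance axis of the strain-based migration rule: parallel to the
#' absolute maximum principal strain direction for |EP| <= 5%, fully
#' perpendicular for |EP| >= 10%, with a linear angular ramp in between
#' (the rotation side of the ramp is chosen at random, symmetrically).
#' Inputs above the 30% halt threshold are the caller's responsibility.
#'
#' @param ep Absolute maximum principal strain (signed); `NA` means no
#'   strain signal and falls back to the 90-degree (bone axis) tie-break.
#' @param theta Strain direction in degrees, [0, 180).
#' @param params EC parameter list (see [ec_params()]).
#' @return Target axis in degrees, [0, 180).
#' @export
strain_target_angle <- function(ep, theta, params = ec_params()) {
  a <- abs(ep)
  theta <- ifelse(is.na(theta), 90, theta)
  lo <- params$strain_parallel_max
  hi <- params$strain_perpendicular_min
  frac <- pmin(1, pmax(0, (a - lo) / (hi - lo)))
  frac[is.na(frac)] <- 0
  sgn <- ifelse(stats::runif(length(theta)) < 0.5, -1, 1)
  (theta + sgn * 90 * frac) %% 180
}

#' Choose migration directions for a set of tips
#'
#' For each tip: if the local strain magnitude exceeds the halt threshold
#' the tip does not migrate this iteration. Otherwise a uniform draw picks
#' persistence (probability `p1`, requires a previous direction),
#' randomness (`p2`: uniform over the 8 lattice directions) or the strain
#' rule (`p3`: nearest lattice direction to the [strain_target_angle()],
#' forward sense avoiding immediate reversal). Tips without a previous
#' direction renormalize the draw over the random and strain branches.
#'
#' @param ep,theta Node-sampled strain magnitude and direction per tip.
#' @param prev_dir Previous direction codes (1..8 or `NA`).
#' @param params EC parameter list.
#' @return List with integer `dir` (NA = halted), integer `branch`
#'   (1 persistence, 2 random, 3 strain) and logical `halted`.
#' @export
choose_directions <- function(ep, theta, prev_dir, params = ec_params()) {
  n <- length(ep)
  halted <- !is.na(ep) & abs(ep) > params$strain_halt
  branch <- integer(n)
  u <- stats::runif(n)
  branch[u < params$p1] <- 1L
  branch[u >= params$p1 & u < params$p1 + params$p2] <- 2L
  branch[u >= params$p1 + params$p2] <- 3L
  # no persistence memory: split the persistence draw over the other rules
  redo <- branch == 1L & is.na(prev_dir)
  if (any(redo)) {
    p23 <- params$p2 + params$p3
    if (p23 <= 0) {
      branch[redo] <- 2L
    } else {
      branch[redo] <- ifelse(stats::runif(sum(redo)) < params$p2 / p23, 2L, 3L)
    }
  }
  dir <- rep(NA_integer_, n)
  i1 <- which(branch == 1L & !halted)
  dir[i1] <- prev_dir[i1]
  i2 <- which(branch == 2L & !halted)
  if (length(i2)) dir[i2] <- sample.int(8L, length(i2), replace = TRUE)
  i3 <- which(branch == 3L & !halted)
  if (length(i3)) {
    tgt <- strain_target_angle(ep[i3], theta[i3], params)
    dir[i3] <- axis_to_direction(tgt, prev_dir[i3])
  }
  list(dir = dir, branch = branch, halted = halted)
}

# ---- elongation, anastomosis, branching ---------------------------------

#' Advance all active tips by one iteration
#'
#' Each iteration credits the elongation accumulator with
#' `growth_rate * dt` (5 um at the default 15 um/h and 20-min steps); a
#' tip steps to the neighbouring lattice point in its chosen direction
#' once the accumulated length covers the step (one pitch straight,
#' sqrt(2) pitches diagonal). Moving into a point occupied by another
#' vessel (or the own path) triggers anastomosis: the cell loses its tip
#' phenotype and the sprout stops; moving into a stromal cell or a blocked
#' point skips growth for the iteration. Strain above the halt threshold
#' at the tip node suspends migration while it persists.
#'
#' @param state Simulation state environment.
#' @return Invisibly, the number of completed steps this iteration.
#' @export
advance_tips <- function(state) {
  par <- state$config$ec
  mesh <- state$mesh
  credit <- par$growth_rate_um_h * state$config$iteration_minutes / 60
  pitch_um <- mesh$pitch * 1000
  act <- which(state$active[seq_len(state$n_sprouts)])
  if (!length(act)) return(invisible(0L))
  state$accum[act] <- pmin(state$accum[act] + credit, 2 * pitch_um * sqrt(2))
  movers <- act[state$accum[act] >= pitch_um]
  if (!length(movers)) return(invisible(0L))

  s <- sample_strain_at_nodes(state$field, mesh, state$tip[movers])
  ch <- choose_directions(s$ep, s$theta, state$prev_dir[movers], par)
  state$halted[movers] <- ch$halted
  state$last_branch[movers] <- ch$branch

  moved <- 0L
  ord <- sample.int(length(movers))
  ec_occ <- state$ec_occ
  path <- state$path
  tip <- state$tip
  active <- state$active
  loopf <- state$loop
  prev_dir <- state$prev_dir
  accum <- state$accum
  len_um <- state$len_um
  for (k in ord) {
    sp <- movers[k]
    d <- ch$dir[k]
    if (is.na(d)) next                       # halted this iteration
    cost <- pitch_um * DIR_NORM[d]
    if (accum[sp] < cost) next               # wait for diagonal credit
    tgt <- neighbour_nodes(mesh, tip[sp], d)
    if (is.na(tgt) || state$blocked[tgt]) next
    if (ec_occ[tgt]) {                       # vessel point: anastomosis
      active[sp] <- FALSE
      if (tgt %in% path[[sp]]) loopf[sp] <- TRUE
      next
    }
    if (state$shared_occ && state$ov_occ[tgt]) next  # stromal cell blocks
    ec_occ[tgt] <- TRUE
    path[[sp]] <- c(path[[sp]], tgt)
    tip[sp] <- tgt
    prev_dir[sp] <- d
    accum[sp] <- accum[sp] - cost
    len_um[sp] <- len_um[sp] + cost
    moved <- moved + 1L
  }
  state$ec_occ <- ec_occ
  state$path <- path
  state$tip <- tip
  state$active <- active
  state$loop <- loopf
  state$prev_dir <- prev_dir
  state$accum <- accum
  state$len_um <- len_um
  invisible(moved)
}

# path length in um of a node path on the lattice
path_length_um <- function(mesh, path) {
  if (length(path) < 2) return(0)
  xy <- node_coords(mesh, path)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)) * 1000
}

#' Stochastic branching from existing vessel segments
#'
#' Each sprout spawns at most one new tip per iteration; the probability is
#' proportional to the sprout's current length (`branch_coeff` per um).
#' The new tip buds from a random interior point of the parent path into a
#' free neighbouring lattice point and starts without persistence memory.
#'
#' @param state Simulation state environment.
#' @return Invisibly, the number of branches formed.
#' @export
branch_sprouts <- function(state) {
  par <- state$config$ec
  if (par$branch_coeff <= 0) return(invisible(0L))
  mesh <- state$mesh
  ns <- state$n_sprouts
  lens <- state$len_um[seq_len(ns)]
  lens[lengths(state$path[seq_len(ns)]) < 3] <- 0
  p <- pmin(1, par$branch_coeff * lens)
  chosen <- which(stats::runif(ns) < p)
  made <- 0L
  for (sp in chosen) {
    path <- state$path[[sp]]
    interior <- path[2:(length(path) - 1)]
    origin <- interior[sample.int(length(interior), 1)]
    nbr <- neighbour_matrix(mesh, origin)
    free <- nbr[!is.na(nbr)]
    free <- free[ec_free(state, free)]
    if (!length(free)) next
    node <- free[sample.int(length(free), 1)]
    add_sprouts(state, node)
    made <- made + 1L
  }
  invisible(made)
}

#' Out-of-plane tip exchange
#'
#' Every `oop_period` iterations, tips whose last migration used the
#' random branch leave the plane with probability 10/17 (10 of the 17
#' candidate positions in a 3D neighbourhood lie out of plane). An equal
#' number of tips enters from the out-of-plane direction at uniformly
#' random free granulation points below the 10% local endothelial density
#' cap, with a random initial direction and no persistence memory of the
#' previous section.
#'
#' @param state Simulation state environment.
#' @return Invisibly, the number of exchanged tips.
#' @export
out_of_plane_exchange <- function(state) {
  par <- state$config$ec
  mesh <- state$mesh
  ns <- state$n_sprouts
  eligible <- which(state$active[seq_len(ns)] &
                      !is.na(state$last_branch[seq_len(ns)]) &
                      state$last_branch[seq_len(ns)] == 2L)
  if (!length(eligible)) return(invisible(0L))
  leave <- eligible[stats::runif(length(eligible)) < par$oop_prob]
  if (!length(leave)) return(invisible(0L))
  state$active[leave] <- FALSE
  # arrivals equal departures, at free granulation points whose local
  # endothelial density is below the crowding cap (re-entering vessels
  # invade open tissue rather than saturated regions)
  entry <- which(ec_free(state) &
                   state$mesh$node_region %in% c(3L, 4L, 5L))
  if (length(entry)) {
    dens <- local_ec_density(state, entry)
    entry <- entry[dens < par$ingrowth_density_cap]
  }
  n_in <- min(length(leave), length(entry))
  if (n_in > 0) {
    nodes <- entry[sample.int(length(entry), n_in)]
    add_sprouts(state, nodes,
                prev_dir = sample.int(8L, n_in, replace = TRUE))
  }
  invisible(length(leave))
}

# fraction of EC-occupied points in the 8-neighbourhood + self
local_ec_density <- function(state, nodes) {
  nbr <- neighbour_matrix(state$mesh, nodes)
  m <- cbind(nodes, nbr)
  occm <- matrix(state$ec_occ[m], nrow = length(nodes))
  occm[is.na(m)] <- NA
  rowMeans(occm, na.rm = TRUE)
}

#' Callus-front vessel ingrowth
#'
#' The virtual callus circumference shrinks at the vessel growth rate.
#' Lattice points swept by the front (newly external to the shrinking
#' circle) may spawn a new endothelial cell with probability 0.5%,
#' provided the local endothelial density (8-neighbourhood and the point
#' itself) is below 10%.
#'
#' @param state Simulation state environment.
#' @return Invisibly, the number of cells spawned.
#' @export
callus_ingrowth <- function(state) {
  par <- state$config$ec
  mesh <- state$mesh
  if (state$front_radius <= 0) return(invisible(0L))
  dr <- par$growth_rate_um_h * state$config$iteration_minutes / 60 / 1000  # mm
  r_old <- state$front_radius
  r_new <- max(0, r_old - dr)
  state$front_radius <- r_new
  xy <- node_coords(mesh)
  d <- sqrt((xy[, 1] - mesh$cx)^2 + (xy[, 2] - mesh$cy)^2)
  swept <- which(d > r_new & d <= r_old & ec_free(state))
  if (!length(swept)) return(invisible(0L))
  trial <- swept[stats::runif(length(swept)) < par$ingrowth_prob]
  if (!length(trial)) return(invisible(0L))
  dens <- local_ec_density(state, trial)
  trial <- trial[dens < par$ingrowth_density_cap]
  add_sprouts(state, trial)
  invisible(length(trial))
}

#' Traction loads of the active tip cells
#'
#' Each tip with a growth direction is a contractile force dipole along
#' that direction: two forces of half the total magnitude on the two
#' lattice nodes adjacent to the tip along the axis, both pointing toward
#' the cell core. Stalk cells exert no traction. Tips at the domain edge
#' with a missing adjacent node are skipped.
#'
#' @param tips Integer tip node ids.
#' @param dirs Direction codes (1..8) per tip; `NA` entries are skipped.
#' @param mesh `fe_mesh`.
#' @param total_force Total dipole magnitude in N (default 20e-6).
#' @return A `point_load_set`.
#' @export
ec_traction_loads <- function(tips, dirs, mesh, total_force = 20e-6) {
  keep <- !is.na(dirs)
  tips <- tips[keep]; dirs <- dirs[keep]
  if (!length(tips)) return(point_load_set())
  ahead <- neighbour_nodes(mesh, tips, dirs)
  behind <- neighbour_nodes(mesh, tips, ((dirs + 3L) %% 8L) + 1L)
  ok <- !is.na(ahead) & !is.na(behind)
  tips <- tips[ok]; dirs <- dirs[ok]
  ahead <- ahead[ok]; behind <- behind[ok]
  if (!length(tips)) return(point_load_set())
  f2 <- total_force / 2
  ux <- DIR_UX[dirs]; uy <- DIR_UY[dirs]
  point_load_set(node = c(ahead, behind),
                 fx = c(-f2 * ux, f2 * ux),
                 fy = c(-f2 * uy, f2 * uy))
}
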