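# Agent-based model of outer-vascular stromal cells (OVSCs): fibroblasts,
# pericytes and mesenchymal stromal cells surrounding the vasculature.
# OVSCs occupy single lattice points, carry one of four dipole orientations
# (horizontal 0, diagonal-right 45, vertical 90, diagonal-left 135 degrees)
# and load the matrix as contractile dipoles. Migration is a density-biased
# random walk during the first four days (growth-factor attraction towards
# the sparse gap), then a durotaxis rule: a trial position/orientation is
# adopted only if the deformation probed along the dipole axis is strictly
# lower than in the current configuration.

#' Default stromal-cell parameters
#'
#' Seeding fraction in marrow and periosteum (20%), migration rate
#' (30 um/day), proliferation (33%/day), apoptosis (0.03%/day), total
#' dipole magnitude (32 uN) and the day at which durotaxis replaces the
#' density-driven walk (day 4).
#'
#' @return Named list of parameters.
#' @export
ovsc_params <- function() {
  list(seed_frac = 0.20,
       migration_rate_um_day = 30,
       proliferation_day = 0.33,
       apoptosis_day = 0.0003,
       ovsc_force_total = 32e-6,
       durotaxis_onset_day = 4,
       durotaxis_patch_radius = 5L,
       relax_fraction = 1/3)
}

#' Seed the initial stromal cells
#'
#' Occupies each free marrow and periosteal lattice point with probability
#' 20%, with uniformly random initial dipole orientation. Gap granulation
#' is not seeded at time zero.
#'
#' @param state Simulation state environment.
#' @return Invisibly, the number of cells seeded.
#' @export
seed_ovscs <- function(state) {
  mesh <- state$mesh
  par <- state$config$ovsc
  eligible <- which(mesh$node_region %in% c(2L, 4L) & ov_free(state))
  sel <- eligible[stats::runif(length(eligible)) < par$seed_frac]
  n <- length(sel)
  state$ov_node <- c(state$ov_node, sel)
  state$ov_orient <- c(state$ov_orient, sample.int(4L, n, replace = TRUE))
  state$ov_alive <- c(state$ov_alive, rep(TRUE, n))
  state$ov_occ[sel] <- TRUE
  invisible(n)
}

# fraction of occupied points in the 8-neighbourhood + self (any agent)
local_occupancy <- function(state, nodes) {
  nbr <- neighbour_matrix(state$mesh, nodes)
  m <- cbind(nodes, nbr)
  occm <- matrix(state$ec_occ[m] | state$ov_occ[m], nrow = length(nodes))
  occm[is.na(m)] <- NA
  rowMeans(occm, na.rm = TRUE)
}

#' Density-biased random-walk migration (early phase)
#'
#' During the first four days, each cell attempting migration moves to one
#' of its free 8-neighbours sampled with probability proportional to
#' `1 - local occupancy` of the candidate point, producing a net drift
#' towards sparsely populated regions (the gap core). Cells with no free
#' neighbour stay (contact inhibition).
#'
#' @param state Simulation state environment.
#' @param cells Indices into the stromal arrays that attempt a move.
#' @return Invisibly, the number of moves.
#' @export
migrate_density <- function(state, cells) {
  mesh <- state$mesh
  moved <- 0L
  # crowding field frozen at the start of the migration event
  dens <- neigh_mean9(mesh, state$ec_occ | state$ov_occ)
  ord <- cells[sample.int(length(cells))]
  nbrs <- neighbour_matrix(mesh, state$ov_node[ord])
  ov_occ <- state$ov_occ          # local copies: in-place updates
  ov_node <- state$ov_node
  ec_occ <- state$ec_occ
  blocked <- state$blocked
  shared <- state$shared_occ
  for (k in seq_along(ord)) {
    i <- ord[k]
    nb <- nbrs[k, ]
    nb <- nb[!is.na(nb)]
    free <- nb[!ov_occ[nb] & !blocked[nb]]
    if (shared && length(free)) free <- free[!ec_occ[free]]
    if (!length(free)) next
    tgt <- if (length(free) == 1L) free else
      free[sample.int(length(free), 1, prob = pmax(1 - dens[free], 1e-9))]
    ov_occ[ov_node[i]] <- FALSE
    ov_occ[tgt] <- TRUE
    ov_node[i] <- tgt
    moved <- moved + 1L
  }
  state$ov_occ <- ov_occ
  state$ov_node <- ov_node
  invisible(moved)
}

# ---- durotaxis ----------------------------------------------------------

# Own-dipole approach along the dipole axis, solved on a local FE patch
# clamped at its outer boundary and cached by (orientation, material
# pattern, clipping). Returns the approach (positive = the two loaded
# nodes move toward each other) in mm.
own_dipole_approach <- function(state, node, orient) {
  own_patch_field(state, node, orient)$appr
}

# Cached patch solution of a cell's own dipole at (node, orient): local
# displacement field, patch geometry and pair approach. The cache key is
# the (orientation, clipping, material pattern) of the patch, so nodes in
# identical local surroundings share one dense solve.
own_patch_field <- function(state, node, orient) {
  mesh <- state$mesh
  R <- state$config$ovsc$durotaxis_patch_radius
  nx <- mesh$nx; ny <- mesh$ny
  ix <- (node - 1L) %% (nx + 1L)
  iy <- (node - 1L) %/% (nx + 1L)
  ex0 <- max(0L, ix - R); ey0 <- max(0L, iy - R)
  key0 <- state$duro_key[node]          # per-node pattern key, lazily built
  if (is.na(key0)) {
    ex1 <- min(nx - 1L, ix + R - 1L)
    ey1 <- min(ny - 1L, iy + R - 1L)
    pex <- ex1 - ex0 + 1L; pey <- ey1 - ey0 + 1L
    els <- rep(ex0:ex1, pey) + nx * rep(ey0:ey1, each = pex) + 1L
    key0 <- paste0(ix - ex0, ",", iy - ey0, "|", pex, "x", pey, "|",
                   paste(state$mat_code[els], collapse = ""))
    state$duro_key[node] <- key0
  }
  key <- paste0(orient, "|", key0)
  hit <- state$duro_cache[[key]]
  if (is.null(hit)) {
    ex1 <- min(nx - 1L, ix + R - 1L)
    ey1 <- min(ny - 1L, iy + R - 1L)
    pex <- ex1 - ex0 + 1L; pey <- ey1 - ey0 + 1L
    els <- rep(ex0:ex1, pey) + nx * rep(ey0:ey1, each = pex) + 1L
    hit <- patch_dipole_solve(state, state$mat_code[els], pex, pey,
                              ix - ex0, iy - ey0, orient)
    state$duro_cache[[key]] <- hit
  }
  hit$ex0 <- ex0; hit$ey0 <- ey0
  hit$orient <- orient
  hit
}

# Calibration of the patch-based self-field against the full solve: the
# clamped patch slightly underestimates a dipole's strain footprint
# (more for diagonal arms). Scaling the subtracted self tensor by the
# exact/patch ratio at a reference interior node removes the
# orientation-aligned residual that would otherwise act as a spurious
# self-memory in the sensed environment.
self_scale <- function(state, orient) {
  sc <- state$self_scale_cache
  if (!is.null(sc)) return(sc[orient])
  sc <- rep(1, 4)
  if (!is.null(state$op)) {
    mesh <- state$mesh
    ref <- round(mesh$cx / mesh$pitch) +
      (mesh$nx + 1L) * round(mesh$cy / mesh$pitch) + 1L
    for (o in 1:4) {
      P <- own_patch_field(state, ref, o)
      pt <- patch_node_tensor(P, mesh, ref)
      ex <- self_tensor_exact(state, ref, o)
      cc <- DIR_UX[o]; ss <- DIR_UY[o]
      ax_p <- pt[1] * cc^2 + pt[2] * ss^2 + pt[3] * cc * ss
      ax_e <- ex[1] * cc^2 + ex[2] * ss^2 + ex[3] * cc * ss
      if (is.finite(ax_e) && is.finite(ax_p) && abs(ax_p) > 0)
        sc[o] <- ax_e / ax_p
    }
  }
  state$self_scale_cache <- sc
  sc[orient]
}

# exact self strain tensor at a node (mean of incident elements) under
# the cell's own dipole, via the global factorization
self_tensor_exact <- function(state, node, orient) {
  mesh <- state$mesh
  d <- orient
  a <- neighbour_nodes(mesh, node, d)
  b <- neighbour_nodes(mesh, node, ((d + 3L) %% 8L) + 1L)
  if (is.na(a) || is.na(b)) return(c(NA, NA, NA))
  f2 <- state$config$ovsc$ovsc_force_total / 2
  if (f2 == 0) f2 <- 16e-6
  loads <- point_load_set(node = c(a, b),
                          fx = c(-f2, f2) * DIR_UX[d],
                          fy = c(-f2, f2) * DIR_UY[d])
  u <- solve_displacements(state$op, loads)
  fld <- principal_strains(u, mesh)
  inc <- mesh$inc[node, ]
  inc <- inc[!is.na(inc)]
  c(mean(fld$exx[inc]), mean(fld$eyy[inc]), mean(fld$gxy[inc]))
}

# approach of a node pair under a cached patch field; nodes beyond the
# patch carry zero displacement (the patch is clamped there anyway)
patch_pair_approach <- function(P, mesh, a, b, d) {
  if (!length(P$u)) return(0)
  nx1 <- mesh$nx + 1L
  getu <- function(g) {
    lx <- (g - 1L) %% nx1 - P$ex0
    ly <- (g - 1L) %/% nx1 - P$ey0
    if (lx < 0L || lx > P$pnx - 1L || ly < 0L || ly > P$pny - 1L)
      return(c(0, 0))
    i <- lx + P$pnx * ly + 1L
    c(P$u[2L * i - 1L], P$u[2L * i])
  }
  ua <- getu(a); ub <- getu(b)
  -((ua[1] - ub[1]) * DIR_UX[d] + (ua[2] - ub[2]) * DIR_UY[d])
}

# mean strain tensor of the elements incident to a global node under a
# cached patch field (zero outside the patch)
patch_node_tensor <- function(P, mesh, node) {
  if (!length(P$u)) return(c(0, 0, 0))
  nx1 <- mesh$nx + 1L
  lx <- (node - 1L) %% nx1 - P$ex0
  ly <- (node - 1L) %/% nx1 - P$ey0
  p <- mesh$pitch
  cx <- c(-1, 1, 1, -1) / (2 * p)
  cyd <- c(-1, -1, 1, 1) / (2 * p)
  acc <- c(0, 0, 0); nel <- 0L
  for (dx in c(-1L, 0L)) for (dy in c(-1L, 0L)) {
    ex <- lx + dx; ey <- ly + dy
    if (ex < 0L || ex > P$pnx - 2L || ey < 0L || ey > P$pny - 2L) next
    n1 <- ex + P$pnx * ey + 1L
    nd <- c(n1, n1 + 1L, n1 + P$pnx + 1L, n1 + P$pnx)
    ux <- P$u[2L * nd - 1L]; uy <- P$u[2L * nd]
    acc <- acc + c(sum(ux * cx), sum(uy * cyd), sum(ux * cyd) + sum(uy * cx))
    nel <- nel + 1L
  }
  if (nel == 0L) return(c(0, 0, 0))
  acc / nel
}

# Solve a dipole on a small dense patch (pex x pey elements), outer
# boundary clamped; the probing node sits at local node grid position
# (nlx, nly). Returns the local displacement field, patch geometry and
# the approach of the two loaded nodes (mm).
patch_dipole_solve <- function(state, mat, pex, pey, nlx, nly, orient) {
  pnx <- pex + 1L; pny <- pey + 1L
  # dipole poles must lie on the patch grid; a cell on the domain edge
  # has no valid pair along this orientation
  if (nlx + DIR_DX[orient] < 0L || nlx + DIR_DX[orient] > pnx - 1L ||
      nly + DIR_DY[orient] < 0L || nly + DIR_DY[orient] > pny - 1L ||
      nlx - DIR_DX[orient] < 0L || nlx - DIR_DX[orient] > pnx - 1L ||
      nly - DIR_DY[orient] < 0L || nly - DIR_DY[orient] > pny - 1L)
    return(list(u = numeric(0), pnx = pnx, pny = pny, appr = NA_real_,
                ten0 = c(0, 0, 0)))
  nnp <- pnx * pny
  Kp <- matrix(0, 2 * nnp, 2 * nnp)
  for (k in seq_along(mat)) {
    lex <- (k - 1L) %% pex; ley <- (k - 1L) %/% pex
    n1 <- lex + pnx * ley + 1L
    nd <- c(n1, n1 + 1L, n1 + pnx + 1L, n1 + pnx)
    dof <- as.integer(rbind(2L * nd - 1L, 2L * nd))
    Kp[dof, dof] <- Kp[dof, dof] + state$ke_by_mat[[mat[k]]]
  }
  bix <- rep(0:(pnx - 1L), pny); biy <- rep(0:(pny - 1L), each = pnx)
  bnd <- which(bix == 0L | bix == pnx - 1L | biy == 0L | biy == pny - 1L)
  fixed <- sort(c(2L * bnd - 1L, 2L * bnd))
  free <- setdiff(seq_len(2 * nnp), fixed)

  ctr <- nlx + pnx * nly + 1L
  d <- orient                               # orientation code = axis code
  a <- ctr + DIR_DX[d] + pnx * DIR_DY[d]
  b <- ctr - DIR_DX[d] - pnx * DIR_DY[d]
  f2 <- state$config$ovsc$ovsc_force_total / 2
  if (f2 == 0) f2 <- 16e-6            # probing force under traction knockout
  f <- numeric(2 * nnp)
  f[2L * a - 1L] <- -f2 * DIR_UX[d]; f[2L * a] <- -f2 * DIR_UY[d]
  f[2L * b - 1L] <- f2 * DIR_UX[d];  f[2L * b] <- f2 * DIR_UY[d]
  u <- numeric(2 * nnp)
  u[free] <- solve(Kp[free, free], f[free])
  appr <- -((u[2L * a - 1L] - u[2L * b - 1L]) * DIR_UX[d] +
              (u[2L * a] - u[2L * b]) * DIR_UY[d])
  P <- list(u = u, pnx = pnx, pny = pny, appr = appr)
  # strain tensor at the probing node (mean of its incident patch
  # elements), reused by every node sharing this patch pattern
  P$ten0 <- patch_centre_tensor(P, nlx, nly, state$mesh$pitch)
  P
}

# mean strain tensor of the elements incident to local node (nlx, nly)
# of a patch field
patch_centre_tensor <- function(P, nlx, nly, pitch) {
  if (!length(P$u)) return(c(0, 0, 0))
  cx <- c(-1, 1, 1, -1) / (2 * pitch)
  cyd <- c(-1, -1, 1, 1) / (2 * pitch)
  acc <- c(0, 0, 0); nel <- 0L
  for (dx in c(-1L, 0L)) for (dy in c(-1L, 0L)) {
    ex <- nlx + dx; ey <- nly + dy
    if (ex < 0L || ex > P$pnx - 2L || ey < 0L || ey > P$pny - 2L) next
    n1 <- ex + P$pnx * ey + 1L
    nd <- c(n1, n1 + 1L, n1 + P$pnx + 1L, n1 + P$pnx)
    ux <- P$u[2L * nd - 1L]; uy <- P$u[2L * nd]
    acc <- acc + c(sum(ux * cx), sum(uy * cyd), sum(ux * cyd) + sum(uy * cx))
    nel <- nel + 1L
  }
  if (nel == 0L) return(c(0, 0, 0))
  acc / nel
}

# Exact own-dipole approach via the cached global factorization (used as
# the reference in tests; O(one back-substitution) per call).
own_dipole_approach_exact <- function(state, node, orient) {
  mesh <- state$mesh
  d <- orient
  a <- neighbour_nodes(mesh, node, d)
  b <- neighbour_nodes(mesh, node, ((d + 3L) %% 8L) + 1L)
  if (is.na(a) || is.na(b)) return(NA_real_)
  f2 <- state$config$ovsc$ovsc_force_total / 2
  if (f2 == 0) f2 <- 16e-6            # probing force under traction knockout
  loads <- point_load_set(node = c(a, b),
                          fx = c(-f2, f2) * DIR_UX[d],
                          fy = c(-f2, f2) * DIR_UY[d])
  u <- solve_displacements(state$op, loads)
  -((u[a, 1] - u[b, 1]) * DIR_UX[d] + (u[a, 2] - u[b, 2]) * DIR_UY[d])
}

# Reference own-dipole approach per orientation: an uncut patch of
# homogeneous granulation tissue. Normalizing by it removes the lattice
# asymmetry between straight and diagonal dipole arms (diagonal arms are
# sqrt(2) longer and would otherwise always probe a smaller deformation).
own_reference <- function(state, orient) {
  key <- paste0("ref", orient)
  hit <- state$duro_cache[[key]]
  if (!is.null(hit)) return(hit)
  mesh <- state$mesh
  # granulation = softest material present
  soft <- which.min(vapply(state$ke_by_mat, function(k) k[1, 1], numeric(1)))
  R <- state$config$ovsc$durotaxis_patch_radius
  pex <- 2L * R
  ref <- patch_dipole_solve(state, rep(soft, pex * pex), pex, pex, R, R,
                            orient)$appr
  state$duro_cache[[key]] <- ref
  ref
}

#' Durotaxis deformation metric
#'
#' The unfavourability of a stromal cell configuration (lattice node plus
#' dipole orientation), on a strain scale. Two terms are summed:
#'
#' * compliance probing: the relative approach of the cell's two
#'   dipole-loaded nodes under its own traction, solved on a clamped
#'   local patch, cached by orientation and local material pattern and
#'   normalized by the homogeneous-granulation reference of the same
#'   orientation, so that all four lattice orientations are
#'   commensurable. Stiffer surroundings deform less, which drives the
#'   classical durotaxis drift and the alignment along stiff interfaces;
#' * strain response: the local environmental strain (tensor average of
#'   the incident elements, the probing cell's own contribution
#'   excluded) defines a preferred axis with the same thresholds as the
#'   endothelial guidance rule — along the absolute maximum principal
#'   strain direction while its magnitude is below 5%, perpendicular to
#'   it above 10%, linear ramp in between. The term penalizes angular
#'   distance from that axis in proportion to the strain magnitude, so
#'   cells re-orient away from strongly deformed directions and follow
#'   weak cell-induced strains.
#'
#' @param state Simulation state environment.
#' @param node Lattice node id.
#' @param orient Orientation code 1..4.
#' @param self Optional cached patch field of the probing cell's own
#'   dipole in its current configuration (internal use by
#'   [migrate_durotaxis()]): its contribution is subtracted from the
#'   measured field so that a cell does not sense its own traction as
#'   environmental deformation.
#' @param exact Use the exact global solve for the own-dipole term.
#' @return Non-negative unfavourability (strain scale), or `NA` at the
#'   domain edge.
#' @export
durotaxis_metric <- function(state, node, orient, self = NULL,
                             exact = state$config$durotaxis_exact) {
  mesh <- state$mesh
  d <- orient
  a <- neighbour_nodes(mesh, node, d)
  b <- neighbour_nodes(mesh, node, ((d + 3L) %% 8L) + 1L)
  if (is.na(a) || is.na(b)) return(NA_real_)
  # environmental strain tensor at the node (mean of incident elements)
  inc <- mesh$inc[node, ]
  inc <- inc[!is.na(inc)]
  fld <- state$field
  ten <- c(mean(fld$exx[inc]), mean(fld$eyy[inc]), mean(fld$gxy[inc]))
  if (!is.null(self))
    ten <- ten - patch_node_tensor(self, mesh, node) * self_scale(state, self$orient)
  pr <- principal_from_tensor(ten[1], ten[2], ten[3])
  ecp <- state$config$ec
  frac <- min(1, max(0, (abs(pr$ep) - ecp$strain_parallel_max) /
                       (ecp$strain_perpendicular_min - ecp$strain_parallel_max)))
  off <- 90 * frac
  misalign <- min(axis_distance(ORIENT_ANGLE[d], pr$theta + off),
                  axis_distance(ORIENT_ANGLE[d], pr$theta - off))
  own <- if (isTRUE(exact)) own_dipole_approach_exact(state, node, orient)
         else own_dipole_approach(state, node, orient)
  # compliance ratio relative to homogeneous granulation, on the strain
  # scale of the straight reference dipole
  s0 <- own_reference(state, 1L) / (2 * mesh$pitch)
  ratio <- own / own_reference(state, orient)
  ratio * s0 + abs(pr$ep) * misalign / 90
}

#' Durotaxis-biased migration and re-orientation (after day 4)
#'
#' Each attempting cell picks one uniformly random free 8-neighbour and a
#' random trial orientation, probes the substrate deformation in the trial
#' configuration and adopts it only if the deformation is strictly lower
#' than in its current configuration; otherwise it stays. No free
#' neighbour means contact inhibition (no move, no re-orientation). The
#' strict-descent acceptance drives cells towards stiffer, less deformed
#' surroundings.
#'
#' @param state Simulation state environment.
#' @param cells Indices into the stromal arrays attempting migration.
#' @return Invisibly, the number of accepted moves.
#' @export
migrate_durotaxis <- function(state, cells) {
  mesh <- state$mesh
  accepted <- 0L
  exact <- isTRUE(state$config$durotaxis_exact)
  if (exact) return(migrate_durotaxis_exact(state, cells))
  ord <- cells[sample.int(length(cells))]
  node <- state$ov_node[ord]
  orient <- state$ov_orient[ord]
  n <- length(ord)
  # trial positions drawn against the occupancy frozen at event start
  nbrs <- neighbour_matrix(mesh, node)
  freem <- !is.na(nbrs)
  freem[freem] <- !state$ov_occ[nbrs[freem]] & !state$blocked[nbrs[freem]]
  if (state$shared_occ) freem[freem] <- !state$ec_occ[nbrs[freem]]
  nfree <- rowSums(freem)
  has <- nfree > 0L
  if (!any(has)) return(invisible(0L))
  r <- 1L + floor(stats::runif(n) * nfree)
  cum <- freem * 1L
  for (j in 2:8) cum[, j] <- cum[, j - 1L] + freem[, j]
  selcol <- max.col(cum == r & freem, ties.method = "first")
  trial_node <- nbrs[cbind(seq_len(n), selcol)]
  trial_node[!has] <- NA_integer_
  trial_orient <- sample.int(4L, n, replace = TRUE)

  # per-cell patch fields of the current configuration (cached solves)
  selfs <- vector("list", n)
  for (k in which(has)) selfs[[k]] <- own_patch_field(state, node[k], orient[k])
  self_cur <- matrix(0, n, 3)
  self_new <- matrix(0, n, 3)
  for (k in which(has)) {
    sc <- self_scale(state, selfs[[k]]$orient)
    self_cur[k, ] <- selfs[[k]]$ten0 * sc
    self_new[k, ] <- patch_node_tensor(selfs[[k]], mesh, trial_node[k]) * sc
  }
  cur <- batch_duro_metric(state, node, orient, self_cur)
  new <- batch_duro_metric(state, trial_node, trial_orient, self_new)
  ok <- which(has & !is.na(cur) & !is.na(new) & new < cur)

  ov_occ <- state$ov_occ
  ov_node <- state$ov_node
  ov_orient <- state$ov_orient
  for (k in ok) {
    tgt <- trial_node[k]
    if (ov_occ[tgt]) next               # taken earlier in this event
    ov_occ[ov_node[ord[k]]] <- FALSE
    ov_occ[tgt] <- TRUE
    ov_node[ord[k]] <- tgt
    ov_orient[ord[k]] <- trial_orient[k]
    accepted <- accepted + 1L
  }
  state$ov_occ <- ov_occ
  state$ov_node <- ov_node
  state$ov_orient <- ov_orient
  invisible(accepted)
}

# vectorized durotaxis metric over (node, orient) configurations with
# per-cell self tensors already removed
batch_duro_metric <- function(state, nodes, orients, self_ten) {
  mesh <- state$mesh
  n <- length(nodes)
  out <- rep(NA_real_, n)
  ok <- !is.na(nodes)
  a <- neighbour_nodes(mesh, nodes, orients)
  b <- neighbour_nodes(mesh, nodes, ((orients + 3L) %% 8L) + 1L)
  ok <- ok & !is.na(a) & !is.na(b)
  if (!any(ok)) return(out)
  idx <- which(ok)
  inc <- mesh$inc[nodes[idx], , drop = FALSE]
  fld <- state$field
  pick <- function(v) matrix(v[inc], nrow = nrow(inc))
  ten <- cbind(rowMeans(pick(fld$exx), na.rm = TRUE),
               rowMeans(pick(fld$eyy), na.rm = TRUE),
               rowMeans(pick(fld$gxy), na.rm = TRUE)) - self_ten[idx, , drop = FALSE]
  pr <- principal_from_tensor(ten[, 1], ten[, 2], ten[, 3])
  ecp <- state$config$ec
  frac <- pmin(1, pmax(0, (abs(pr$ep) - ecp$strain_parallel_max) /
                         (ecp$strain_perpendicular_min - ecp$strain_parallel_max)))
  off <- 90 * frac
  oa <- ORIENT_ANGLE[orients[idx]]
  mis <- pmin(axis_distance(oa, pr$theta + off),
              axis_distance(oa, pr$theta - off))
  # own-dipole compliance ratios, lazily cached per (node, orientation)
  ratio <- ratio_cached(state, nodes[idx], orients[idx])
  s0 <- own_reference(state, 1L) / (2 * mesh$pitch)
  out[idx] <- ratio * s0 + abs(pr$ep) * mis / 90
  out
}

#' Per-iteration orientation re-evaluation
#'
#' After durotaxis onset, every cell re-evaluates its dipole orientation
#' once per iteration: a random trial orientation at the current position
#' is adopted if the durotaxis metric is strictly lower. Re-orientation
#' in place is not migration, so it is not limited by the migration rate;
#' position changes are handled by [migrate_durotaxis()] at the
#' rate-limited cadence.
#'
#' @param state Simulation state environment.
#' @param cells Indices into the stromal arrays.
#' @return Invisibly, the number of accepted re-orientations.
#' @export
relax_orientations <- function(state, cells) {
  mesh <- state$mesh
  # asynchronous-style update: only a random subset re-evaluates per
  # iteration, avoiding synchronous flip-flop artifacts in strongly
  # coupled neighbourhoods
  fr <- state$config$ovsc$relax_fraction
  if (fr < 1) {
    cells <- cells[stats::runif(length(cells)) < fr]
    if (!length(cells)) return(invisible(0L))
  }
  node <- state$ov_node[cells]
  cur <- state$ov_orient[cells]
  trial <- sample.int(4L, length(cells), replace = TRUE)
  differs <- trial != cur
  if (!any(differs)) return(invisible(0L))
  idx <- which(differs)
  node <- node[idx]; cur <- cur[idx]; trial <- trial[idx]
  # self strain tensors of the current configuration, cached per
  # (node pattern, orientation)
  st <- self_tensor_cached(state, node, cur)
  inc <- mesh$inc[node, , drop = FALSE]
  fld <- state$field
  pick <- function(v) matrix(v[inc], nrow = nrow(inc))
  ten <- cbind(rowMeans(pick(fld$exx), na.rm = TRUE),
               rowMeans(pick(fld$eyy), na.rm = TRUE),
               rowMeans(pick(fld$gxy), na.rm = TRUE)) - st
  pr <- principal_from_tensor(ten[, 1], ten[, 2], ten[, 3])
  ecp <- state$config$ec
  frac <- pmin(1, pmax(0, (abs(pr$ep) - ecp$strain_parallel_max) /
                         (ecp$strain_perpendicular_min - ecp$strain_parallel_max)))
  off <- 90 * frac
  mis_of <- function(o) pmin(axis_distance(ORIENT_ANGLE[o], pr$theta + off),
                             axis_distance(ORIENT_ANGLE[o], pr$theta - off))
  ratio_cur <- ratio_cached(state, node, cur)
  ratio_new <- ratio_cached(state, node, trial)
  s0 <- own_reference(state, 1L) / (2 * mesh$pitch)
  m_cur <- ratio_cur * s0 + abs(pr$ep) * mis_of(cur) / 90
  m_new <- ratio_new * s0 + abs(pr$ep) * mis_of(trial) / 90
  acc <- which(!is.na(m_new) & !is.na(m_cur) & m_new < m_cur)
  if (length(acc)) {
    orient <- state$ov_orient
    orient[cells[idx[acc]]] <- trial[acc]
    state$ov_orient <- orient
  }
  invisible(length(acc))
}

# own-dipole compliance ratios with lazy (node, orientation) cache
ratio_cached <- function(state, nodes, orients) {
  key <- cbind(nodes, orients)
  ratio <- state$duro_ratio[key]
  miss <- which(is.na(ratio))
  for (k in miss) {
    own <- own_patch_field(state, nodes[k], orients[k])$appr
    # an edge configuration has no valid dipole pair: never favourable
    ratio[k] <- if (is.na(own)) Inf else own / own_reference(state, orients[k])
  }
  if (length(miss)) state$duro_ratio[key[miss, , drop = FALSE]] <- ratio[miss]
  ratio
}

# self strain tensor (mean over the node's incident elements) of a cell's
# own dipole, cached per (node, orientation)
self_tensor_cached <- function(state, nodes, orients) {
  if (is.null(state$self_ten)) state$self_ten <- array(NA_real_, c(state$mesh$nn, 4, 3))
  st <- cbind(state$self_ten[cbind(nodes, orients, 1L)],
              state$self_ten[cbind(nodes, orients, 2L)],
              state$self_ten[cbind(nodes, orients, 3L)])
  miss <- which(is.na(st[, 1]))
  if (length(miss)) {
    A <- state$self_ten
    for (k in miss) {
      P <- own_patch_field(state, nodes[k], orients[k])
      st[k, ] <- P$ten0 * self_scale(state, orients[k])
      A[nodes[k], orients[k], ] <- st[k, ]
    }
    state$self_ten <- A
  }
  st
}

# reference implementation: sequential, full-solve own-dipole probing
migrate_durotaxis_exact <- function(state, cells) {
  mesh <- state$mesh
  accepted <- 0L
  for (i in cells[sample.int(length(cells))]) {
    node <- state$ov_node[i]
    nb <- neighbour_matrix(mesh, node)
    nb <- nb[!is.na(nb)]
    free <- nb[!state$ov_occ[nb] & !state$blocked[nb]]
    if (state$shared_occ && length(free)) free <- free[!state$ec_occ[free]]
    if (!length(free)) next
    trial_node <- if (length(free) == 1L) free else free[sample.int(length(free), 1)]
    trial_orient <- sample.int(4L, 1)
    cur <- durotaxis_metric(state, node, state$ov_orient[i], exact = TRUE)
    new <- durotaxis_metric(state, trial_node, trial_orient, exact = TRUE)
    if (is.na(new) || is.na(cur) || new >= cur) next
    state$ov_occ[node] <- FALSE
    state$ov_occ[trial_node] <- TRUE
    state$ov_node[i] <- trial_node
    state$ov_orient[i] <- trial_orient
    accepted <- accepted + 1L
  }
  invisible(accepted)
}

#' Stromal proliferation and apoptosis
#'
#' Per iteration, each cell divides with probability
#' `proliferation_day * dt/day` into a uniformly random free 8-neighbour
#' (skipped when fully surrounded: contact inhibition); the daughter
#' inherits the parent's orientation. Each cell dies with probability
#' `apoptosis_day * dt/day`.
#'
#' @param state Simulation state environment.
#' @return Invisibly, `c(births, deaths)`.
#' @export
proliferate_and_die <- function(state) {
  par <- state$config$ovsc
  frac_day <- state$config$iteration_minutes / (24 * 60)
  alive <- which(state$ov_alive)
  if (!length(alive)) return(invisible(c(0L, 0L)))
  p_div <- par$proliferation_day * frac_day
  p_die <- par$apoptosis_day * frac_day
  births <- 0L
  dividers <- alive[stats::runif(length(alive)) < p_div]
  if (length(dividers)) {
    dividers <- dividers[sample.int(length(dividers))]
    nbrs <- neighbour_matrix(state$mesh, state$ov_node[dividers])
    ov_occ <- state$ov_occ
    ec_occ <- state$ec_occ
    blocked <- state$blocked
    shared <- state$shared_occ
    new_node <- integer(length(dividers)); new_par <- integer(length(dividers))
    for (k in seq_along(dividers)) {
      nb <- nbrs[k, ]
      nb <- nb[!is.na(nb)]
      free <- nb[!ov_occ[nb] & !blocked[nb]]
      if (shared && length(free)) free <- free[!ec_occ[free]]
      if (!length(free)) next
      tgt <- if (length(free) == 1L) free else free[sample.int(length(free), 1)]
      ov_occ[tgt] <- TRUE
      births <- births + 1L
      new_node[births] <- tgt
      new_par[births] <- dividers[k]
    }
    if (births > 0L) {
      new_node <- new_node[seq_len(births)]
      new_par <- new_par[seq_len(births)]
      state$ov_node <- c(state$ov_node, new_node)
      state$ov_orient <- c(state$ov_orient, state$ov_orient[new_par])
      state$ov_alive <- c(state$ov_alive, rep(TRUE, births))
      state$ov_occ <- ov_occ
    }
  }
  deaths_idx <- alive[stats::runif(length(alive)) < p_die]
  if (length(deaths_idx)) {
    state$ov_alive[deaths_idx] <- FALSE
    ov_occ <- state$ov_occ
    ov_occ[state$ov_node[deaths_idx]] <- FALSE
    state$ov_occ <- ov_occ
  }
  invisible(c(births, length(deaths_idx)))
}

#' Traction loads of the stromal cells
#'
#' Each cell is a contractile dipole along its orientation axis: two
#' forces of half the total magnitude on the two adjacent lattice nodes,
#' pointing toward the cell. Under the traction-force knockout scenario
#' the returned set is empty (forces are 0 N). Cells at the domain edge
#' with a missing adjacent node are skipped.
#'
#' @param nodes Stromal cell node ids.
#' @param orients Orientation codes 1..4.
#' @param mesh `fe_mesh`.
#' @param total_force Total dipole magnitude in N (default 32e-6). Zero
#'   yields an empty load set.
#' @return A `point_load_set`.
#' @export
ovsc_traction_loads <- function(nodes, orients, mesh, total_force = 32e-6) {
  if (total_force == 0 || !length(nodes)) return(point_load_set())
  d <- orients
  ahead <- neighbour_nodes(mesh, nodes, d)
  behind <- neighbour_nodes(mesh, nodes, ((d + 3L) %% 8L) + 1L)
  ok <- !is.na(ahead) & !is.na(behind)
  d <- d[ok]; ahead <- ahead[ok]; behind <- behind[ok]
  if (!length(d)) return(point_load_set())
  f2 <- total_force / 2
  point_load_set(node = c(ahead, behind),
                 fx = c(-f2 * DIR_UX[d], f2 * DIR_UX[d]),
                 fy = c(-f2 * DIR_UY[d], f2 * DIR_UY[d]))
}
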