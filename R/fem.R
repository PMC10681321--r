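# Plane-strain linear-elastic solver on the regular quad mesh.
#
# DOF numbering: node i owns DOFs (2i-1, 2i) = (ux, uy). All elements are
# identical squares, so one 8x8 stiffness matrix per distinct material
# covers the whole mesh and assembly is a sparse scatter.

#' Element stiffness matrix of a square bilinear plane-strain quad
#'
#' 2x2 Gauss quadrature, counter-clockwise node order, unit out-of-plane
#' thickness. Units: E in MPa (N/mm^2), side in mm, forces in N.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio (< 0.5).
#' @param side Element edge length (mm).
#' @return Symmetric 8x8 matrix.
#' @export
element_stiffness <- function(E, nu, side) {
  if (nu >= 0.5) stop("plane strain is singular for nu >= 0.5")
  D <- E / ((1 + nu) * (1 - 2 * nu)) *
    matrix(c(1 - nu, nu, 0,
             nu, 1 - nu, 0,
             0, 0, (1 - 2 * nu) / 2), 3, 3, byrow = TRUE)
  g <- 1 / sqrt(3)
  pts <- expand.grid(xi = c(-g, g), eta = c(-g, g))
  Ke <- matrix(0, 8, 8)
  J <- side / 2                       # d(x)/d(xi), square element
  for (k in seq_len(nrow(pts))) {
    xi <- pts$xi[k]; eta <- pts$eta[k]
    # shape function derivatives wrt xi/eta, ccw nodes
    dNdxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    dNdx <- dNdxi / J
    dNdy <- dNdeta / J
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx
    B[2, seq(2, 8, 2)] <- dNdy
    B[3, seq(1, 8, 2)] <- dNdy
    B[3, seq(2, 8, 2)] <- dNdx
    Ke <- Ke + t(B) %*% D %*% B * J * J
  }
  (Ke + t(Ke)) / 2
}

#' Assemble the global plane-strain stiffness matrix
#'
#' @param mesh An `fe_mesh` with materials assigned
#'   (see [assign_materials()]).
#' @return Sparse symmetric `dgCMatrix` of size `2*nn`.
#' @export
assemble_stiffness <- function(mesh) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (is.null(mesh$E)) stop("mesh has no materials; call assign_materials()")
  mat_key <- paste(mesh$E, mesh$nu)
  keys <- unique(mat_key)
  kes <- lapply(keys, function(k) {
    i <- match(k, mat_key)
    element_stiffness(mesh$E[i], mesh$nu[i], mesh$pitch)
  })
  names(kes) <- keys

  # element DOF map: ne x 8
  ed <- matrix(0L, mesh$ne, 8)
  ed[, seq(1, 8, 2)] <- 2L * mesh$enodes - 1L
  ed[, seq(2, 8, 2)] <- 2L * mesh$enodes

  ii <- jj <- vector("list", length(keys))
  xx <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    els <- which(mat_key == keys[k])
    edk <- ed[els, , drop = FALSE]
    ii[[k]] <- as.integer(edk[, rep(1:8, each = 8)])
    jj[[k]] <- as.integer(edk[, rep(1:8, times = 8)])
    xx[[k]] <- rep(as.numeric(kes[[k]]), each = length(els))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2 * mesh$nn, 2 * mesh$nn))
}

#' Boundary conditions for a fixation preset
#'
#' Builds the prescribed-displacement set on the cortical bone fragments.
#' `unloaded` fixes every cortical node in all degrees of freedom. The
#' `rigid` and `semirigid` surrogates compress the gap axially: the upper
#' fragment moves down and the lower fragment up by `amplitude/2` each,
#' with a linear medio-lateral asymmetry (`asymmetry` medial:lateral,
#' medial = low x) mimicking the bending component of fixator loading;
#' cortical `ux` is held at zero. Amplitudes are usually set by
#' [calibrate_amplitude()] so that the mean compressive gap strain matches
#' the target interfragmentary strain of the preset.
#'
#' @param mesh `fe_mesh`.
#' @param preset `"rigid"`, `"semirigid"` or `"unloaded"`.
#' @param amplitude Total axial closing displacement of the gap (mm).
#' @param asymmetry Medial/lateral amplitude ratio (default 1.2).
#' @return Object of class `bc_set`: integer `dof` and numeric `value`.
#' @export
boundary_conditions <- function(mesh, preset = c("rigid", "semirigid", "unloaded"),
                                amplitude = 0, asymmetry = 1.2) {
  preset <- match.arg(preset)
  cort <- which(mesh$node_region == 1L)
  if (!length(cort)) stop("mesh has no cortical nodes to constrain")
  xy <- node_coords(mesh, cort)
  dof <- c(2L * cort - 1L, 2L * cort)
  val <- numeric(length(dof))
  if (preset != "unloaded") {
    w <- asymmetry - (asymmetry - 1) * xy[, 1] / mesh$domain$domain_width
    upper <- xy[, 2] > mesh$cy
    uy <- ifelse(upper, -1, 1) * amplitude / 2 * w
    val[seq_along(cort) + length(cort)] <- uy
  }
  structure(list(preset = preset, amplitude = amplitude,
                 asymmetry = asymmetry, dof = dof, value = val),
            class = "bc_set")
}

#' Factorize the constrained stiffness operator
#'
#' Eliminates prescribed DOFs and caches a sparse Cholesky factorization.
#' Geometry and materials are constant throughout a simulation, so the
#' factor is reused across iterations: every time step costs one
#' back-substitution.
#'
#' @param mesh `fe_mesh` with materials.
#' @param bcs A `bc_set` from [boundary_conditions()].
#' @return Object of class `fe_operator`.
#' @export
fe_factorize <- function(mesh, bcs) {
  K <- assemble_stiffness(mesh)
  ndof <- 2L * mesh$nn
  fixed <- bcs$dof
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- K[free, free, drop = FALSE]
  sing <- function(msg)
    stop("constrained system is singular: a rigid-body mode (translation/",
         "rotation) is unconstrained; check the boundary conditions [",
         msg, "]", call. = FALSE)
  chol <- withCallingHandlers(
    tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
             error = function(e) sing(conditionMessage(e))),
    warning = function(w) {
      if (grepl("not positive definite", conditionMessage(w)))
        sing(conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  # constant part of the free-RHS from prescribed displacements
  rhs0 <- as.numeric(-K[free, fixed, drop = FALSE] %*% bcs$value)
  structure(list(mesh = mesh, bcs = bcs, K = K, chol = chol,
                 free = free, fixed = fixed, rhs0 = rhs0, ndof = ndof),
            class = "fe_operator")
}

#' Solve for displacements under point loads
#'
#' @param op `fe_operator` from [fe_factorize()].
#' @param loads Either `NULL` (no cell loads), a full length-`2*nn` force
#'   vector (N), or a `point_load_set` (see [ec_traction_loads()]).
#' @return `nn x 2` matrix of nodal displacements (mm); prescribed DOFs
#'   hold their prescribed values exactly.
#' @export
solve_displacements <- function(op, loads = NULL) {
  f <- numeric(op$ndof)
  if (!is.null(loads)) {
    if (inherits(loads, "point_load_set")) loads <- as_force_vector(loads, op$ndof)
    if (length(loads) != op$ndof) stop("load vector has wrong length")
    f <- loads
  }
  rhs <- f[op$free] + op$rhs0
  uf <- as.numeric(Matrix::solve(op$chol, rhs, system = "A"))
  u <- numeric(op$ndof)
  u[op$free] <- uf
  u[op$fixed] <- op$bcs$value
  matrix(u, ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("ux", "uy")))
}

#' Reaction forces at prescribed DOFs
#'
#' For equilibrium checks: the sum of reactions balances the sum of
#' applied point loads.
#' @param op `fe_operator`.
#' @param u Displacement matrix from [solve_displacements()].
#' @param loads Optional applied load vector (length `2*nn`).
#' @return Numeric vector of reactions at `op$fixed`.
#' @export
reaction_forces <- function(op, u, loads = NULL) {
  uv <- as.numeric(t(u))
  r <- as.numeric(op$K %*% uv)
  if (!is.null(loads)) {
    if (inherits(loads, "point_load_set")) loads <- as_force_vector(loads, op$ndof)
    r <- r - loads
  }
  r[op$fixed]
}

# Principal decomposition of 2D small-strain tensors (vectorized).
# Returns the principal strain of largest magnitude with its sign
# ("absolute maximum principal strain") and its direction in [0, 180).
# Tie-break when both principal magnitudes are equal: take the compressive
# one; a zero tensor reports 0 strain at 90 degrees (bone axis).
principal_from_tensor <- function(exx, eyy, gxy) {
  avg <- (exx + eyy) / 2
  dif <- (exx - eyy) / 2
  R <- sqrt(dif^2 + (gxy / 2)^2)
  e1 <- avg + R
  e2 <- avg - R
  th1 <- (atan2(gxy, exx - eyy) * 90 / pi) %% 180   # direction of e1
  scale <- pmax(abs(e1), abs(e2))
  tie <- abs(abs(e1) - abs(e2)) <= 1e-12 * pmax(scale, 1e-300)
  pick1 <- (abs(e1) > abs(e2) & !tie) | (tie & e1 < 0)
  ep <- ifelse(pick1, e1, e2)
  th <- ifelse(pick1, th1, (th1 + 90) %% 180)
  zero <- scale == 0
  ep[zero] <- 0
  th[zero] <- 90
  list(ep = ep, theta = th)
}

#' Element strain field from a displacement solution
#'
#' Small-strain tensor at each element centroid, its absolute maximum
#' principal strain (sign retained, compression negative) and direction in
#' degrees within [0, 180), where 90 degrees is the bone long axis.
#'
#' @param u `nn x 2` displacement matrix.
#' @param mesh `fe_mesh`.
#' @return Object of class `strain_field`: list with vectors `exx`, `eyy`,
#'   `gxy`, `ep` (absolute maximum principal strain) and `theta`
#'   (degrees).
#' @export
principal_strains <- function(u, mesh) {
  p <- mesh$pitch
  en <- mesh$enodes
  # centroid shape-function derivatives for the square bilinear quad
  cx <- c(-1, 1, 1, -1) / (2 * p)
  cyd <- c(-1, -1, 1, 1) / (2 * p)
  ux <- matrix(u[en, 1], ncol = 4)
  uy <- matrix(u[en, 2], ncol = 4)
  exx <- ux %*% cx
  eyy <- uy %*% cyd
  gxy <- ux %*% cyd + uy %*% cx
  pr <- principal_from_tensor(as.numeric(exx), as.numeric(eyy), as.numeric(gxy))
  structure(list(exx = as.numeric(exx), eyy = as.numeric(eyy),
                 gxy = as.numeric(gxy), ep = pr$ep, theta = pr$theta),
            class = "strain_field")
}

#' Sample the strain tensor at lattice nodes
#'
#' Element-centroid strain tensors of the (up to four) incident elements
#' are averaged as tensors, excluding elements outside the callus, and the
#' averaged tensor is decomposed. Nodes surrounded only by outside-callus
#' elements carry `NA` ("no strain signal").
#'
#' @param field `strain_field` from [principal_strains()].
#' @param mesh `fe_mesh`.
#' @param nodes Node ids to sample (default all).
#' @return List with `ep` and `theta` (degrees) per requested node.
#' @export
sample_strain_at_nodes <- function(field, mesh, nodes = seq_len(mesh$nn)) {
  if (!length(nodes)) return(list(ep = numeric(0), theta = numeric(0)))
  inc_all <- if (!is.null(mesh$inc)) mesh$inc else incident_elements(mesh)
  inc <- inc_all[nodes, , drop = FALSE]
  excl <- matrix(mesh$region[inc] == 5L, nrow = nrow(inc))
  inc[excl | is.na(inc)] <- NA_integer_
  pick <- function(v) matrix(v[inc], nrow = nrow(inc))
  n_ok <- rowSums(!is.na(inc))
  mexx <- rowMeans(pick(field$exx), na.rm = TRUE)
  meyy <- rowMeans(pick(field$eyy), na.rm = TRUE)
  mgxy <- rowMeans(pick(field$gxy), na.rm = TRUE)
  pr <- principal_from_tensor(mexx, meyy, mgxy)
  pr$ep[n_ok == 0] <- NA_real_
  pr$theta[n_ok == 0] <- NA_real_
  pr
}

#' Calibrate the axial boundary-condition amplitude
#'
#' Sets the closing displacement of a loading preset so that the mean
#' compressive absolute-maximum principal strain over the endosteal gap
#' ROI equals a target interfragmentary strain (rigid about 11%, semirigid
#' about 45%). The problem is linear, so one unit-amplitude solve suffices
#' and the calibration is exact.
#'
#' @param mesh `fe_mesh` with materials.
#' @param rois ROI set from [define_rois()]; the `ROI1_gap` box is used.
#' @param preset `"rigid"` or `"semirigid"`.
#' @param target_gap_strain Target mean compressive strain magnitude
#'   (e.g. 0.11).
#' @param asymmetry Medio-lateral asymmetry passed through.
#' @return Amplitude in mm.
#' @export
calibrate_amplitude <- function(mesh, rois, preset, target_gap_strain,
                                asymmetry = 1.2) {
  stopifnot(preset %in% c("rigid", "semirigid"))
  bcs <- boundary_conditions(mesh, preset, amplitude = 1, asymmetry = asymmetry)
  op <- fe_factorize(mesh, bcs)
  u <- solve_displacements(op)
  fld <- principal_strains(u, mesh)
  roi <- roi_by_id(rois, "ROI1_gap")
  sel <- elements_in_roi(mesh, roi) & mesh$region != 1L
  m <- mean(abs(fld$ep[sel]))
  if (!is.finite(m) || m <= 0) stop("gap ROI strain response is zero; cannot calibrate")
  target_gap_strain / m
}
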