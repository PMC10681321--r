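test_that("element stiffness has rigid-body null space and is symmetric", {
  Ke <- element_stiffness(200, 0.3, 0.01)
  expect_equal(Ke, t(Ke))
  # unit x- and y-translations produce no force
  tx <- rep(c(1, 0), 4)
  ty <- rep(c(0, 1), 4)
  expect_equal(max(abs(Ke %*% tx)), 0, tolerance = 1e-9)
  expect_equal(max(abs(Ke %*% ty)), 0, tolerance = 1e-9)
  expect_error(element_stiffness(1, 0.5, 0.01), "singular")
})

test_that("element stiffness matches a brute-force integration oracle", {
  skip_if_not_installed("pracma")
  E <- 1; nu <- 0; side <- 1
  D <- E / ((1 + nu) * (1 - 2 * nu)) *
    matrix(c(1 - nu, nu, 0, nu, 1 - nu, 0, 0, 0, (1 - 2 * nu) / 2), 3, 3,
           byrow = TRUE)
  Bfun <- function(xi, eta) {
    dNdxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    J <- side / 2
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdxi / J
    B[2, seq(2, 8, 2)] <- dNdeta / J
    B[3, seq(1, 8, 2)] <- dNdeta / J
    B[3, seq(2, 8, 2)] <- dNdxi / J
    B
  }
  # brute-force midpoint quadrature on a fine grid
  n <- 200
  h <- 2 / n
  pts <- -1 + h * (seq_len(n) - 0.5)
  Ke_oracle <- matrix(0, 8, 8)
  for (xi in pts) for (eta in pts) {
    B <- Bfun(xi, eta)
    Ke_oracle <- Ke_oracle + t(B) %*% D %*% B * (side / 2)^2 * h * h
  }
  expect_equal(element_stiffness(E, nu, side), Ke_oracle, tolerance = 1e-4)
})

test_that("uniaxial patch test is exact and equilibrium holds", {
  m <- square_mesh(8, 0.1)
  xy <- node_coords(m)
  H <- 0.8
  top <- which(abs(xy[, 2] - H) < 1e-9)
  bot <- which(xy[, 2] < 1e-9)
  delta <- 0.04
  bcs <- structure(list(preset = "rigid", amplitude = 0, asymmetry = 1,
                        dof = c(2L * top, 2L * bot, 2L * bot[1] - 1L),
                        value = c(rep(-delta, length(top)),
                                  rep(0, length(bot) + 1))),
                   class = "bc_set")
  op <- fe_factorize(m, bcs)
  u <- solve_displacements(op)
  f <- principal_strains(u, m)
  expect_equal(f$eyy, rep(-delta / H, m$ne), tolerance = 1e-12)
  expect_equal(f$ep, rep(-delta / H, m$ne), tolerance = 1e-12)
  expect_equal(f$theta, rep(90, m$ne), tolerance = 1e-9)
  # prescribed DOFs returned exactly
  expect_equal(u[top, 2], rep(-delta, length(top)))
  # global equilibrium: reactions balance (no applied loads)
  expect_lt(abs(sum(reaction_forces(op, u))), 1e-10)
})

test_that("zero loads and zero prescribed displacements give zero solution", {
  m <- square_mesh(6, 0.1)
  xy <- node_coords(m)
  bot <- which(xy[, 2] < 1e-9)
  bcs <- structure(list(preset = "unloaded", amplitude = 0, asymmetry = 1,
                        dof = c(2L * bot - 1L, 2L * bot),
                        value = numeric(2 * length(bot))),
                   class = "bc_set")
  op <- fe_factorize(m, bcs)
  expect_equal(max(abs(solve_displacements(op))), 0)
})

test_that("an unconstrained system reports the free rigid-body mode", {
  m <- square_mesh(4, 0.1)
  bcs <- structure(list(preset = "unloaded", amplitude = 0, asymmetry = 1,
                        dof = integer(0), value = numeric(0)),
                   class = "bc_set")
  expect_error(fe_factorize(m, bcs), "rigid-body")
})

test_that("dipole displacement decays with distance from the source", {
  m <- square_mesh(40, 0.01)
  state <- sim_init(make_fixture("uniform-strain", size = 40), seed = 1)
  mesh <- state$mesh
  ctr <- round(mesh$nx / 2) + (mesh$nx + 1L) * round(mesh$ny / 2) + 1L
  loads <- ovsc_traction_loads(ctr, 3L, mesh)
  op <- fe_factorize(mesh, sproutmech:::clamp_boundary(mesh))
  u <- solve_displacements(op, loads)
  mag <- sqrt(u[, 1]^2 + u[, 2]^2)
  xy <- node_coords(mesh)
  d <- sqrt((xy[, 1] - xy[ctr, 1])^2 + (xy[, 2] - xy[ctr, 2])^2)
  rings <- vapply(c(0.03, 0.06, 0.09, 0.12), function(r)
    mean(mag[abs(d - r) < mesh$pitch]), numeric(1))
  expect_true(all(diff(rings) < 0))
})

test_that("principal decomposition matches the eigen oracle", {
  # uniaxial compression and pure shear closed forms
  pr <- sproutmech:::principal_from_tensor(0, -0.05, 0)
  expect_equal(pr$ep, -0.05)
  expect_equal(pr$theta, 90)
  pr <- sproutmech:::principal_from_tensor(0, 0, 0.02)
  expect_equal(abs(pr$ep), 0.01)
  expect_true(min(abs(pr$theta - c(45, 135))) < 1e-9)
  # zero tensor tie-break points along the bone axis
  pr <- sproutmech:::principal_from_tensor(0, 0, 0)
  expect_equal(pr$ep, 0)
  expect_equal(pr$theta, 90)
  # random tensors against an independent eigen() oracle
  set.seed(42)
  for (i in 1:50) {
    t3 <- stats::rnorm(3, sd = 0.1)
    pr <- sproutmech:::principal_from_tensor(t3[1], t3[2], t3[3])
    or <- eigen_oracle(t3[1], t3[2], t3[3])
    expect_equal(pr$ep, or$ep, tolerance = 1e-12)
    expect_lt(min(abs(pr$theta - or$theta), 180 - abs(pr$theta - or$theta)),
              1e-9)
  }
})

test_that("node sampling averages tensors, not angles", {
  m <- square_mesh(6, 0.1)
  set.seed(7)
  u <- matrix(stats::rnorm(2 * m$nn, sd = 1e-3), ncol = 2)
  fld <- principal_strains(u, m)
  nodes <- c(15L, 22L, 30L)
  s <- sample_strain_at_nodes(fld, m, nodes)
  for (k in seq_along(nodes)) {
    inc <- sproutmech:::incident_elements(m)[nodes[k], ]
    inc <- inc[!is.na(inc)]
    or <- eigen_oracle(mean(fld$exx[inc]), mean(fld$eyy[inc]),
                       mean(fld$gxy[inc]))
    expect_equal(s$ep[k], or$ep, tolerance = 1e-12)
  }
  # interior node of a uniform-strain patch equals the element value
  u2 <- cbind(0, -0.1 * node_coords(m)[, 2])
  f2 <- principal_strains(u2, m)
  s2 <- sample_strain_at_nodes(f2, m, 22L)
  expect_equal(s2$ep, f2$ep[1], tolerance = 1e-12)
})

test_that("dipole load sets are self-equilibrated", {
  m <- square_mesh(10, 0.01)
  nodes <- c(34L, 56L, 67L)
  l1 <- ovsc_traction_loads(nodes, c(1L, 3L, 2L), m)
  nl <- net_load(l1, m)
  expect_equal(nl$force, c(0, 0), tolerance = 1e-20)
  expect_equal(nl$moment, 0, tolerance = 1e-20)
  l2 <- ec_traction_loads(c(45L), c(3L), m)
  expect_equal(net_load(l2, m)$force, c(0, 0), tolerance = 1e-20)
})

test_that("boundary amplitude calibration hits the target gap strain", {
  dom <- mini_domain()
  mesh <- assign_materials(build_mesh(dom))
  rois <- define_rois(dom)
  amp <- calibrate_amplitude(mesh, rois, "rigid", 0.11)
  bcs <- boundary_conditions(mesh, "rigid", amp)
  op <- fe_factorize(mesh, bcs)
  fld <- principal_strains(solve_displacements(op), mesh)
  sel <- sproutmech:::elements_in_roi(mesh, rois[rois$id == "ROI1_gap", ]) &
    mesh$region != 1L
  expect_equal(mean(abs(fld$ep[sel])), 0.11, tolerance = 1e-10)
})

test_that("the unloaded preset fixes all cortical DOFs", {
  dom <- mini_domain()
  mesh <- assign_materials(build_mesh(dom))
  bcs <- boundary_conditions(mesh, "unloaded")
  cort <- which(mesh$node_region == 1L)
  expect_setequal(bcs$dof, c(2L * cort - 1L, 2L * cort))
  expect_true(all(bcs$value == 0))
})
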