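test_that("stromal seeding covers marrow and periosteal tissue at 20%", {
  cfg <- mini_config(ec = list(seed_frac_periosteum = 0, seed_frac_marrow = 0))
  state <- sim_init(cfg, seed = 13)
  eligible <- sum(state$mesh$node_region %in% c(2L, 4L))
  n <- sum(state$ov_alive)
  expect_lt(abs(n - 0.2 * eligible), 4 * sqrt(0.2 * 0.8 * eligible))
  # gap granulation carries no cells at time zero
  expect_false(any(state$mesh$node_region[state$ov_node] == 3L))
  # all four orientations present
  expect_setequal(unique(state$ov_orient), 1:4)
  # reproducibility
  s2 <- sim_init(cfg, seed = 13)
  expect_identical(state$ov_node, s2$ov_node)
  expect_identical(state$ov_orient, s2$ov_orient)
})

test_that("density-biased migration moves a lone cell and drifts down gradients", {
  cfg <- make_fixture("uniform-strain", size = 40)
  state <- sim_init(cfg, seed = 3)
  nx1 <- state$mesh$nx + 1L
  i <- seed_cell(state, 20L + nx1 * 20L + 1L, 1L)
  old <- state$ov_node[i]
  migrate_density(state, i)
  expect_false(state$ov_node[i] == old)
  expect_true(state$ov_node[i] %in% sproutmech:::neighbour_matrix(state$mesh, old))
  # contact inhibition: fully surrounded cell stays
  state2 <- sim_init(cfg, seed = 3)
  ctr <- 20L + nx1 * 20L + 1L
  j <- seed_cell(state2, ctr, 1L)
  for (nb in sproutmech:::neighbour_matrix(state2$mesh, ctr)) seed_cell(state2, nb, 1L)
  migrate_density(state2, j)
  expect_equal(state2$ov_node[j], ctr)

  # net drift towards the sparse half under a density gradient
  state3 <- sim_init(cfg, seed = 4)
  xy <- node_coords(state3$mesh)
  dense <- which(xy[, 1] < 0.2 & xy[, 1] > 0.02 & xy[, 2] > 0.02 &
                   xy[, 2] < 0.38)
  set.seed(4)
  for (n in sample(dense, floor(length(dense) * 0.55))) seed_cell(state3, n, 1L)
  x0 <- mean(node_coords(state3$mesh, state3$ov_node)[, 1])
  for (k in 1:12) migrate_density(state3, which(state3$ov_alive))
  x1 <- mean(node_coords(state3$mesh, state3$ov_node)[, 1])
  expect_gt(x1, x0)
})

test_that("durotaxis metric is orientation-neutral in homogeneous tissue and lower on stiff ground", {
  # homogeneous: all four orientations probe the same deformation
  cfg <- make_fixture("two-stiffness", size = 40)
  state <- sim_init(cfg, seed = 5)
  nx1 <- state$mesh$nx + 1L
  soft_interior <- 10L + nx1 * 20L + 1L
  ms <- vapply(1:4, function(o) durotaxis_metric(state, soft_interior, o),
               numeric(1))
  expect_lt(diff(range(ms[c(1, 3)])), 1e-12)       # straight pair identical
  expect_lt(diff(range(ms[c(2, 4)])), 1e-12)       # diagonal pair identical
  expect_lt(diff(range(ms)), 1e-3 * max(ms))       # classes commensurable
  # stiff side probes a lower deformation
  stiff_interior <- 30L + nx1 * 20L + 1L
  expect_lt(durotaxis_metric(state, stiff_interior, 3L),
            durotaxis_metric(state, soft_interior, 3L))
})

test_that("durotaxis acceptance is strict descent and rejects equal metrics", {
  cfg <- make_fixture("two-stiffness", size = 40,
                      ovsc = list(durotaxis_onset_day = 0))
  state <- sim_init(cfg, seed = 6)
  nx1 <- state$mesh$nx + 1L
  i <- seed_cell(state, 10L + nx1 * 20L + 1L, 1L)
  metrics <- c()
  for (k in 1:40) {
    migrate_durotaxis(state, i)
    metrics <- c(metrics, durotaxis_metric(state, state$ov_node[i],
                                           state$ov_orient[i]))
  }
  # the lone cell's probed deformation never increases on a static substrate
  expect_true(all(diff(metrics) <= 1e-15))
})

test_that("a population on a stiffness step drifts onto the stiff side", {
  set.seed(7)
  cfg <- make_fixture("two-stiffness", size = 40,
                      ovsc = list(durotaxis_onset_day = 0,
                                  proliferation_day = 0, apoptosis_day = 0))
  state <- sim_init(cfg, seed = 7)
  free <- which(sproutmech:::ov_free(state))
  xy <- node_coords(state$mesh, free)
  inner <- free[xy[, 1] > 0.05 & xy[, 1] < 0.35 & xy[, 2] > 0.05 & xy[, 2] < 0.35]
  for (n in sample(inner, 100)) seed_cell(state, n, sample.int(4, 1))
  on_stiff <- function() {
    sum(node_coords(state$mesh, state$ov_node[state$ov_alive])[, 1] > 0.2)
  }
  before <- on_stiff()
  for (i in 1:504) sim_step(state)
  expect_gt(on_stiff(), before)
})

test_that("patch and exact own-dipole probing rank stiffness identically", {
  cfg <- make_fixture("two-stiffness", size = 30)
  state <- sim_init(cfg, seed = 8)
  nx1 <- state$mesh$nx + 1L
  nodes <- c(8L + nx1 * 15L + 1L,    # soft interior
             22L + nx1 * 15L + 1L,   # stiff interior
             19L + nx1 * 15L + 1L)   # near the step, soft side
  for (o in c(1L, 3L)) {
    patch <- vapply(nodes, function(n)
      sproutmech:::own_dipole_approach(state, n, o), numeric(1))
    exact <- vapply(nodes, function(n)
      sproutmech:::own_dipole_approach_exact(state, n, o), numeric(1))
    expect_identical(order(patch), order(exact))
    # patch truncation stays within ~10% of the full solve
    expect_true(all(abs(patch / exact - 1) < 0.1))
  }
})

test_that("proliferation matches the branching-process expectation with space", {
  cfg <- make_fixture("uniform-strain", size = 80)
  state <- sim_init(cfg, seed = 9)
  free <- which(sproutmech:::ov_free(state))
  set.seed(9)
  for (n in sample(free, 800)) seed_cell(state, n, 1L)
  n0 <- sum(state$ov_alive)
  for (i in 1:72) proliferate_and_die(state)   # one simulated day
  growth <- sum(state$ov_alive) / n0
  expected <- (1 + 0.33 / 72)^72 * (1 - 0.0003 / 72)^72
  expect_lt(abs(growth - expected), 4 * sqrt(expected / n0))
  # fully packed neighbourhood: no division
  st2 <- sim_init(cfg, seed = 10)
  nx1 <- st2$mesh$nx + 1L
  ctr <- 40L + nx1 * 40L + 1L
  seed_cell(st2, ctr, 1L)
  for (nb in sproutmech:::neighbour_matrix(st2$mesh, ctr)) seed_cell(st2, nb, 1L)
  st2$config$ovsc$proliferation_day <- 72 * 1440 / 20  # divide every iteration
  n_before <- sum(st2$ov_alive)
  proliferate_and_die(st2)
  # the 8 ring cells can still divide outward, the centre cannot; at most 8 births
  expect_lte(sum(st2$ov_alive) - n_before, 8L)
})

test_that("apoptosis-only dynamics lose cells at the stated rate", {
  cfg <- make_fixture("uniform-strain", size = 60,
                      ovsc = list(proliferation_day = 0, apoptosis_day = 0.2))
  state <- sim_init(cfg, seed = 11)
  free <- which(sproutmech:::ov_free(state))
  set.seed(11)
  for (n in sample(free, 1500)) seed_cell(state, n, 1L)
  n0 <- sum(state$ov_alive)
  for (i in 1:72) proliferate_and_die(state)
  loss <- 1 - sum(state$ov_alive) / n0
  expected <- 1 - (1 - 0.2 / 72)^72
  expect_lt(abs(loss - expected), 4 * sqrt(expected * (1 - expected) / n0))
})

test_that("stromal dipoles load the matrix toward the cell and vanish under knockout", {
  m <- square_mesh(10, 0.01)
  nx1 <- m$nx + 1L
  ctr <- 5L + nx1 * 5L + 1L
  l <- ovsc_traction_loads(ctr, 3L, m)           # vertical
  expect_equal(l$fy[l$node == ctr + nx1], -16e-6)
  expect_equal(l$fy[l$node == ctr - nx1], 16e-6)
  expect_equal(net_load(l, m)$force, c(0, 0))
  expect_length(ovsc_traction_loads(ctr, 3L, m, total_force = 0)$node, 0L)
})

test_that("orientation relaxation follows the strain response thresholds", {
  relax_to <- function(ep) {
    cfg <- make_fixture("uniform-strain", size = 30, ep = ep, theta = 90,
                        ovsc = list(durotaxis_onset_day = 0,
                                    proliferation_day = 0, apoptosis_day = 0,
                                    migration_rate_um_day = 0,
                                    relax_fraction = 1))
    state <- sim_init(cfg, seed = 12)
    free <- which(sproutmech:::ov_free(state))
    set.seed(12)
    for (n in sample(free, 60)) seed_cell(state, n, sample.int(4, 1))
    for (i in 1:30) relax_orientations(state, which(state$ov_alive))
    tabulate(state$ov_orient[state$ov_alive], 4)
  }
  # weak compression along the bone axis: align with it (vertical)
  low <- relax_to(-0.04)
  expect_equal(which.max(low), 3L)
  expect_gt(low[3] / sum(low), 0.9)
  # strong compression: avoid it (horizontal)
  high <- relax_to(-0.15)
  expect_equal(which.max(high), 1L)
  expect_gt(high[1] / sum(high), 0.9)
})
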