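# Orchestration of the coupled FEM <-> ABM loop: scenario configuration,
# the per-iteration update, full runs, replicates and parameter sweeps.
#
# One iteration represents 20 minutes; a 7-day simulation is 504
# iterations. Within an iteration: (1) collect EC and OVSC traction
# loads, (2) finite-element solve, (3) strain-field update, (4) EC
# updates (direction choice, elongation, branching, anastomosis, cadenced
# out-of-plane exchange, callus-front ingrowth), (5) OVSC updates
# (migration, proliferation/apoptosis).

#' Scenario configuration
#'
#' Builds the full configuration of a simulation scenario: boundary
#' condition preset, knockout switches, migration probabilities, material
#' table, cell parameters and run controls. The endothelial
#' mechano-response knockout fixes the migration mix at
#' `(p1, p2, p3) = (0.4, 0.6, 0)` (persistence kept, randomness raised,
#' strain rule removed); the baseline mix is `(0.4, 0.4, 0.2)`. The
#' stromal traction-force knockout sets the OVSC dipole magnitude to 0 N.
#'
#' @param scenario One of `"baseline-rigid"`, `"baseline-semirigid"`,
#'   `"ec-mr-ko"`, `"ovsc-tf-ko"`, `"unloaded"`,
#'   `"unloaded-ovsc-tf-ko"`.
#' @param domain A [healing_domain()]; the default is the full-size
#'   geometry.
#' @param materials Material table (see [default_material_table()]).
#' @param ec,ovsc Parameter lists ([ec_params()], [ovsc_params()]);
#'   entries given here override the defaults.
#' @param iteration_minutes Minutes of healing per iteration (default 20).
#' @param horizon_days Simulated duration (default 7).
#' @param replicates Number of stochastic realizations (default 6).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param target_gap_strain Mean compressive gap strain the boundary
#'   amplitude is calibrated to; defaults: rigid 0.11, semirigid 0.45.
#' @param bc_amplitude Optional explicit amplitude (mm), skipping
#'   calibration.
#' @param asymmetry Medio-lateral loading asymmetry (default 1.2).
#' @param update_order `"ec_first"` (default) or `"ovsc_first"`.
#' @param shared_occupancy If `TRUE`, endothelial and stromal cells block
#'   each other's lattice points; by default the two cell types occupy
#'   separate layers (two cell populations of a thick section projected
#'   onto one plane) and only vessel-vessel contact triggers anastomosis.
#' @param durotaxis_exact Probe the durotaxis deformation with a full
#'   solve of the cell's own dipole instead of the cached local patch.
#' @param fixed_strain Optional list `(ep, theta)` imposing a uniform
#'   analytic strain field and bypassing the FE solve (rule unit tests).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = "baseline-rigid",
                            domain = healing_domain(),
                            materials = default_material_table(),
                            ec = list(), ovsc = list(),
                            iteration_minutes = 20, horizon_days = 7,
                            replicates = 6, seed = 1L,
                            target_gap_strain = NULL,
                            bc_amplitude = NULL, asymmetry = 1.2,
                            update_order = c("ec_first", "ovsc_first"),
                            shared_occupancy = FALSE,
                            durotaxis_exact = FALSE,
                            fixed_strain = NULL) {
  scenarios <- c("baseline-rigid", "baseline-semirigid", "ec-mr-ko",
                 "ovsc-tf-ko", "unloaded", "unloaded-ovsc-tf-ko")
  if (!scenario %in% scenarios)
    stop("unknown scenario '", scenario, "'; expected one of ",
         paste(scenarios, collapse = ", "))
  update_order <- match.arg(update_order)
  ecp <- utils::modifyList(ec_params(), ec)
  ovp <- utils::modifyList(ovsc_params(), ovsc)

  bc_preset <- switch(scenario,
                      "baseline-semirigid" = "semirigid",
                      "unloaded" = ,
                      "unloaded-ovsc-tf-ko" = "unloaded",
                      "rigid")
  ec_mechanoresponse <- !(scenario == "ec-mr-ko")
  ovsc_traction <- !(scenario %in% c("ovsc-tf-ko", "unloaded-ovsc-tf-ko"))
  if (!ec_mechanoresponse && !length(ec)) {
    ecp$p1 <- 0.4; ecp$p2 <- 0.6; ecp$p3 <- 0
  }
  if (!ovsc_traction) ovp$ovsc_force_total <- 0

  if (is.null(target_gap_strain))
    target_gap_strain <- switch(bc_preset, rigid = 0.11, semirigid = 0.45, 0)

  cfg <- structure(list(
    scenario = scenario, bc_preset = bc_preset,
    ec_mechanoresponse = ec_mechanoresponse, ovsc_traction = ovsc_traction,
    domain = domain, materials = materials, ec = ecp, ovsc = ovp,
    iteration_minutes = iteration_minutes, horizon_days = horizon_days,
    replicates = replicates, seed = as.integer(seed),
    target_gap_strain = target_gap_strain, bc_amplitude = bc_amplitude,
    asymmetry = asymmetry, update_order = update_order,
    shared_occupancy = shared_occupancy,
    durotaxis_exact = durotaxis_exact, fixed_strain = fixed_strain
  ), class = "scenario_config")
  validate_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks the probability simplex of the migration mix, threshold ordering
#' and rate positivity; errors name the offending fields.
#'
#' @param config A `scenario_config`.
#' @return The config, invisibly.
#' @export
validate_config <- function(config) {
  ec <- config$ec; ov <- config$ovsc
  ps <- c(ec$p1, ec$p2, ec$p3)
  if (any(ps < 0) || any(ps > 1) || abs(sum(ps) - 1) > 1e-9)
    stop(sprintf("p1, p2, p3 must lie in [0,1] and sum to 1 (got %g, %g, %g)",
                 ps[1], ps[2], ps[3]))
  thr <- c(ec$strain_parallel_max, ec$strain_perpendicular_min, ec$strain_halt)
  if (any(diff(thr) <= 0))
    stop("strain thresholds must be strictly increasing: ",
         "strain_parallel_max < strain_perpendicular_min < strain_halt")
  rates <- c(growth_rate_um_h = ec$growth_rate_um_h,
             branch_coeff = ec$branch_coeff,
             migration_rate_um_day = ov$migration_rate_um_day,
             proliferation_day = ov$proliferation_day,
             apoptosis_day = ov$apoptosis_day)
  if (any(rates < 0))
    stop("negative rate(s): ",
         paste(names(rates)[rates < 0], collapse = ", "))
  if (config$ovsc$durotaxis_onset_day > config$horizon_days)
    stop("durotaxis_onset_day lies beyond the simulation horizon")
  if (config$iteration_minutes <= 0 || config$horizon_days <= 0 ||
      config$replicates < 1)
    stop("iteration_minutes, horizon_days must be positive; replicates >= 1")
  invisible(config)
}

#' Total number of iterations of a configuration
#' @param config `scenario_config`.
#' @return Integer iteration count (e.g. 504 for 7 days of 20-min steps).
#' @export
n_iterations <- function(config) {
  as.integer(round(config$horizon_days * 24 * 60 / config$iteration_minutes))
}

# Shared, read-only per-geometry context: mesh, ROIs, operator.
build_context <- function(config) {
  if (!is.null(config$fixture)) {
    # homogeneous / two-stiffness square harness, clamped at its boundary
    mesh <- square_mesh(config$fixture_size, config$fixture_pitch,
                        two_stiffness = config$fixture == "two-stiffness")
    rois <- NULL
    bcs <- clamp_boundary(mesh)
    op <- if (is.null(config$fixed_strain)) fe_factorize(mesh, bcs) else NULL
    amplitude <- 0
  } else {
    mesh <- assign_materials(build_mesh(config$domain), config$materials)
    rois <- define_rois(config$domain)
    amplitude <- config$bc_amplitude
    if (config$bc_preset == "unloaded") {
      amplitude <- 0
    } else if (is.null(amplitude)) {
      amplitude <- calibrate_amplitude(mesh, rois, config$bc_preset,
                                       config$target_gap_strain,
                                       config$asymmetry)
    }
    bcs <- boundary_conditions(mesh, config$bc_preset, amplitude,
                               config$asymmetry)
    op <- if (is.null(config$fixed_strain)) fe_factorize(mesh, bcs) else NULL
  }
  mat_key <- paste(mesh$E, mesh$nu)
  keys <- unique(mat_key)
  ke <- lapply(keys, function(k) {
    i <- match(k, mat_key)
    element_stiffness(mesh$E[i], mesh$nu[i], mesh$pitch)
  })
  list(mesh = mesh, rois = rois, bcs = bcs, op = op,
       amplitude = amplitude,
       mat_code = match(mat_key, keys), ke_by_mat = ke)
}

# fix all DOFs on the outer boundary of a mesh (fixated-dish harness)
clamp_boundary <- function(mesh) {
  xy <- node_coords(mesh)
  W <- mesh$nx * mesh$pitch; H <- mesh$ny * mesh$pitch
  eps <- mesh$pitch / 10
  bnd <- which(xy[, 1] < eps | xy[, 1] > W - eps |
                 xy[, 2] < eps | xy[, 2] > H - eps)
  dof <- c(2L * bnd - 1L, 2L * bnd)
  structure(list(preset = "unloaded", amplitude = 0, asymmetry = 1,
                 dof = dof, value = numeric(length(dof))),
            class = "bc_set")
}

#' Initialize a simulation state
#'
#' Builds (or reuses) the mesh and factorized operator, seeds the RNG,
#' seeds endothelial and stromal cells and returns the mutable state
#' environment on which [sim_step()] operates.
#'
#' @param config `scenario_config`.
#' @param seed Replicate seed (integer); `NULL` keeps the current RNG
#'   state.
#' @param context Optional shared context from a previous `sim_init` with
#'   the same geometry/materials/BCs (reused across replicates).
#' @return Environment of class `sim_state`.
#' @export
sim_init <- function(config, seed = NULL, context = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(context)) context <- build_context(config)
  mesh <- context$mesh
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$seed <- seed
  state$context <- context
  state$mesh <- mesh
  state$rois <- context$rois
  state$op <- context$op
  state$mat_code <- context$mat_code
  state$ke_by_mat <- context$ke_by_mat
  state$iter <- 0L
  state$ec_occ <- logical(mesh$nn)
  state$ov_occ <- logical(mesh$nn)
  state$shared_occ <- isTRUE(config$shared_occupancy)
  state$blocked <- mesh$node_region == 1L
  state$front_radius <- config$domain$callus_radius
  # sprout arrays
  state$n_sprouts <- 0L
  state$tip <- integer(0)
  state$active <- logical(0)
  state$loop <- logical(0)
  state$halted <- logical(0)
  state$prev_dir <- integer(0)
  state$last_branch <- integer(0)
  state$accum <- numeric(0)
  state$len_um <- numeric(0)
  state$path <- list()
  # stromal arrays
  state$ov_node <- integer(0)
  state$ov_orient <- integer(0)
  state$ov_alive <- logical(0)
  state$duro_cache <- new.env(parent = emptyenv())
  state$duro_key <- rep(NA_character_, mesh$nn)
  state$duro_ratio <- matrix(NA_real_, mesh$nn, 4)
  # fields
  state$u <- matrix(0, mesh$nn, 2, dimnames = list(NULL, c("ux", "uy")))
  state$field <- make_strain_field(mesh, config$fixed_strain)
  seed_initial_ecs(state)
  seed_ovscs(state)
  class(state) <- c("sim_state", "environment")
  state
}

# uniform (or zero) analytic strain field
make_strain_field <- function(mesh, fixed = NULL) {
  if (is.null(fixed)) fixed <- list(ep = 0, theta = 90)
  th <- fixed$theta * pi / 180
  ep <- fixed$ep
  # uniaxial strain of magnitude ep along theta
  exx <- ep * cos(th)^2
  eyy <- ep * sin(th)^2
  gxy <- 2 * ep * sin(th) * cos(th)
  pr <- principal_from_tensor(rep(exx, mesh$ne), rep(eyy, mesh$ne),
                              rep(gxy, mesh$ne))
  structure(list(exx = rep(exx, mesh$ne), eyy = rep(eyy, mesh$ne),
                 gxy = rep(gxy, mesh$ne), ep = pr$ep, theta = pr$theta),
            class = "strain_field")
}

#' Advance the simulation by one iteration
#'
#' Executes one 20-minute step in the fixed order: traction-load
#' collection, finite-element solve, strain sampling, endothelial updates,
#' stromal updates (order switchable via the configuration).
#'
#' @param state `sim_state` environment.
#' @return The state, invisibly.
#' @export
sim_step <- function(state) {
  config <- state$config
  state$iter <- state$iter + 1L

  # (1) cell traction loads
  ns <- state$n_sprouts
  act <- which(state$active[seq_len(ns)] & !is.na(state$prev_dir[seq_len(ns)]))
  ec_loads <- ec_traction_loads(state$tip[act], state$prev_dir[act],
                                state$mesh, config$ec$ec_force_total)
  ov <- which(state$ov_alive)
  ov_loads <- ovsc_traction_loads(state$ov_node[ov], state$ov_orient[ov],
                                  state$mesh, config$ovsc$ovsc_force_total)

  # (2)-(3) solve and strain field
  if (is.null(config$fixed_strain)) {
    loads <- combine_loads(ec_loads, ov_loads)
    state$u <- solve_displacements(state$op, loads)
    state$field <- principal_strains(state$u, state$mesh)
  }

  ec_phase <- function() {
    advance_tips(state)
    branch_sprouts(state)
    if (state$iter %% config$ec$oop_period == 0L) out_of_plane_exchange(state)
    callus_ingrowth(state)
  }
  ovsc_phase <- function() {
    pitch_um <- state$mesh$pitch * 1000
    credit <- config$ovsc$migration_rate_um_day * config$iteration_minutes / 1440
    period <- if (credit > 0) max(1L, as.integer(round(pitch_um / credit))) else NA
    day <- state$iter * config$iteration_minutes / 1440
    duro <- day >= config$ovsc$durotaxis_onset_day
    if (!is.na(period) && state$iter %% period == 0L) {
      cells <- which(state$ov_alive)
      if (length(cells)) {
        if (duro) migrate_durotaxis(state, cells) else migrate_density(state, cells)
      }
    }
    if (duro) {
      cells <- which(state$ov_alive)
      if (length(cells)) relax_orientations(state, cells)
    }
    proliferate_and_die(state)
  }
  if (config$update_order == "ec_first") { ec_phase(); ovsc_phase() }
  else { ovsc_phase(); ec_phase() }
  invisible(state)
}

#' Run a complete simulation
#'
#' @param config `scenario_config`.
#' @param seed Replicate seed.
#' @param context Optional shared geometry context (see [sim_init()]).
#' @param iterations Override the iteration count (default from the
#'   horizon).
#' @return Object of class `sim_result`: final state snapshot with the
#'   mesh, ROIs, sprout paths, stromal cells, displacement and strain
#'   fields.
#' @export
run_simulation <- function(config, seed = config$seed, context = NULL,
                           iterations = n_iterations(config)) {
  state <- sim_init(config, seed, context)
  for (i in seq_len(iterations)) sim_step(state)
  sim_result(state)
}

#' Snapshot a simulation state into a result object
#' @param state `sim_state`.
#' @return `sim_result` list.
#' @export
sim_result <- function(state) {
  ns <- state$n_sprouts
  alive <- which(state$ov_alive)
  structure(list(
    config = state$config, seed = state$seed, mesh = state$mesh,
    rois = state$rois, iterations = state$iter,
    path = state$path[seq_len(ns)],
    tip = state$tip[seq_len(ns)],
    active = state$active[seq_len(ns)],
    loop = state$loop[seq_len(ns)],
    prev_dir = state$prev_dir[seq_len(ns)],
    ov_node = state$ov_node[alive],
    ov_orient = state$ov_orient[alive],
    ec_occ = state$ec_occ, ov_occ = state$ov_occ,
    u = state$u, field = state$field,
    front_radius = state$front_radius
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: scenario %s, %d iterations, seed %s\n",
              x$config$scenario, x$iterations, format(x$seed)))
  cat(sprintf("  %d sprouts (%d active), %d stromal cells\n",
              length(x$path), sum(x$active), length(x$ov_node)))
  invisible(x)
}

#' Checkpoint and restore a running simulation
#'
#' `sim_checkpoint()` captures the complete state (including the RNG
#' stream) as a serializable list; `sim_restore()` rebuilds a state
#' environment that continues bit-identically to an uninterrupted run.
#' The factorized operator is rebuilt on restore.
#'
#' @param state `sim_state` environment.
#' @return For `sim_checkpoint`, a list; for `sim_restore`, a `sim_state`.
#' @export
sim_checkpoint <- function(state) {
  fields <- c("config", "seed", "iter", "ec_occ", "ov_occ", "front_radius",
              "n_sprouts", "tip", "active", "loop", "halted", "prev_dir",
              "last_branch", "accum", "len_um", "path",
              "ov_node", "ov_orient", "ov_alive", "u")
  chk <- stats::setNames(lapply(fields, function(f) state[[f]]), fields)
  chk$rng <- get(".Random.seed", envir = globalenv())
  chk
}

#' @rdname sim_checkpoint
#' @param chk A checkpoint list from [sim_checkpoint()].
#' @param context Optional shared context to avoid refactorizing.
#' @export
sim_restore <- function(chk, context = NULL) {
  if (is.null(context)) context <- build_context(chk$config)
  state <- new.env(parent = emptyenv())
  for (f in setdiff(names(chk), "rng")) state[[f]] <- chk[[f]]
  state$context <- context
  state$mesh <- context$mesh
  state$rois <- context$rois
  state$op <- context$op
  state$mat_code <- context$mat_code
  state$ke_by_mat <- context$ke_by_mat
  state$blocked <- context$mesh$node_region == 1L
  state$shared_occ <- isTRUE(chk$config$shared_occupancy)
  state$duro_cache <- new.env(parent = emptyenv())
  state$duro_key <- rep(NA_character_, context$mesh$nn)
  state$duro_ratio <- matrix(NA_real_, context$mesh$nn, 4)
  state$field <- if (is.null(chk$config$fixed_strain))
    principal_strains(chk$u, context$mesh)
  else make_strain_field(context$mesh, chk$config$fixed_strain)
  assign(".Random.seed", chk$rng, envir = globalenv())
  class(state) <- c("sim_state", "environment")
  state
}

# default per-replicate summary: ROI vessel densities + whole-region
# directionality bin fractions
replicate_metrics <- function(result) {
  rois <- result$rois
  dens <- vapply(c("ROI1_gap", "ROI2_marrow", "ROI3_periosteum"),
                 function(id) vessel_length_density(result, roi_by_id(rois, id)),
                 numeric(1))
  names(dens) <- paste0("density_", c("gap", "marrow", "periosteum"))
  dh <- directionality(result)
  bins <- dh$percent / 100
  names(bins) <- paste0("dirbin_", seq_along(bins))
  c(dens, bins)
}

#' Derive a replicate seed from the master seed
#' @param master Master seed.
#' @param i Replicate index.
#' @return Integer seed below 2^31.
#' @export
replicate_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + 7919 * i) %% 2147483647)
}

#' Run replicate realizations of a scenario
#'
#' Runs `config$replicates` seeded realizations, summarises each with a
#' metric vector (ROI vessel densities plus directionality-bin fractions
#' by default) and reports the mean and standard deviation per metric
#' together with the representative realization: the one whose metric
#' vector is closest (Euclidean) to the replicate mean.
#'
#' @param config `scenario_config`.
#' @param metrics_fn Function `sim_result -> named numeric vector`.
#' @param keep_results Keep the full `sim_result` objects (default TRUE).
#' @return Object of class `replicate_set`: list with `metrics` (matrix,
#'   replicates x metrics), `mean`, `sd`, `representative` (index),
#'   `seeds` and optionally `results`.
#' @export
run_replicates <- function(config, metrics_fn = replicate_metrics,
                           keep_results = TRUE) {
  n <- config$replicates
  seeds <- vapply(seq_len(n), function(i) replicate_seed(config$seed, i),
                  integer(1))
  if (anyDuplicated(seeds)) stop("derived replicate seeds collide")
  context <- build_context(config)
  results <- vector("list", n)
  mets <- NULL
  for (i in seq_len(n)) {
    r <- run_simulation(config, seed = seeds[i], context = context)
    m <- metrics_fn(r)
    if (is.null(mets)) mets <- matrix(NA_real_, n, length(m),
                                      dimnames = list(NULL, names(m)))
    mets[i, ] <- m
    if (keep_results) results[[i]] <- r
  }
  mu <- colMeans(mets)
  dist <- sqrt(rowSums(sweep(mets, 2, mu)^2))
  structure(list(metrics = mets, mean = mu,
                 sd = apply(mets, 2, stats::sd),
                 representative = which.min(dist), seeds = seeds,
                 results = if (keep_results) results else NULL),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set: %d realizations, representative #%d\n",
              nrow(x$metrics), x$representative))
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Parameter sweep over the migration probability mix
#'
#' Runs replicate sets over a grid of `(p1, p2)` with `p3 = 1 - p1 - p2`;
#' grid points off the probability simplex are skipped with a warning. No
#' automatic selection of a best point is made.
#'
#' @param p1_grid,p2_grid Numeric grids.
#' @param config Base `scenario_config`.
#' @param metrics_fn Per-replicate summary function.
#' @return data.frame with one row per valid grid point and replicate
#'   metric means (suffix `_sd` for standard deviations).
#' @export
run_sweep <- function(p1_grid, p2_grid, config,
                      metrics_fn = replicate_metrics) {
  rows <- list()
  for (p1 in p1_grid) for (p2 in p2_grid) {
    p3 <- 1 - p1 - p2
    if (p3 < -1e-9 || p1 < 0 || p2 < 0) {
      warning(sprintf("skipping (p1=%g, p2=%g): p3 = %g < 0", p1, p2, p3))
      next
    }
    cfg <- config
    cfg$ec$p1 <- p1; cfg$ec$p2 <- p2; cfg$ec$p3 <- max(0, p3)
    reps <- run_replicates(cfg, metrics_fn, keep_results = FALSE)
    rows[[length(rows) + 1]] <- c(p1 = p1, p2 = p2, p3 = max(0, p3),
                                  reps$mean,
                                  stats::setNames(reps$sd,
                                                  paste0(names(reps$sd), "_sd")))
  }
  if (!length(rows)) return(data.frame())
  as.data.frame(do.call(rbind, rows))
}
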