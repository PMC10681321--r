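# Shared lattice helpers: the 8 lattice directions, neighbourhoods and
# point-load containers.

# direction codes 1..8: E, NE, N, NW, W, SW, S, SE
DIR_DX <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
DIR_DY <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
DIR_ANGLE <- (0:7) * 45                       # degrees, ccw from +x
DIR_NORM <- sqrt(DIR_DX^2 + DIR_DY^2)         # 1 or sqrt(2) lattice units
DIR_UX <- DIR_DX / DIR_NORM
DIR_UY <- DIR_DY / DIR_NORM

# stromal orientation codes 1..4: horizontal 0, diagonal-right 45,
# vertical 90, diagonal-left 135 -> the same axes as direction codes 1..4
ORIENT_ANGLE <- c(0, 45, 90, 135)

# free-lattice predicates. ECs and OVSCs live on separate occupancy
# layers by default (an endothelial cell and a stromal cell may project
# onto the same lattice point of the 2D section); with
# `shared_occupancy = TRUE` the two cell types block each other.
ec_free <- function(state, nodes = seq_len(state$mesh$nn)) {
  ok <- !state$ec_occ[nodes] & !state$blocked[nodes]
  if (state$shared_occ) ok <- ok & !state$ov_occ[nodes]
  ok
}

ov_free <- function(state, nodes = seq_len(state$mesh$nn)) {
  ok <- !state$ov_occ[nodes] & !state$blocked[nodes]
  if (state$shared_occ) ok <- ok & !state$ec_occ[nodes]
  ok
}

# smallest angular distance between two axes (degrees, mod 180)
axis_distance <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

# neighbour node ids along direction codes; NA when off-grid (vectorized)
neighbour_nodes <- function(mesh, nodes, dirs) {
  nx <- mesh$nx
  ix <- (nodes - 1L) %% (nx + 1L) + DIR_DX[dirs]
  iy <- (nodes - 1L) %/% (nx + 1L) + DIR_DY[dirs]
  out <- ix + (nx + 1L) * iy + 1L
  out[ix < 0L | ix > nx | iy < 0L | iy > mesh$ny] <- NA_integer_
  out
}

# all 8 neighbours of a set of nodes: length(nodes) x 8 matrix, NA off-grid
neighbour_matrix <- function(mesh, nodes) {
  nx <- mesh$nx
  ix <- outer((nodes - 1L) %% (nx + 1L), DIR_DX, `+`)
  iy <- outer((nodes - 1L) %/% (nx + 1L), DIR_DY, `+`)
  out <- ix + (nx + 1L) * iy + 1L
  out[ix < 0L | ix > nx | iy < 0L | iy > mesh$ny] <- NA_integer_
  storage.mode(out) <- "integer"
  out
}

# mean of a numeric field over each node's 9-point neighbourhood
# (self + 8 neighbours), handling the grid boundary
neigh_mean9 <- function(mesh, x) {
  nx1 <- mesh$nx + 1L; ny1 <- mesh$ny + 1L
  M <- matrix(as.numeric(x), nx1, ny1)
  P <- matrix(0, nx1 + 2L, ny1 + 2L)
  C <- matrix(0, nx1 + 2L, ny1 + 2L)
  P[2:(nx1 + 1L), 2:(ny1 + 1L)] <- M
  C[2:(nx1 + 1L), 2:(ny1 + 1L)] <- 1
  S <- 0; W <- 0
  for (dx in 0:2) for (dy in 0:2) {
    S <- S + P[dx + seq_len(nx1), dy + seq_len(ny1)]
    W <- W + C[dx + seq_len(nx1), dy + seq_len(ny1)]
  }
  as.numeric(S / W)
}

# map a continuous target axis (degrees mod 180) to a signed lattice
# direction code: nearest of the four lattice axes, forward sense chosen to
# maximize the dot product with the previous step (no immediate reversal);
# exact ties are broken at random.
axis_to_direction <- function(theta_target, prev_dir) {
  n <- length(theta_target)
  out <- integer(n)
  # tiny random jitter resolves exact 22.5-degree ties via the rng
  th <- (theta_target + stats::runif(n, -1e-6, 1e-6)) %% 180
  axis <- (round(th / 45) %% 4) + 1L           # codes 1..4 (axes 0,45,90,135)
  fwd <- axis                                  # code with angle < 180
  bwd <- axis + 4L                             # opposite sense
  for (i in seq_len(n)) {
    if (is.na(prev_dir[i])) {
      out[i] <- if (stats::runif(1) < 0.5) fwd[i] else bwd[i]
    } else {
      dot_f <- DIR_UX[fwd[i]] * DIR_UX[prev_dir[i]] +
        DIR_UY[fwd[i]] * DIR_UY[prev_dir[i]]
      dot_b <- -dot_f
      if (abs(dot_f - dot_b) < 1e-12) {
        out[i] <- if (stats::runif(1) < 0.5) fwd[i] else bwd[i]
      } else if (dot_f > dot_b) out[i] <- fwd[i] else out[i] <- bwd[i]
    }
  }
  out
}

#' Construct a point-load set
#'
#' @param node Integer node ids (may repeat).
#' @param fx,fy Force components (N).
#' @return Object of class `point_load_set`.
#' @export
point_load_set <- function(node = integer(), fx = numeric(), fy = numeric()) {
  stopifnot(length(node) == length(fx), length(fx) == length(fy))
  structure(list(node = as.integer(node), fx = fx, fy = fy),
            class = "point_load_set")
}

#' Combine point-load sets
#' @param ... `point_load_set` objects.
#' @return A single `point_load_set`.
#' @export
combine_loads <- function(...) {
  ls <- list(...)
  point_load_set(unlist(lapply(ls, `[[`, "node")),
                 unlist(lapply(ls, `[[`, "fx")),
                 unlist(lapply(ls, `[[`, "fy")))
}

# dense force vector (length ndof) from a point_load_set; duplicate node
# entries accumulate (sparse-matrix reduction)
as_force_vector <- function(loads, ndof) {
  f <- numeric(ndof)
  if (length(loads$node)) {
    ix <- c(2L * loads$node - 1L, 2L * loads$node)
    v <- c(loads$fx, loads$fy)
    sm <- Matrix::sparseMatrix(i = ix, j = rep(1L, length(ix)), x = v,
                               dims = c(ndof, 1L))
    f[sm@i + 1L] <- sm@x
  }
  f
}

#' Net force and moment of a point-load set
#'
#' Dipole loads are self-equilibrated: zero net force, and zero net moment
#' for collinear pairs.
#' @param loads `point_load_set`.
#' @param mesh `fe_mesh` (for node coordinates, moment about the origin).
#' @return List with `force` (Fx, Fz) and `moment` (N mm).
#' @export
net_load <- function(loads, mesh) {
  if (!length(loads$node)) return(list(force = c(0, 0), moment = 0))
  xy <- node_coords(mesh, loads$node)
  list(force = c(sum(loads$fx), sum(loads$fy)),
       moment = sum(xy[, 1] * loads$fy - xy[, 2] * loads$fx))
}

# FNV-1a 32-bit hash of a character string (config fingerprints);
# arithmetic split into 16-bit halves to stay exact in doubles
fnv1a <- function(s) {
  b <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (x in b) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(x))
    hi <- as.integer(h %/% 65536)
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
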