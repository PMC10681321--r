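# Morphometric quantification of the simulated microvascular network and
# stromal cell organisation, mirroring the image-analysis pipeline used on
# histological sections: vessel length density (skeleton-to-area ratio),
# 20-degree directionality histograms with an axis/perpendicular/other
# grouping, vessel length and self-loop statistics, stromal orientation
# fractions, and the non-parametric group comparisons.

# vessel segments of a result: matrix with midpoint coordinates (mm),
# axis angle (deg, mod 180) and length (um)
vessel_segments <- function(result) {
  mesh <- result$mesh
  segs <- lapply(result$path, function(p) {
    if (length(p) < 2) return(NULL)
    cbind(p[-length(p)], p[-1])
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs) || !nrow(segs))
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("x", "y", "angle", "length_um"))))
  a <- node_coords(mesh, segs[, 1])
  b <- node_coords(mesh, segs[, 2])
  dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
  ang <- (atan2(dy, dx) * 180 / pi) %% 180
  cbind(x = (a[, 1] + b[, 1]) / 2, y = (a[, 2] + b[, 2]) / 2,
        angle = ang, length_um = sqrt(dx^2 + dy^2) * 1000)
}

#' Vessel length density ratio within an ROI
#'
#' The ratio of vessel skeleton area to total area inside the region of
#' interest. Simulated vessels are one lattice point wide, so the ratio is
#' the fraction of ROI lattice points occupied by endothelial cells; an
#' imported raster mask is skeletonized (see [skeletonize_mask()]) before
#' the same ratio is taken.
#'
#' @param x A `sim_result`, or a logical/0-1 raster mask matrix.
#' @param roi One-row ROI (from [define_rois()]); required for
#'   `sim_result` input, ignored for masks (the mask is the ROI).
#' @param skeletonized For mask input: set `TRUE` if the mask is already a
#'   skeleton.
#' @return Density ratio in [0, 1].
#' @export
vessel_length_density <- function(x, roi = NULL, skeletonized = FALSE) {
  if (inherits(x, "sim_result")) {
    stopifnot(!is.null(roi))
    sel <- nodes_in_roi(x$mesh, roi)
    if (!any(sel)) stop("ROI contains no lattice points")
    return(sum(x$ec_occ[sel]) / sum(sel))
  }
  m <- x != 0
  if (!length(m)) stop("empty mask")
  if (!skeletonized) m <- skeletonize_mask(m)
  sum(m) / length(m)
}

#' Skeletonize a binary raster mask
#'
#' Zhang-Suen thinning to a one-pixel-wide skeleton, used to make imported
#' vessel masks comparable with the one-lattice-point-wide simulated
#' vessels. Idempotent on already-thin masks.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of the same size.
#' @export
skeletonize_mask <- function(mask) {
  img <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  pad <- matrix(FALSE, nrow(img) + 2, ncol(img) + 2)
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)] <- img
  nr <- nrow(pad); nc <- ncol(pad)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north (row - 1)
      p <- list(shift(pad, 1, 0), shift(pad, 1, -1), shift(pad, 0, -1),
                shift(pad, -1, -1), shift(pad, -1, 0), shift(pad, -1, 1),
                shift(pad, 0, 1), shift(pad, 1, 1))
      B <- Reduce(`+`, p)
      A <- Reduce(`+`, lapply(1:8, function(i) {
        (!p[[i]]) & p[[if (i == 8) 1 else i + 1]]
      }))
      if (step == 1) {
        c1 <- !(p[[1]] & p[[3]] & p[[5]])
        c2 <- !(p[[3]] & p[[5]] & p[[7]])
      } else {
        c1 <- !(p[[1]] & p[[3]] & p[[7]])
        c2 <- !(p[[1]] & p[[5]] & p[[7]])
      }
      del <- pad & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        pad[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)]
}

#' Directionality histogram of vessel segments
#'
#' Each inter-point vessel segment contributes its length to the 20-degree
#' bin of its axis orientation over [0, 180): bins [0,20), [20,40), ...,
#' [160,180), with 180 wrapping to 0. Percentages are length-weighted and
#' normalized to 100. The grouped summary reports the fraction aligned
#' with the bone long axis (80-100), perpendicular to it (0-20 and
#' 160-180) and all other directions.
#'
#' @param result `sim_result`.
#' @param roi Optional one-row ROI; segments whose midpoint falls inside
#'   are counted (default: whole domain).
#' @return Object of class `directionality_histogram`: list with
#'   `percent` (9 bins), `groups` (axis/perpendicular/other, percent),
#'   `total_length_um` and `n_segments`. With no vessel elements in the
#'   ROI the histogram is flagged `undefined`.
#' @export
directionality <- function(result, roi = NULL) {
  segs <- vessel_segments(result)
  if (!is.null(roi)) {
    keep <- segs[, "x"] >= roi$xmin - 1e-9 & segs[, "x"] <= roi$xmax + 1e-9 &
      segs[, "y"] >= roi$ymin - 1e-9 & segs[, "y"] <= roi$ymax + 1e-9
    segs <- segs[keep, , drop = FALSE]
  }
  edges <- seq(0, 180, by = 20)
  if (!nrow(segs)) {
    return(structure(list(percent = rep(NA_real_, 9), groups = NULL,
                          total_length_um = 0, n_segments = 0L,
                          undefined = TRUE),
                     class = "directionality_histogram"))
  }
  bin <- findInterval(segs[, "angle"] %% 180, edges,
                      rightmost.closed = FALSE)
  bin[bin == 10L] <- 1L                 # 180 wraps to 0
  w <- vapply(1:9, function(b) sum(segs[bin == b, "length_um"]), numeric(1))
  pct <- 100 * w / sum(w)
  groups <- c(axis = pct[5],
              perpendicular = pct[1] + pct[9],
              other = sum(pct[c(2:4, 6:8)]))
  structure(list(percent = pct, groups = groups,
                 total_length_um = sum(segs[, "length_um"]),
                 n_segments = nrow(segs), undefined = FALSE),
            class = "directionality_histogram")
}

#' @export
print.directionality_histogram <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("directionality histogram: undefined (no vessel elements)\n")
    return(invisible(x))
  }
  b <- sprintf("[%d,%d)", seq(0, 160, 20), seq(20, 180, 20))
  print(round(stats::setNames(x$percent, b), 1))
  cat("groups (%):", sprintf("axis %.1f, perpendicular %.1f, other %.1f\n",
                             x$groups["axis"], x$groups["perpendicular"],
                             x$groups["other"]))
  invisible(x)
}

#' Vessel length distribution and self-loop count
#'
#' Per-sprout path length in micrometres (straight steps contribute one
#' pitch, diagonal steps sqrt(2) pitches) and the number of sprouts that
#' closed a loop by intersecting their own path. Single-cell sprouts that
#' never elongated carry zero length and are excluded from the length
#' distribution (a vessel fragment is at least one step long).
#'
#' @param result `sim_result`.
#' @return List with `lengths_um` (per elongated sprout), `mean_length_um`
#'   and `loops`.
#' @export
vessel_lengths_and_loops <- function(result) {
  mesh <- result$mesh
  lens <- vapply(result$path, function(p) path_length_um(mesh, p), numeric(1))
  lens <- lens[lens > 0]
  list(lengths_um = lens,
       mean_length_um = if (length(lens)) mean(lens) else NA_real_,
       loops = sum(result$loop))
}

#' Stromal orientation fractions within an ROI
#'
#' Fraction of stromal cells per orientation class (horizontal, diagonal
#' right, vertical, diagonal left) plus the bone-axis (vertical) and
#' perpendicular (horizontal) summary fractions.
#'
#' @param result `sim_result`.
#' @param roi Optional one-row ROI (default: whole domain).
#' @return List with `fractions` (length 4), `n`, `axis_fraction`
#'   (vertical) and `perpendicular_fraction` (horizontal); `n = 0` flags
#'   an empty ROI.
#' @export
ovsc_orientation_fractions <- function(result, roi = NULL) {
  nodes <- result$ov_node
  orients <- result$ov_orient
  if (!is.null(roi)) {
    keep <- nodes_in_roi(result$mesh, roi)[nodes]
    nodes <- nodes[keep]; orients <- orients[keep]
  }
  n <- length(nodes)
  if (!n) {
    return(list(fractions = stats::setNames(rep(NA_real_, 4),
                                            c("horizontal", "diagonal_right",
                                              "vertical", "diagonal_left")),
                n = 0L, axis_fraction = NA_real_,
                perpendicular_fraction = NA_real_))
  }
  f <- tabulate(orients, nbins = 4) / n
  names(f) <- c("horizontal", "diagonal_right", "vertical", "diagonal_left")
  list(fractions = f, n = n,
       axis_fraction = f[["vertical"]],
       perpendicular_fraction = f[["horizontal"]])
}

#' Non-parametric comparison of orientation groups
#'
#' Kruskal-Wallis H test across the groups; when significant at
#' `alpha`, pairwise two-sided Mann-Whitney U tests (exact where
#' possible) with Bonferroni-corrected significance level. With exactly
#' two groups the Mann-Whitney test is applied directly. Degenerate
#' identical samples report no difference with p = 1.
#'
#' @param samples Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `group_comparison`: list with `kruskal_p`,
#'   `pairwise` (data.frame: pair, p, p_bonferroni, significant,
#'   direction) and `alpha_bonferroni`.
#' @export
compare_orientation_groups <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  if (any(lengths(samples) < 2))
    stop("each group needs at least 2 replicate values")
  vals <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(names(samples), lengths(samples)),
                levels = names(samples))
  if (length(unique(vals)) == 1L) {
    return(structure(list(kruskal_p = 1, pairwise = NULL,
                          alpha_bonferroni = alpha, note = "identical samples"),
                     class = "group_comparison"))
  }
  kp <- if (length(samples) > 2)
    suppressWarnings(stats::kruskal.test(vals, grp)$p.value) else NA_real_
  pairs <- utils::combn(names(samples), 2, simplify = FALSE)
  m <- length(pairs)
  alpha_b <- alpha / m
  do_pairs <- is.na(kp) || kp <= alpha
  pw <- NULL
  if (do_pairs) {
    pw <- do.call(rbind, lapply(pairs, function(p) {
      a <- samples[[p[1]]]; b <- samples[[p[2]]]
      pv <- if (length(unique(c(a, b))) == 1L) 1 else
        suppressWarnings(stats::wilcox.test(a, b)$p.value)
      data.frame(pair = paste(p, collapse = " vs "),
                 p = pv, p_bonferroni = min(1, pv * m),
                 significant = pv <= alpha_b,
                 direction = if (stats::median(a) > stats::median(b))
                   paste(p[1], ">", p[2])
                 else if (stats::median(a) < stats::median(b))
                   paste(p[1], "<", p[2]) else "none",
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(kruskal_p = kp, pairwise = pw, alpha_bonferroni = alpha_b),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  if (!is.na(x$kruskal_p)) cat(sprintf("Kruskal-Wallis p = %.4g\n", x$kruskal_p))
  if (!is.null(x$pairwise)) {
    cat(sprintf("pairwise Mann-Whitney (Bonferroni alpha = %.4g):\n",
                x$alpha_bonferroni))
    print(x$pairwise, row.names = FALSE)
  } else cat("no pairwise tests (omnibus not significant)\n")
  invisible(x)
}

#' Two-sample t-test for density comparisons
#'
#' Two-tailed Student's t-test used for vessel-density comparisons
#' between regions or between simulation and experiment.
#'
#' @param a,b Numeric vectors of replicate densities.
#' @param var_equal Pool variances (classical Student test, default TRUE).
#' @return `htest` object from [stats::t.test()].
#' @export
compare_densities <- function(a, b, var_equal = TRUE) {
  stats::t.test(a, b, var.equal = var_equal)
}
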