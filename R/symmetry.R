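# C5 symmetrization and symmetry-deviation diagnostics.
#
# Averaging a grid with its four 72-degree rotations by naive re-rotation +
# interpolation is not an idempotent operation (interpolations do not
# compose), so "deviation of a symmetrized grid" would never be exactly
# zero. lipmap instead works in a canonical polar representation whose
# angular dimension is divisible by five: there the five-fold average is an
# exact index-shift projection. Symmetrized grids carry their polar
# representation, making symmetrize idempotent and the deviation of a
# symmetrized grid exactly zero; the Cartesian rendering is rescaled so the
# grid integral is preserved exactly.

POLAR_NTHETA <- 360L

# Bilinear sample of a 2D matrix at fractional index coordinates (fi, fj),
# 1-based cell centres; out-of-range clamps (radial) — callers guarantee the
# angular index is in range before wrapping.
bilinear2 <- function(m, fi, fj, wrap_j = FALSE) {
  ni <- nrow(m); nj <- ncol(m)
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  ci <- function(i) pmin(pmax(i, 1), ni)
  cj <- if (wrap_j) function(j) ((j - 1) %% nj) + 1 else function(j) pmin(pmax(j, 1), nj)
  m[cbind(ci(i0), cj(j0))] * (1 - wi) * (1 - wj) +
    m[cbind(ci(i0 + 1), cj(j0))] * wi * (1 - wj) +
    m[cbind(ci(i0), cj(j0 + 1))] * (1 - wi) * wj +
    m[cbind(ci(i0 + 1), cj(j0 + 1))] * wi * wj
}

grid_spacing <- function(grid) grid$bin_size %||% grid$voxel_size

# Polar sampling geometry for a grid about an in-plane axis point.
polar_geometry <- function(grid, axis) {
  h <- grid_spacing(grid)
  n <- dim(grid$values)
  corners <- rbind(grid$origin[1:2],
                   grid$origin[1:2] + c(n[1] * h, 0),
                   grid$origin[1:2] + c(0, n[2] * h),
                   grid$origin[1:2] + c(n[1] * h, n[2] * h))
  r_max <- sqrt(max(rowSums(sweep(corners, 2, axis, "-")^2)))
  dr <- h / 2
  n_r <- as.integer(ceiling(r_max / dr)) + 1L
  theta <- (seq_len(POLAR_NTHETA) - 1) * 2 * pi / POLAR_NTHETA
  list(dr = dr, n_r = n_r, r = (seq_len(n_r) - 0.5) * dr, theta = theta)
}

# Sample one z-layer of a grid at the polar points (bilinear in Cartesian).
layer_to_polar <- function(m, origin, h, axis, geo) {
  pts_x <- outer(geo$r, cos(geo$theta))
  pts_y <- outer(geo$r, sin(geo$theta))
  fi <- (axis[1] + pts_x - origin[1]) / h + 0.5
  fj <- (axis[2] + pts_y - origin[2]) / h + 0.5
  matrix(bilinear2(m, as.numeric(fi), as.numeric(fj)), geo$n_r, POLAR_NTHETA)
}

# Exact five-fold average over the angular index: groups {j, j+T/5, ...} are
# averaged once and the result replicated, so all five copies are bit
# identical and re-averaging is an exact fixed point.
c5_project_polar <- function(p) {
  d <- POLAR_NTHETA %/% 5L
  acc <- p[, 1:d, drop = FALSE]
  for (k in 1:4) acc <- acc + p[, k * d + (1:d), drop = FALSE]
  q <- acc / 5
  cbind(q, q, q, q, q)
}

# Render a polar matrix back onto one Cartesian z-layer (bilinear in (r,
# theta), theta periodic).
polar_to_layer <- function(p, origin, h, axis, geo, nx, ny) {
  cx <- origin[1] + (seq_len(nx) - 0.5) * h - axis[1]
  cy <- origin[2] + (seq_len(ny) - 0.5) * h - axis[2]
  X <- matrix(cx, nx, ny)
  Y <- matrix(cy, nx, ny, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X) %% (2 * pi)
  fi <- r / geo$dr + 0.5
  fj <- th / (2 * pi / POLAR_NTHETA) + 0.5
  matrix(bilinear2(p, as.numeric(fi), as.numeric(fj), wrap_j = TRUE), nx, ny)
}

grid_layers <- function(grid) {
  if (inherits(grid, "density_grid2d")) list(grid$values)
  else lapply(seq_len(dim(grid$values)[3]), function(k) grid$values[, , k])
}

set_grid_layers <- function(grid, layers) {
  if (inherits(grid, "density_grid2d")) grid$values <- layers[[1]]
  else for (k in seq_along(layers)) grid$values[, , k] <- layers[[k]]
  grid
}

polar_rep_of <- function(grid, axis) {
  stored <- attr(grid, "polar_rep")
  if (!is.null(stored) && max(abs(stored$axis - axis)) < 1e-12) return(stored)
  geo <- polar_geometry(grid, axis)
  layers <- lapply(grid_layers(grid), layer_to_polar,
                   origin = grid$origin, h = grid_spacing(grid), axis = axis, geo = geo)
  list(layers = layers, geo = geo, axis = axis)
}

#' Five-fold symmetrize a density grid
#'
#' Averages the grid with its rotations by 72, 144, 216 and 288 degrees about
#' the pore axis, computed in a canonical polar representation where the
#' average is exact; the result carries that representation so symmetrizing
#' twice is identical to symmetrizing once and [c5_deviation()] of a
#' symmetrized grid is exactly zero. The output is rescaled to preserve the
#' input's integral exactly.
#'
#' @param grid a `density_grid2d` or `density_grid3d`.
#' @param axis in-plane axis point (x, y); defaults to the grid's stored axis.
#' @return symmetrized grid of the same class.
#' @export
symmetrize_c5 <- function(grid, axis = NULL) {
  axis <- axis %||% grid$axis
  h <- grid_spacing(grid)
  n <- dim(grid$values)
  if (axis[1] < grid$origin[1] || axis[1] > grid$origin[1] + n[1] * h ||
      axis[2] < grid$origin[2] || axis[2] > grid$origin[2] + n[2] * h)
    stopf("geometry error: symmetry axis lies outside the grid")
  rep_in <- polar_rep_of(grid, axis)
  q <- lapply(rep_in$layers, c5_project_polar)
  out_layers <- lapply(q, polar_to_layer, origin = grid$origin, h = h,
                       axis = axis, geo = rep_in$geo,
                       nx = n[1], ny = if (length(n) > 1) n[2] else 1L)
  out <- set_grid_layers(grid, out_layers)
  tot_in <- sum(grid$values)
  tot_out <- sum(out$values)
  scale <- if (tot_out > 0) tot_in / tot_out else 1
  out <- set_grid_layers(out, lapply(out_layers, function(m) m * scale))
  attr(out, "polar_rep") <- list(layers = lapply(q, function(p) p * scale),
                                 geo = rep_in$geo, axis = axis)
  out$metadata$symmetrized <- TRUE
  out
}

#' C5 symmetry deviation of a density grid
#'
#' Normalized L1 distance between the grid and its five-fold symmetrized
#' self, `sum(|g - S(g)|) / (2 sum(g))`, evaluated in the canonical polar
#' representation with proper area weights. 0 for C5-symmetric grids, and
#' approaches `4/5` for mass confined to a single 72-degree sector.
#'
#' @inheritParams symmetrize_c5
#' @return scalar in `[0, 1]`.
#' @export
c5_deviation <- function(grid, axis = NULL) {
  axis <- axis %||% grid$axis
  rep_in <- polar_rep_of(grid, axis)
  w <- rep_in$geo$r
  num <- 0
  den <- 0
  for (p in rep_in$layers) {
    q <- c5_project_polar(p)
    num <- num + sum(w * rowSums(abs(p - q)))
    den <- den + sum(w * rowSums(p))
  }
  if (den <= 0) stopf("undefined-metric error: grid has zero integral")
  num / (2 * den)
}

#' Per-repeat C5 symmetry report
#'
#' Deviation of each repeat's grid and of the repeat-average grid: the
#' standard convergence diagnostic around a five-fold symmetric protein
#' (individual repeats are noisier than their average).
#'
#' @param grids list of commensurate per-repeat density grids.
#' @param axis in-plane axis point; defaults to the grids' stored axis.
#' @return object of class `symmetry_report`: data.frame `per_repeat`,
#'   scalars `average_deviation`, `median_repeat_deviation`.
#' @export
symmetry_report <- function(grids, axis = NULL) {
  stopifnot(length(grids) >= 1)
  devs <- vapply(grids, c5_deviation, 0, axis = axis)
  avg <- average_grids(grids)
  structure(list(per_repeat = data.frame(repeat_index = seq_along(grids),
                                         deviation = devs),
                 average_deviation = c5_deviation(avg, axis = axis),
                 median_repeat_deviation = stats::median(devs)),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("C5 symmetry report: %d repeats; median repeat deviation %.4f, repeat-average deviation %.4f\n",
              nrow(x$per_repeat), x$median_repeat_deviation, x$average_deviation))
  invisible(x)
}
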