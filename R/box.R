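# Periodic-cell geometry. The simulation cell is triclinic; the default is a
# hexagonal prism represented with lattice vectors
#   v1 = (a, 0, 0),  v2 = (-a/2, a*sqrt(3)/2, 0),  v3 = (0, 0, c),
# the standard triclinic embedding of a hexagonal cross-section.

#' Hexagonal prism periodic cell
#'
#' @param a in-plane lattice constant (nm).
#' @param c height of the prism (nm).
#' @return 3x3 matrix whose rows are the lattice vectors (nm).
#' @examples
#' hexagonal_box(12, 10)
#' @export
hexagonal_box <- function(a, c = a) {
  stopifnot(a > 0, c > 0)
  matrix(c(a, 0, 0, -a / 2, a * sqrt(3) / 2, 0, 0, 0, c),
         nrow = 3, byrow = TRUE)
}

box_volume <- function(box) det(box)

check_box <- function(box) {
  if (!is.matrix(box) || !all(dim(box) == c(3, 3)) || !all(is.finite(box)))
    stopf("box must be a finite 3x3 matrix of lattice vectors")
  if (box_volume(box) <= 0)
    stopf("degenerate box: volume must be positive")
  invisible(box)
}

# Cartesian (rows of x) -> fractional coordinates, row convention x = s %*% box.
cart_to_frac <- function(x, box) x %*% solve(box)
frac_to_cart <- function(s, box) s %*% box

#' Wrap points into the primitive cell
#'
#' @param x n x 3 matrix of coordinates (nm).
#' @param box 3x3 lattice-vector matrix.
#' @return n x 3 matrix with fractional coordinates in [0, 1).
#' @export
wrap_points <- function(x, box) {
  check_box(box)
  s <- cart_to_frac(x, box)
  frac_to_cart(s - floor(s), box)
}

#' Minimum-image distance under a triclinic cell
#'
#' Minimum over the 27 nearest lattice images of |p - q + n1 v1 + n2 v2 + n3 v3|.
#' Valid for separations well below the cell size (the use case here:
#' contact cutoffs and site radii much smaller than the box).
#'
#' @param p,q points, either length-3 vectors or n x 3 matrices (nm).
#' @param box 3x3 lattice-vector matrix.
#' @return numeric vector of distances (nm).
#' @examples
#' b <- hexagonal_box(10)
#' min_image_distance(c(9.5, 0, 0), c(0, 0, 0), b)  # 0.5
#' @export
min_image_distance <- function(p, q, box) {
  check_box(box)
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  stopifnot(ncol(p) == 3, ncol(q) == 3, nrow(p) == nrow(q))
  sqrt(min_image_dist2(p - q, box))
}

# Squared minimum-image length of displacement rows `d`. Strategy: reduce to
# the central image by rounding fractional coordinates, then search the 27
# neighbouring images, which is exact for any reduced displacement.
min_image_dist2 <- function(d, box) {
  s <- cart_to_frac(d, box)
  s <- s - round(s)
  d0 <- frac_to_cart(s, box)
  best <- rep(Inf, nrow(d0))
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    shift <- i * box[1, ] + j * box[2, ] + k * box[3, ]
    dd <- sweep(d0, 2, shift, "+")
    best <- pmin(best, rowSums(dd * dd))
  }
  best
}

# In-plane (x, y) squared minimum-image distance: used by the 2D lipid
# dynamics and density code, where z is not a periodic degree of freedom of
# interest. `d` is an n x 2 matrix of displacements.
min_image_dist2_xy <- function(d, box) {
  b2 <- box[1:2, 1:2]
  s <- d %*% solve(b2)
  s <- s - round(s)
  d0 <- s %*% b2
  best <- rowSums(d0 * d0)
  for (i in -1:1) for (j in -1:1) {
    if (i == 0 && j == 0) next
    dd <- sweep(d0, 2, i * b2[1, ] + j * b2[2, ], "+")
    best <- pmin(best, rowSums(dd * dd))
  }
  best
}

# Minimum-image displacement vectors in-plane (returns n x 2 matrix pointing
# from q to p, i.e. p - q reduced).
min_image_disp_xy <- function(d, box) {
  b2 <- box[1:2, 1:2]
  s <- d %*% solve(b2)
  s <- s - round(s)
  d0 <- s %*% b2
  best <- rowSums(d0 * d0)
  out <- d0
  for (i in -1:1) for (j in -1:1) {
    if (i == 0 && j == 0) next
    dd <- sweep(d0, 2, i * b2[1, ] + j * b2[2, ], "+")
    r2 <- rowSums(dd * dd)
    take <- r2 < best
    if (any(take)) {
      out[take, ] <- dd[take, , drop = FALSE]
      best[take] <- r2[take]
    }
  }
  out
}

# Geometric centre of the cell.
box_center <- function(box) as.numeric(colSums(box) / 2)
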