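# Ligand-site overlap analysis: quantify lipid density inside structurally
# defined sites (e.g. an ivermectin or PIP2 pocket from a user-supplied,
# pre-aligned PDB), compare receptor states voxelwise, and measure how deep
# density penetrates the subunit-interface wedges.

#' Define a density analysis site
#'
#' Either a set of reference points (typically ligand atom positions) with an
#' inclusion radius, or a subunit-interface wedge (interface index 0-4,
#' angular half-width, leaflet).
#'
#' @param name site label.
#' @param points k x 3 matrix of reference coordinates (nm), or NULL for a
#'   wedge site.
#' @param radius inclusion radius around reference points (nm); default
#'   0.7 nm, about one coarse-grained bead contact distance.
#' @param wedge NULL, or `list(index, half_width_deg, leaflet)`.
#' @return object of class `site_definition`.
#' @export
site_definition <- function(name, points = NULL, radius = 0.7, wedge = NULL) {
  if (is.null(points) && is.null(wedge))
    stopf("site needs reference points or a wedge spec")
  stopifnot(radius > 0)
  if (!is.null(points)) {
    points <- matrix(points, ncol = 3)
    stopifnot(nrow(points) >= 1, all(is.finite(points)))
  }
  if (!is.null(wedge)) {
    stopifnot(wedge$index %in% 0:4, wedge$half_width_deg > 0,
              wedge$leaflet %in% LEAFLETS)
  }
  structure(list(name = name, points = points, radius = radius, wedge = wedge),
            class = "site_definition")
}

#' Load ligand sites from a structure
#'
#' Extracts every copy of a ligand residue from a PDB (coordinates converted
#' from Angstrom to nm) and returns one site per copy, named by residue name
#' and chain. The structure must already be registered to the trajectory
#' frame; no alignment is performed.
#'
#' @param pdb_path PDB file.
#' @param ligand_residue_name residue name of the ligand (e.g. `"IVM"`).
#' @param radius inclusion radius (nm).
#' @return list of [site_definition()] objects.
#' @export
load_site_from_structure <- function(pdb_path, ligand_residue_name, radius = 0.7) {
  pdb <- bio3d::read.pdb(pdb_path)
  a <- pdb$atom
  sel <- a$resid == ligand_residue_name
  if (!any(sel)) {
    het <- unique(a$resid[a$type == "HETATM"])
    stopf("ligand '%s' not found; available heteroresidues: %s",
          ligand_residue_name,
          if (length(het)) paste(het, collapse = ", ") else "(none)")
  }
  copies <- split(which(sel), paste(a$chain[sel], a$resno[sel]))
  lapply(copies, function(idx) {
    chain <- a$chain[idx[1]]
    site_definition(
      name = sprintf("%s_%s", ligand_residue_name,
                     if (is.na(chain) || !nzchar(chain)) a$resno[idx[1]] else chain),
      points = cbind(a$x[idx], a$y[idx], a$z[idx]) / 10,
      radius = radius)
  })
}

# Points whose whole voxel footprint lies inside the periodic cell (the
# density grid covers the cell's bounding rectangle; its corners, and voxels
# straddling the cell boundary, carry diluted or zero density and must not
# enter bulk averages).
in_cell_xy <- function(x, y, box, h) {
  binv <- solve(box[1:2, 1:2])
  s <- cbind(x, y) %*% binv
  m1 <- h * sum(abs(binv[, 1]))
  m2 <- h * sum(abs(binv[, 2]))
  s[, 1] >= m1 & s[, 1] <= 1 - m1 & s[, 2] >= m2 & s[, 2] <= 1 - m2
}

voxel_centers <- function(grid) {
  n <- dim(grid$values)
  h <- grid$voxel_size
  list(x = grid$origin[1] + (seq_len(n[1]) - 0.5) * h,
       y = grid$origin[2] + (seq_len(n[2]) - 0.5) * h,
       z = grid$origin[3] + (seq_len(n[3]) - 0.5) * h)
}

# Logical mask of voxels belonging to a site, plus the z-slab it occupies.
site_mask <- function(grid, site, axis, footprint_radius, leaflet_z, slab_half_width) {
  n <- dim(grid$values)
  vc <- voxel_centers(grid)
  X <- array(vc$x, n)
  Y <- array(rep(vc$y, each = n[1]), n)
  Z <- array(rep(vc$z, each = n[1] * n[2]), n)
  if (!is.null(site$points)) {
    mask <- array(FALSE, n)
    for (k in seq_len(nrow(site$points))) {
      p <- site$points[k, ]
      mask <- mask | ((X - p[1])^2 + (Y - p[2])^2 + (Z - p[3])^2 <= site$radius^2)
    }
    zr <- if (any(mask)) range(Z[mask]) else c(NA, NA)
  } else {
    w <- site$wedge
    zc <- axis[3] + leaflet_z[[w$leaflet]]
    ang0 <- (36 + 72 * w$index) * pi / 180
    th <- atan2(Y - axis[2], X - axis[1])
    dth <- abs(((th - ang0 + pi) %% (2 * pi)) - pi)
    r <- sqrt((X - axis[1])^2 + (Y - axis[2])^2)
    mask <- dth <= w$half_width_deg * pi / 180 & r <= footprint_radius &
      abs(Z - zc) <= slab_half_width
    zr <- c(zc - slab_half_width, zc + slab_half_width)
  }
  list(mask = mask, zrange = zr, X = X, Y = Y, Z = Z)
}

#' Density enrichment of a site
#'
#' Mean density inside the site region versus the bulk (voxels in the same
#' z-slab at in-plane radius beyond `bulk_min_radius`, by default twice the
#' protein footprint radius), plus the occupancy integral over the site
#' (in molecules, when the grid is a one-bead-per-molecule density).
#'
#' @param grid3d a `density_grid3d`.
#' @param site a [site_definition()].
#' @param axis pore-axis point (x, y, z at the membrane midplane); defaults
#'   to the grid's in-plane axis at the grid's z centre.
#' @param footprint_radius protein footprint radius (nm), used by wedge sites
#'   and the default bulk radius.
#' @param bulk_min_radius bulk region inner radius (nm); default
#'   `2 * footprint_radius`.
#' @param leaflet_z named leaflet offsets from the midplane (nm), for wedge
#'   sites.
#' @param slab_half_width half-thickness of the leaflet slab (nm).
#' @return object of class `site_report`.
#' @export
site_enrichment <- function(grid3d, site, axis = NULL, footprint_radius = 2.1,
                            bulk_min_radius = NULL,
                            leaflet_z = c(extracellular = 1.8, intracellular = -1.8),
                            slab_half_width = 1.0) {
  stopifnot(inherits(grid3d, "density_grid3d"), inherits(site, "site_definition"))
  n <- dim(grid3d$values)
  axis <- axis %||% c(grid3d$axis, grid3d$origin[3] + n[3] * grid3d$voxel_size / 2)
  bulk_min_radius <- bulk_min_radius %||% (2 * footprint_radius)
  sm <- site_mask(grid3d, site, axis, footprint_radius, leaflet_z, slab_half_width)
  if (!any(sm$mask))
    stopf("geometry error: site does not intersect the density grid")
  r <- sqrt((sm$X - axis[1])^2 + (sm$Y - axis[2])^2)
  bulk <- r >= bulk_min_radius & sm$Z >= sm$zrange[1] & sm$Z <= sm$zrange[2]
  if (!is.null(grid3d$box))
    bulk <- bulk & array(in_cell_xy(as.numeric(sm$X), as.numeric(sm$Y),
                                    grid3d$box, grid3d$voxel_size),
                         dim(grid3d$values))
  if (!any(bulk))
    stopf("geometry error: bulk region (r >= %.2f nm) is empty on this grid",
          bulk_min_radius)
  mean_site <- mean(grid3d$values[sm$mask])
  mean_bulk <- mean(grid3d$values[bulk])
  structure(list(site = site$name,
                 lipid_type = grid3d$metadata$lipid_type %||% NA,
                 state = grid3d$metadata$state %||% NA,
                 mean_site_density = mean_site,
                 bulk_density = mean_bulk,
                 enrichment = if (mean_bulk > 0) mean_site / mean_bulk else NA_real_,
                 occupancy = sum(grid3d$values[sm$mask]) * grid3d$voxel_size^3,
                 n_site_voxels = sum(sm$mask), n_bulk_voxels = sum(bulk)),
            class = "site_report")
}

#' @export
print.site_report <- function(x, ...) {
  cat(sprintf("Site '%s' (%s): mean density %.4g, bulk %.4g, enrichment %.2f, occupancy %.2f molecules\n",
              x$site, x$lipid_type, x$mean_site_density, x$bulk_density,
              x$enrichment, x$occupancy))
  invisible(x)
}

#' Voxelwise state-difference map
#'
#' `active - inactive` on commensurate grids (no silent resampling), with L1
#' difference, signed maximum and its location.
#'
#' @param grid_active,grid_inactive commensurate `density_grid3d` objects.
#' @return object of class `state_difference`: `values` (difference array),
#'   grid geometry, `l1` (integral of |difference|), `max_signed`,
#'   `max_location` (nm).
#' @export
state_difference <- function(grid_active, grid_inactive) {
  check_commensurate(grid_active, grid_inactive)
  d <- grid_active$values - grid_inactive$values
  imax <- which.max(abs(d))
  n <- dim(d)
  idx <- arrayInd(imax, n)
  h <- grid_active$voxel_size
  structure(list(values = d, origin = grid_active$origin, voxel_size = h,
                 axis = grid_active$axis,
                 l1 = sum(abs(d)) * h^3,
                 max_signed = d[imax],
                 max_location = grid_active$origin + (as.numeric(idx) - 0.5) * h,
                 metadata = list(kind = "3d", units = "difference")),
            class = c("state_difference", "density_grid3d"))
}

#' Interface penetration depth per subunit wedge
#'
#' For each of the five subunit-interface wedges (72 degrees apart, centred
#' between adjacent subunit axes), the depth to which supra-threshold density
#' penetrates toward the pore axis: `depth = R_ref - r_min`, with `r_min` the
#' smallest in-plane radius of any voxel in the wedge whose value exceeds
#' `threshold`. Wedges with no voxel above threshold report depth 0 and an
#' `empty` flag.
#'
#' @param grid3d a `density_grid3d`.
#' @param axis pore-axis point (x, y); defaults to the grid's axis.
#' @param wedge_half_width_deg angular half-width of each wedge (degrees).
#' @param threshold density threshold (grid units).
#' @param footprint_radius reference protein footprint radius `R_ref` (nm).
#' @return data.frame with columns wedge (0-4), depth_nm, r_min_nm, empty.
#' @export
interface_penetration <- function(grid3d, axis = NULL, wedge_half_width_deg = 12,
                                  threshold, footprint_radius = 2.1) {
  stopifnot(inherits(grid3d, "density_grid3d"), threshold > 0)
  axis <- axis %||% grid3d$axis
  if (!all(is.finite(axis[1:2]))) stopf("geometry error: invalid axis")
  n <- dim(grid3d$values)
  vc <- voxel_centers(grid3d)
  X <- array(vc$x, n)
  Y <- array(rep(vc$y, each = n[1]), n)
  th <- atan2(Y - axis[2], X - axis[1])
  r <- sqrt((X - axis[1])^2 + (Y - axis[2])^2)
  hot <- grid3d$values > threshold
  out <- data.frame(wedge = 0:4, depth_nm = 0, r_min_nm = NA_real_, empty = TRUE)
  for (w in 0:4) {
    ang0 <- (36 + 72 * w) * pi / 180
    dth <- abs(((th - ang0 + pi) %% (2 * pi)) - pi)
    inw <- hot & dth <= wedge_half_width_deg * pi / 180
    if (any(inw)) {
      rmin <- min(r[inw])
      out$depth_nm[w + 1] <- footprint_radius - rmin
      out$r_min_nm[w + 1] <- rmin
      out$empty[w + 1] <- FALSE
    }
  }
  out
}

#' Bulk density in a thin z-layer
#'
#' Mean density over in-cell voxels beyond `bulk_min_radius` whose centre
#' lies within `z_half` of `z_center`. Useful as a reference level when
#' thresholding density in a layer (e.g. the headgroup-anchor plane) where
#' the full-slab bulk mean would be diluted by empty z.
#'
#' @param grid3d a `density_grid3d`.
#' @param z_center layer centre (nm, absolute grid coordinates).
#' @param z_half layer half-thickness (nm).
#' @param axis pore-axis point (x, y); defaults to the grid's axis.
#' @param bulk_min_radius inner radius of the bulk region (nm).
#' @return mean density in the layer (grid units).
#' @export
bulk_layer_density <- function(grid3d, z_center, z_half = 0.3, axis = NULL,
                               bulk_min_radius = 4.2) {
  axis <- axis %||% grid3d$axis
  n <- dim(grid3d$values)
  vc <- voxel_centers(grid3d)
  X <- array(vc$x, n)
  Y <- array(rep(vc$y, each = n[1]), n)
  Z <- array(rep(vc$z, each = n[1] * n[2]), n)
  sel <- sqrt((X - axis[1])^2 + (Y - axis[2])^2) >= bulk_min_radius &
    abs(Z - z_center) <= z_half
  if (!is.null(grid3d$box))
    sel <- sel & array(in_cell_xy(as.numeric(X), as.numeric(Y),
                                  grid3d$box, grid3d$voxel_size), n)
  if (!any(sel)) stopf("geometry error: empty bulk layer")
  mean(grid3d$values[sel])
}

#' Site definition from a planted truth site
#'
#' Convenience bridge from the synthetic generator's ground truth to the site
#' analysis: reference points at the planted site centre(s) (all five C5
#' copies where replicated), at the leaflet's headgroup plane.
#'
#' @param truth_site a [planted_site()].
#' @param axis pore-axis point (x, y, z at the membrane midplane).
#' @param leaflet_z named leaflet offsets (nm).
#' @param radius inclusion radius (nm); default `2 * width` of the site.
#' @return [site_definition()].
#' @export
site_from_planted <- function(truth_site, axis,
                              leaflet_z = c(extracellular = 1.8, intracellular = -1.8),
                              radius = NULL) {
  centers <- site_centers(truth_site, axis[1:2])
  z <- axis[3] + leaflet_z[[truth_site$leaflet]]
  site_definition(name = truth_site$name,
                  points = cbind(centers, z),
                  radius = radius %||% (2 * truth_site$width))
}
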