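# Leaflet assignment and time-averaged lipid number densities (2D per-leaflet
# maps and 3D bead densities), with exact count conservation:
# sum(values) * bin_area == time-averaged molecule count, to rounding.

#' Assign every lipid molecule to a leaflet, per frame
#'
#' Per frame, the bilayer midplane is the mean z of all lipid anchor beads
#' (phosphate for phospholipids, hydroxyl for cholesterol); a lipid is
#' extracellular iff its anchor sits above the midplane. Assignments may
#' change across frames (cholesterol flip-flop).
#'
#' @param trajectory a [new_trajectory()] object.
#' @param topology matching [topology()].
#' @return object of class `leaflet_assignment`: `mol_ids`, `lipid_type`,
#'   `leaflet` (frames x molecules character matrix).
#' @export
assign_leaflets <- function(trajectory, topology) {
  anch <- lipid_anchors(topology)
  z <- trajectory$coords[, anch$bead_id, 3, drop = FALSE]
  z <- matrix(z, trajectory$n_frames, nrow(anch))
  zmid <- rowMeans(z)
  lf <- ifelse(z > zmid, "extracellular", "intracellular")
  colnames(lf) <- anch$mol_id
  structure(list(mol_ids = anch$mol_id, lipid_type = anch$lipid_type,
                 leaflet = lf),
            class = "leaflet_assignment")
}

# Regular grid spec covering the bounding rectangle (2D) or box (3D) of a
# periodic cell, so every wrapped coordinate lands in a bin. Fixing the grid
# to the cell makes grids from different repeats commensurate.
grid2d_from_box <- function(box, bin_size) {
  corners <- rbind(c(0, 0), box[1, 1:2], box[2, 1:2], box[1, 1:2] + box[2, 1:2])
  org <- apply(corners, 2, min)
  ext <- apply(corners, 2, max)
  n <- pmax(1L, as.integer(ceiling((ext - org) / bin_size - 1e-9)))
  list(origin = org, n = n)
}

grid3d_from_box <- function(box, voxel_size) {
  g2 <- grid2d_from_box(box, voxel_size)
  nz <- max(1L, as.integer(ceiling(box[3, 3] / voxel_size - 1e-9)))
  list(origin = c(g2$origin, 0), n = c(g2$n, nz))
}

bin_index <- function(x, origin, h, n) {
  pmin(pmax(floor((x - origin) / h), 0), n - 1) + 1
}

#' 2D per-leaflet lipid density map
#'
#' Each molecule of `lipid_type` assigned to `leaflet` in a frame contributes
#' one count (at its anchor bead's x,y) to the bin containing it; values are
#' `counts / (n_frames * bin_area)`, i.e. time-averaged molecules per nm^2.
#' The integral of the grid equals the time-averaged molecule count of that
#' type in that leaflet exactly.
#'
#' @param trajectory windowed [new_trajectory()].
#' @param topology matching [topology()].
#' @param assignment [assign_leaflets()] result.
#' @param lipid_type,leaflet selection.
#' @param bin_size bin edge (nm).
#' @param axis pore-axis point (x, y); defaults to the box centre.
#' @return object of class `density_grid2d`.
#' @export
density2d <- function(trajectory, topology, assignment, lipid_type, leaflet,
                      bin_size = 0.2, axis = NULL) {
  stopifnot(inherits(assignment, "leaflet_assignment"), bin_size > 0)
  sel_mol <- which(assignment$lipid_type == lipid_type)
  if (!length(sel_mol))
    stopf("empty selection: no molecules of lipid type '%s' in topology", lipid_type)
  anch <- lipid_anchors(topology)
  beads <- anch$bead_id[sel_mol]
  box <- frame_box(trajectory, 1)
  g <- grid2d_from_box(box, bin_size)
  counts <- numeric(prod(g$n))
  total <- 0
  for (f in seq_len(trajectory$n_frames)) {
    here <- assignment$leaflet[f, sel_mol] == leaflet
    if (!any(here)) next
    xy <- wrap_points(matrix(trajectory$coords[f, beads[here], ], ncol = 3),
                      box)[, 1:2, drop = FALSE]
    ix <- bin_index(xy[, 1], g$origin[1], bin_size, g$n[1])
    iy <- bin_index(xy[, 2], g$origin[2], bin_size, g$n[2])
    lin <- ix + (iy - 1) * g$n[1]
    counts <- counts + tabulate(lin, nbins = prod(g$n))
    total <- total + sum(here)
  }
  if (total == 0)
    stopf("empty selection: lipid type '%s' never occupies leaflet '%s'",
          lipid_type, leaflet)
  values <- matrix(counts / (trajectory$n_frames * bin_size^2), g$n[1], g$n[2])
  structure(list(origin = g$origin, bin_size = bin_size, values = values,
                 box = box,
                 axis = axis %||% box_center(box)[1:2],
                 metadata = list(kind = "2d", lipid_type = lipid_type,
                                 leaflet = leaflet,
                                 n_frames = trajectory$n_frames,
                                 units = "molecules/nm^2",
                                 anchor_convention = "one anchor bead per molecule")),
            class = "density_grid2d")
}

#' 3D lipid bead density
#'
#' Beads of `lipid_type` matching `role_selector` are binned per frame;
#' values are `counts / (n_frames * voxel_volume)`. When the selector picks
#' exactly one bead per molecule the units are molecules/nm^3; otherwise this
#' is a bead density and the `beads_per_molecule` metadata flag records the
#' normalization.
#'
#' @param trajectory windowed [new_trajectory()].
#' @param topology matching [topology()].
#' @param lipid_type lipid type to select.
#' @param role_selector one of `"any"`, `"cationic-headgroup"`, `"phosphate"`,
#'   `"hydroxyl"`, `"tail"`.
#' @param voxel_size voxel edge (nm).
#' @param axis pore-axis point (x, y); defaults to the box centre.
#' @return object of class `density_grid3d`.
#' @export
density3d <- function(trajectory, topology, lipid_type, role_selector = "any",
                      voxel_size = 0.1, axis = NULL) {
  stopifnot(voxel_size > 0)
  if (!role_selector %in% c("any", "cationic-headgroup", "phosphate", "hydroxyl", "tail"))
    stopf("selection error: unknown bead role selector '%s'", role_selector)
  sel <- topology$mol_class == "lipid" & topology$lipid_type == lipid_type
  if (role_selector != "any") sel <- sel & topology$role == role_selector
  beads <- which(sel)
  if (!length(beads))
    stopf("empty selection: no '%s' beads with role '%s'", lipid_type, role_selector)
  n_mol <- length(unique(topology$mol_id[beads]))
  bpm <- length(beads) / n_mol
  box <- frame_box(trajectory, 1)
  g <- grid3d_from_box(box, voxel_size)
  counts <- numeric(prod(g$n))
  for (f in seq_len(trajectory$n_frames)) {
    xyz <- wrap_points(matrix(trajectory$coords[f, beads, ], ncol = 3), box)
    ix <- bin_index(xyz[, 1], g$origin[1], voxel_size, g$n[1])
    iy <- bin_index(xyz[, 2], g$origin[2], voxel_size, g$n[2])
    iz <- bin_index(xyz[, 3], g$origin[3], voxel_size, g$n[3])
    lin <- ix + (iy - 1) * g$n[1] + (iz - 1) * g$n[1] * g$n[2]
    counts <- counts + tabulate(lin, nbins = prod(g$n))
  }
  values <- array(counts / (trajectory$n_frames * voxel_size^3), g$n)
  structure(list(origin = g$origin, voxel_size = voxel_size, values = values,
                 box = box,
                 axis = axis %||% box_center(box)[1:2],
                 metadata = list(kind = "3d", lipid_type = lipid_type,
                                 role_selector = role_selector,
                                 n_frames = trajectory$n_frames,
                                 beads_per_molecule = bpm,
                                 units = if (abs(bpm - 1) < 1e-12)
                                   "molecules/nm^3" else "beads/nm^3")),
            class = "density_grid3d")
}

#' Integral of a density grid
#'
#' `sum(values) * bin_area` (2D) or `* voxel_volume` (3D): the time-averaged
#' selected count.
#'
#' @param grid a density grid.
#' @return scalar.
#' @export
grid_integral <- function(grid) {
  if (inherits(grid, "density_grid2d")) sum(grid$values) * grid$bin_size^2
  else if (inherits(grid, "density_grid3d")) sum(grid$values) * grid$voxel_size^3
  else stopf("not a density grid")
}

#' Average commensurate density grids
#'
#' Arithmetic mean of per-repeat grids computed on identical grids/origins
#' (used for repeat averaging).
#'
#' @param grids list of density grids with identical origin/spacing/dims.
#' @return density grid of the same class.
#' @export
average_grids <- function(grids) {
  stopifnot(length(grids) >= 1)
  g0 <- grids[[1]]
  for (g in grids[-1]) check_commensurate(g0, g)
  out <- g0
  vals <- Reduce(`+`, lapply(grids, `[[`, "values"))
  out$values <- vals / length(grids)
  out$metadata$n_repeats <- length(grids)
  attr(out, "polar_rep") <- NULL
  out
}

check_commensurate <- function(a, b) {
  ha <- a$bin_size %||% a$voxel_size
  hb <- b$bin_size %||% b$voxel_size
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$origin - b$origin)) > 1e-9 || abs(ha - hb) > 1e-12)
    stopf("commensurability error: grids differ in origin, spacing or shape")
  invisible(TRUE)
}

#' Equal-composition isovalue reweighting
#'
#' Rescales a reference isovalue so that displaying each lipid type's density
#' at its own rescaled isovalue shows them as if the membrane consisted of
#' equal amounts of each type: `reference_iso * fraction / (1 / n_types)`.
#'
#' @param reference_iso reference isovalue (molecules/nm^3).
#' @param fraction the lipid type's mole fraction.
#' @param n_types number of lipid types in the membrane.
#' @return rescaled isovalue (molecules/nm^3).
#' @examples
#' equal_composition_isovalue(5, 0.4, 5)    # 10
#' equal_composition_isovalue(6.7, 0.448, 5)  # ~15, cholesterol at Table-1 abundance
#' @export
equal_composition_isovalue <- function(reference_iso, fraction, n_types) {
  if (n_types < 1) stopf("domain error: n_types must be >= 1")
  stopifnot(fraction >= 0, fraction <= 1)
  reference_iso * fraction * n_types
}
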