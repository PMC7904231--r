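# Membrane builder: place lipids uniformly at random in each leaflet plane of
# a periodic cell, outside the protein footprint, with minimum in-plane
# spacing, and emit an annotated topology plus starting coordinates.

# Rigid per-molecule bead layouts. Offsets are along the leaflet normal,
# positive = away from the bilayer midplane (sign is flipped for the
# intracellular leaflet). Anchor beads (phosphate / hydroxyl) sit at offset 0.
lipid_bead_template <- function(type) {
  switch(type,
    POPC = data.frame(bead_name = c("NC3", "PO4", "C1A", "C2A"),
                      dz = c(0.3, 0, -0.5, -0.9)),
    POPE = data.frame(bead_name = c("NH3", "PO4", "C1A", "C2A"),
                      dz = c(0.3, 0, -0.5, -0.9)),
    DOPS = data.frame(bead_name = c("CNO", "PO4", "C1A", "C2A"),
                      dz = c(0.3, 0, -0.5, -0.9)),
    SM   = data.frame(bead_name = c("NC3", "PO4", "C1A", "C2A"),
                      dz = c(0.3, 0, -0.5, -0.9)),
    CHOL = data.frame(bead_name = c("ROH", "R1", "C1"),
                      dz = c(0, -0.4, -0.8)),
    stopf("no bead template for lipid type '%s'", type))
}

lipid_resname <- function(type) c(POPC = "POPC", POPE = "POPE", DOPS = "DOPS",
                                  SM = "DPSM", CHOL = "CHOL")[[type]]

#' Build membrane system around a (possibly absent) pentamer
#'
#' Lipids are placed uniformly at random in their leaflet's plane, excluding a
#' disc around the protein and respecting a minimum in-plane spacing, with
#' headgroup z drawn as `leaflet_z + N(0, headgroup_noise_sd)`. Counts per
#' lipid type come from [apportion_counts()] applied to the spec's per-leaflet
#' mole percents. Placement is reproducible from `seed`.
#'
#' @param spec [membrane_spec()] composition.
#' @param pentamer [build_pentamer()] model, or NULL for a protein-free bilayer.
#' @param box 3x3 lattice-vector matrix (see [hexagonal_box()]).
#' @param seed integer seed controlling placement.
#' @param min_spacing minimum in-plane distance between lipid anchors (nm).
#' @param exclusion_margin added to the protein footprint radius to form the
#'   lipid-free disc at build time (nm).
#' @param max_tries_per_lipid bounded rejection-sampling budget.
#' @return object of class `membrane_system`: `topology`, `coords`
#'   (beads x 3 nm), `box`, `lipids` (per-molecule table: mol_id, lipid_type,
#'   leaflet, anchor x/y/z-noise), `pentamer`, `spec`.
#' @examples
#' sys <- build_membrane(neuronal_membrane_spec(nominal_per_leaflet = 20),
#'                       pentamer = NULL, box = hexagonal_box(12), seed = 1)
#' sys$topology
#' @export
build_membrane <- function(spec, pentamer = NULL, box = hexagonal_box(12),
                           seed = 1, min_spacing = 0.45,
                           exclusion_margin = 0.3,
                           max_tries_per_lipid = 200) {
  stopifnot(inherits(spec, "membrane_spec"))
  check_box(box)
  center <- box_center(box)
  r_excl <- if (is.null(pentamer)) 0 else pentamer$footprint_radius + exclusion_margin

  place_leaflet <- function(n, leaflet) {
    pts <- matrix(NA_real_, n, 2)
    placed <- 0L
    tries <- 0L
    budget <- max_tries_per_lipid * n
    while (placed < n) {
      if (tries >= budget)
        stopf("packing error: could not place %d lipids in leaflet '%s' at %.2f nm spacing",
              n, leaflet, min_spacing)
      tries <- tries + 1L
      s <- stats::runif(2)
      xy <- as.numeric(s %*% box[1:2, 1:2])
      rel <- xy - center[1:2]
      if (r_excl > 0 && sqrt(min(min_image_dist2_xy(matrix(rel, 1), box))) < r_excl) next
      if (placed > 0L) {
        d2 <- min_image_dist2_xy(sweep(pts[seq_len(placed), , drop = FALSE], 2, xy, "-"), box)
        if (min(d2) < min_spacing^2) next
      }
      placed <- placed + 1L
      pts[placed, ] <- xy
    }
    pts
  }

  build <- function() {
    prot_rows <- pentamer_topology_rows(pentamer)
    prot_coords <- if (is.null(pentamer)) NULL else
      sweep(pentamer$coords, 2, center, "+")
    n_prot_beads <- if (is.null(prot_rows)) 0L else nrow(prot_rows)
    n_prot_mols <- if (is.null(prot_rows)) 0L else max(prot_rows$mol_id)

    lip_rows <- list()
    lip_coords <- list()
    lip_tab <- list()
    bead_id <- n_prot_beads
    mol_id <- n_prot_mols
    resid0 <- if (is.null(prot_rows)) 0L else max(prot_rows$resid)

    for (lf in LEAFLETS) {
      counts <- apportion_counts(spec$per_leaflet_percent[[lf]], spec$nominal_per_leaflet)
      counts <- counts[counts > 0]
      n <- sum(counts)
      if (n == 0L) next
      xy <- place_leaflet(n, lf)
      types <- rep(names(counts), counts)
      znoise <- stats::rnorm(n, 0, spec$headgroup_noise_sd)
      zsign <- if (lf == "extracellular") 1 else -1
      for (i in seq_len(n)) {
        mol_id <- mol_id + 1L
        tmpl <- lipid_bead_template(types[i])
        nb <- nrow(tmpl)
        z_anchor <- center[3] + spec$leaflet_z[[lf]] + znoise[i]
        lip_rows[[length(lip_rows) + 1L]] <- data.frame(
          bead_id = bead_id + seq_len(nb),
          bead_name = tmpl$bead_name,
          mol_id = mol_id,
          mol_class = "lipid",
          lipid_type = types[i],
          resid = resid0 + (mol_id - n_prot_mols),
          resname = lipid_resname(types[i]),
          subunit = NA_character_,
          role = bead_role_from_name(tmpl$bead_name, default_naming_config()),
          stringsAsFactors = FALSE)
        lip_coords[[length(lip_coords) + 1L]] <- cbind(
          rep(xy[i, 1], nb), rep(xy[i, 2], nb), z_anchor + zsign * tmpl$dz)
        lip_tab[[length(lip_tab) + 1L]] <- data.frame(
          mol_id = mol_id, lipid_type = types[i], leaflet = lf,
          x = xy[i, 1], y = xy[i, 2], z_noise = znoise[i],
          stringsAsFactors = FALSE)
        bead_id <- bead_id + nb
      }
    }

    top <- topology(rbind(prot_rows, do.call(rbind, lip_rows)))
    coords <- rbind(prot_coords, do.call(rbind, lip_coords))
    rownames(coords) <- NULL
    structure(list(topology = top, coords = coords, box = box,
                   lipids = do.call(rbind, lip_tab),
                   pentamer = pentamer, spec = spec, seed = seed),
              class = "membrane_system")
  }

  with_private_seed(seed, build())
}

#' @export
print.membrane_system <- function(x, ...) {
  cat(sprintf("Membrane system: %d beads, %d lipid molecules (%s)\n",
              nrow(x$coords), nrow(x$lipids),
              paste(names(table(x$lipids$lipid_type)), collapse = "/")))
  invisible(x)
}
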