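# Toy C5-symmetric pentameric inclusion. Five identical subunits (A..E),
# each a bundle of four vertical pseudo-helices standing in for the
# transmembrane helices of a pentameric ligand-gated ion channel:
# an inner pore-lining helix, two middle helices and an outer lipid-facing
# helix. Held static throughout the toy dynamics, mirroring the
# position-restrained protein of the reference workflow.

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), nrow = 3)
}

#' Build a C5-symmetric toy pentamer
#'
#' Each subunit contains four vertical pseudo-helices placed on three
#' concentric rings around the pore axis: the inner helix (pore-lining, "M2"),
#' two middle helices ("M1", "M3") flanking it in angle, and the outer
#' lipid-facing helix ("M4"). Subunit k is the first subunit rotated by
#' k * 72 degrees about the pore axis, so the model is exactly C5-symmetric
#' and residue indexing is identical across subunits. Angular gaps between
#' adjacent subunits leave lipid-accessible crevices at the five
#' subunit interfaces (centred 36 degrees off each subunit axis).
#'
#' @param n_res_per_helix beads (= residues) per pseudo-helix.
#' @param helix_radius named numeric: ring radius (nm) for M1, M2, M3, M4.
#' @param helix_angle_deg named numeric: angular offset (degrees) of each helix
#'   from the subunit axis.
#' @param z_span total vertical extent of the helices (nm), centred on z = 0.
#' @param sidechain_radius radial position (nm) of the lipid-facing sidechain
#'   beads carried by every outer-helix residue (the toy analogue of M4
#'   sidechains pointing into the membrane); NULL disables them.
#' @return object of class `pentamer_model`: fields `coords` (n x 3 nm,
#'   axis through the origin along +z), `info` (per-bead resid/resname/
#'   subunit/helix/ring/bead_name), `axis` (point + unit direction),
#'   `footprint_radius` (nm).
#' @examples
#' p <- build_pentamer()
#' p$footprint_radius
#' @export
build_pentamer <- function(n_res_per_helix = 8,
                           helix_radius = c(M1 = 1.5, M2 = 0.9, M3 = 1.5, M4 = 2.1),
                           helix_angle_deg = c(M1 = 20, M2 = 0, M3 = -20, M4 = 0),
                           z_span = 2.8, sidechain_radius = 2.35) {
  stopifnot(n_res_per_helix >= 2, z_span > 0)
  helices <- c("M1", "M2", "M3", "M4")
  rings <- c(M1 = "middle", M2 = "inner", M3 = "middle", M4 = "outer")
  zs <- seq(-z_span / 2, z_span / 2, length.out = n_res_per_helix)
  resnames <- c("ALA", "LEU", "VAL", "ILE", "PHE", "SER", "THR", "GLY")

  sub_coords <- NULL
  sub_info <- NULL
  resid <- 0L
  for (h in helices) {
    # M2 sits at a slightly different radius than M4 on purpose: the outer
    # ring shields the inner one except at the subunit interfaces.
    th <- helix_angle_deg[[h]] * pi / 180
    r <- helix_radius[[h]]
    xy <- c(r * cos(th), r * sin(th))
    for (i in seq_len(n_res_per_helix)) {
      resid <- resid + 1L
      resname <- resnames[(resid - 1L) %% length(resnames) + 1L]
      sub_coords <- rbind(sub_coords, c(xy, zs[i]))
      sub_info <- rbind(sub_info, data.frame(
        resid = resid, resname = resname, helix = h, ring = rings[[h]],
        bead_name = "BB", stringsAsFactors = FALSE))
      if (h == "M4" && !is.null(sidechain_radius)) {
        # lipid-facing sidechain bead of the outer-helix residue
        sub_coords <- rbind(sub_coords,
                            c(sidechain_radius * cos(th),
                              sidechain_radius * sin(th), zs[i]))
        sub_info <- rbind(sub_info, data.frame(
          resid = resid, resname = resname, helix = h, ring = rings[[h]],
          bead_name = "SC1", stringsAsFactors = FALSE))
      }
    }
  }

  coords <- NULL
  info <- NULL
  for (k in 0:4) {
    R <- rot_z(2 * pi * k / 5)
    coords <- rbind(coords, sub_coords %*% t(R))
    si <- sub_info
    si$subunit <- LETTERS[k + 1]
    info <- rbind(info, si)
  }
  structure(list(coords = coords,
                 info = info,
                 axis = list(point = c(0, 0, 0), direction = c(0, 0, 1)),
                 footprint_radius = max(sqrt(rowSums(coords[, 1:2]^2)))),
            class = "pentamer_model")
}

#' @export
print.pentamer_model <- function(x, ...) {
  cat(sprintf("C5 pentamer: %d beads, %d residues/subunit, footprint radius %.2f nm\n",
              nrow(x$coords), max(x$info$resid), x$footprint_radius))
  invisible(x)
}

# Topology rows for the pentamer beads (bead ids 1..n, one protein molecule
# per subunit).
pentamer_topology_rows <- function(pent) {
  if (is.null(pent)) return(NULL)
  n <- nrow(pent$coords)
  data.frame(bead_id = seq_len(n),
             bead_name = pent$info$bead_name,
             mol_id = match(pent$info$subunit, LETTERS[1:5]),
             mol_class = "protein",
             lipid_type = NA_character_,
             resid = pent$info$resid,
             resname = pent$info$resname,
             subunit = pent$info$subunit,
             role = ifelse(pent$info$bead_name == "BB", "backbone", "sidechain"),
             stringsAsFactors = FALSE)
}
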