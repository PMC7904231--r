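# Trajectory container and window/geometry operations.

#' Construct a trajectory
#'
#' @param times frame times (ns), strictly increasing.
#' @param coords array `n_frames x n_beads x 3` of coordinates (nm).
#' @param box either a single 3x3 lattice-vector matrix (constant cell) or an
#'   array `n_frames x 3 x 3`.
#' @return object of class `trajectory`.
#' @export
new_trajectory <- function(times, coords, box) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n_frames <- dim(coords)[1]
  if (length(times) != n_frames) stopf("times length must equal frame count")
  if (n_frames > 1 && any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (!all(is.finite(coords))) stopf("coordinates must be finite")
  if (is.matrix(box)) {
    check_box(box)
    boxes <- array(rep(t(box), n_frames), c(3, 3, n_frames))
    boxes <- aperm(boxes, c(3, 2, 1))
    for (f in seq_len(n_frames)) boxes[f, , ] <- box
  } else {
    stopifnot(length(dim(box)) == 3, all(dim(box)[2:3] == 3), dim(box)[1] == n_frames)
    boxes <- box
    for (f in seq_len(n_frames)) check_box(matrix(boxes[f, , ], 3, 3))
  }
  structure(list(times = as.numeric(times), coords = coords, box = boxes,
                 n_frames = n_frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d beads, t = %.1f..%.1f ns\n",
              x$n_frames, dim(x$coords)[2], x$times[1], x$times[x$n_frames]))
  invisible(x)
}

frame_box <- function(traj, f = 1) matrix(traj$box[f, , ], 3, 3)
frame_coords <- function(traj, f) matrix(traj$coords[f, , ], ncol = 3)

#' Analysis window specification
#'
#' The analysis convention: keep the last `last_fraction` of the trajectory
#' (frames with time strictly greater than `(1 - last_fraction) * T_end`,
#' half-open, so a frame exactly at the boundary is excluded), then subsample
#' to a spacing of `stride_dt` starting from the first kept frame.
#'
#' @param last_fraction fraction of the trajectory (by time) to keep, in (0, 1].
#' @param stride_dt frame spacing after subsampling (ns).
#' @return object of class `analysis_window`.
#' @export
analysis_window <- function(last_fraction = 0.5, stride_dt = 10) {
  stopifnot(last_fraction > 0, last_fraction <= 1, stride_dt > 0)
  structure(list(last_fraction = last_fraction, stride_dt = stride_dt),
            class = "analysis_window")
}

#' Select the analysis window of a trajectory
#'
#' @param trajectory a [new_trajectory()] object.
#' @param window an [analysis_window()].
#' @return windowed `trajectory`.
#' @examples
#' # 40 us at 10 ns spacing, keep the last half at 10 ns stride: 2000 frames
#' tr <- new_trajectory(seq(0, 40000, by = 10),
#'                      array(0, c(4001, 1, 3)), hexagonal_box(10))
#' select_window(tr, analysis_window(0.5, 10))$n_frames
#' @export
select_window <- function(trajectory, window) {
  stopifnot(inherits(trajectory, "trajectory"), inherits(window, "analysis_window"))
  if (trajectory$n_frames == 0) stopf("empty trajectory")
  times <- trajectory$times
  native <- if (length(times) > 1) min(diff(times)) else Inf
  tol <- 1e-9 * max(1, abs(times[length(times)]))
  if (window$stride_dt < native - tol)
    stopf("resolution error: stride_dt %.3f ns finer than native frame spacing %.3f ns",
          window$stride_dt, native)
  cut <- if (window$last_fraction >= 1) -Inf
         else (1 - window$last_fraction) * times[length(times)]
  kept <- which(times > cut + tol)
  if (!length(kept)) stopf("window selects no frames")
  sel <- kept[1]
  t_next <- times[kept[1]] + window$stride_dt
  for (i in kept[-1]) {
    if (times[i] >= t_next - tol) {
      sel <- c(sel, i)
      t_next <- times[i] + window$stride_dt
    }
  }
  out <- new_trajectory(times = times[sel],
                        coords = trajectory$coords[sel, , , drop = FALSE],
                        box = trajectory$box[sel, , , drop = FALSE])
  for (a in c("leaflet_record", "truth"))
    if (!is.null(attr(trajectory, a))) {
      v <- attr(trajectory, a)
      attr(out, a) <- if (a == "leaflet_record") v[sel, , drop = FALSE] else v
    }
  out
}

#' Centre each frame on the protein centroid
#'
#' Translates every frame so the protein-bead centroid sits at the box centre
#' (valid because the protein is positionally restrained: no rotation is ever
#' applied), then re-wraps lipid molecules whole into the primitive cell.
#' Protein beads are translated but never wrapped.
#'
#' @param trajectory a [new_trajectory()] object.
#' @param topology matching [topology()].
#' @return centred `trajectory`.
#' @export
center_on_protein <- function(trajectory, topology) {
  pro <- which(topology$mol_class == "protein")
  if (!length(pro)) stopf("selection error: topology contains no protein beads")
  lip_mols <- split(which(topology$mol_class == "lipid"),
                    topology$mol_id[topology$mol_class == "lipid"])
  coords <- trajectory$coords
  for (f in seq_len(trajectory$n_frames)) {
    box <- frame_box(trajectory, f)
    x <- frame_coords(trajectory, f)
    shift <- box_center(box) - colMeans(x[pro, , drop = FALSE])
    x <- sweep(x, 2, shift, "+")
    for (beads in lip_mols) {
      cen <- colMeans(x[beads, , drop = FALSE])
      wcen <- wrap_points(matrix(cen, 1), box)
      x[beads, ] <- sweep(x[beads, , drop = FALSE], 2, as.numeric(wcen - cen), "+")
    }
    coords[f, , ] <- x
  }
  out <- trajectory
  out$coords <- coords
  out
}

#' Read a system (topology + trajectory) from standard files
#'
#' @param coordinate_path GRO or PDB file supplying topology and coordinates.
#' @param trajectory_path optional DCD file; when NULL, a single-frame
#'   trajectory is built from the coordinate file.
#' @param naming_config residue/bead naming map (see
#'   [default_naming_config()]); unmatched residue names are classified
#'   `"other"` with a warning.
#' @return list with elements `topology` and `trajectory`.
#' @export
read_system <- function(coordinate_path, trajectory_path = NULL,
                        naming_config = default_naming_config()) {
  ext <- tolower(tools::file_ext(coordinate_path))
  parsed <- switch(ext,
    gro = read_gro(coordinate_path),
    pdb = read_pdb_system(coordinate_path),
    stopf("unsupported coordinate format '%s' (use GRO or PDB)", ext))
  top <- annotate_topology(parsed$atoms, naming_config)
  if (is.null(trajectory_path)) {
    traj <- new_trajectory(times = 0,
                           coords = array(parsed$coords, c(1, nrow(parsed$coords), 3)),
                           box = parsed$box)
  } else {
    traj <- read_dcd_trajectory(trajectory_path)
    if (dim(traj$coords)[2] != nrow(top))
      stopf("structural mismatch: coordinate file has %d beads, trajectory %d",
            nrow(top), dim(traj$coords)[2])
  }
  list(topology = top, trajectory = traj)
}

# Turn raw parsed atoms (bead_name, resid, resname, chain) into an annotated
# topology: lipid residues become one molecule each, protein chains one
# molecule per chain (subunit).
annotate_topology <- function(atoms, cfg) {
  n <- nrow(atoms)
  lipid_type <- unname(cfg$resname_to_lipid[atoms$resname])
  is_lipid <- !is.na(lipid_type)
  is_water <- atoms$resname %in% c("W", "WN", "ION", "NA", "CL", "HOH", "SOL")
  is_protein <- !is_lipid & !is_water &
    (atoms$bead_name == "BB" | grepl("^SC", atoms$bead_name))
  mol_class <- ifelse(is_lipid, "lipid",
                      ifelse(is_protein, "protein",
                             ifelse(is_water, "solvent", "other")))
  unknown <- unique(atoms$resname[mol_class == "other"])
  if (length(unknown))
    warnf("unmatched residue name(s) classified 'other': %s",
          paste(unknown, collapse = ", "))

  subunit <- ifelse(mol_class == "protein",
                    ifelse(is.na(atoms$chain) | !nzchar(atoms$chain),
                           LETTERS[1 + (atoms$resid - 1) %/% 1000],
                           atoms$chain),
                    NA_character_)
  mol_key <- ifelse(mol_class == "protein", paste0("P", subunit),
                    paste0("M", cumsum(c(TRUE, diff(atoms$resid) != 0 |
                                           atoms$resname[-1] != atoms$resname[-n]))))
  topology(data.frame(
    bead_id = seq_len(n),
    bead_name = atoms$bead_name,
    mol_id = as.integer(factor(mol_key, levels = unique(mol_key))),
    mol_class = mol_class,
    lipid_type = lipid_type,
    resid = as.integer(ifelse(mol_class == "protein",
                              1 + (atoms$resid - 1) %% 1000, atoms$resid)),
    resname = atoms$resname,
    subunit = subunit,
    role = bead_role_from_name(atoms$bead_name, cfg),
    stringsAsFactors = FALSE))
}

#' Write a system to GRO (+ optional DCD trajectory)
#'
#' @param topology [topology()] object.
#' @param trajectory [new_trajectory()] object (first frame goes to the GRO).
#' @param coordinate_path output GRO path.
#' @param trajectory_path optional output DCD path for all frames.
#' @export
write_system <- function(topology, trajectory, coordinate_path,
                         trajectory_path = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (trajectory$n_frames < 1) stopf("refusing to write an empty trajectory")
  if (dim(trajectory$coords)[2] != nrow(topology))
    stopf("structural mismatch: topology has %d beads, trajectory %d",
          nrow(topology), dim(trajectory$coords)[2])
  write_gro(topology, frame_coords(trajectory, 1), frame_box(trajectory, 1),
            coordinate_path)
  if (!is.null(trajectory_path)) write_dcd_trajectory(trajectory, trajectory_path)
  invisible(coordinate_path)
}
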