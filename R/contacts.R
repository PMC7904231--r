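# Per-residue protein-lipid contact analysis: boolean contact series at a
# distance cutoff (default 0.6 nm, the first lipid shell), continuous
# contact durations, pooled contact tables with repeat/subunit averaging,
# lipid hierarchy ranking, and B-factor export.

# Reduced minimum-image displacement between two point sets (all pairs),
# exact whenever the true minimum-image separation is well below half the
# cell (the regime enforced by the cutoff precondition). Returns squared
# distances as an |A| x |B| matrix.
pair_dist2_min_image <- function(A, B, box, binv = solve(box)) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  s1 <- dx * binv[1, 1] + dy * binv[2, 1] + dz * binv[3, 1]
  s2 <- dx * binv[1, 2] + dy * binv[2, 2] + dz * binv[3, 2]
  s3 <- dx * binv[1, 3] + dy * binv[2, 3] + dz * binv[3, 3]
  s1 <- s1 - round(s1); s2 <- s2 - round(s2); s3 <- s3 - round(s3)
  rx <- s1 * box[1, 1] + s2 * box[2, 1] + s3 * box[3, 1]
  ry <- s1 * box[1, 2] + s2 * box[2, 2] + s3 * box[3, 2]
  rz <- s1 * box[1, 3] + s2 * box[2, 3] + s3 * box[3, 3]
  rx * rx + ry * ry + rz * rz
}

#' Protein-lipid contact series
#'
#' A residue and a lipid molecule are in contact at a frame iff the minimum
#' over all (residue bead, lipid bead) pairs of the minimum-image distance is
#' at most `cutoff` (any-bead/any-bead convention). The default method prunes
#' pairs with a bounding-sphere test on residue/molecule centroids before the
#' exact any-bead check; `method = "brute"` is the plain all-pairs scan kept
#' as an oracle (both give identical results).
#'
#' @param trajectory windowed [new_trajectory()].
#' @param topology matching [topology()].
#' @param cutoff contact distance (nm), default 0.6.
#' @param method `"pruned"` (default) or `"brute"`.
#' @return object of class `contact_series`: `pairs` (resid, subunit,
#'   lipid_type, mol_id for every pair with at least one contact frame),
#'   `mat` (pairs x frames logical), `times`, `dt`, `cutoff`, plus the full
#'   residue/lipid inventory for downstream tables.
#' @export
contact_series <- function(trajectory, topology, cutoff = 0.6,
                           method = c("pruned", "brute")) {
  method <- match.arg(method)
  stopifnot(cutoff > 0)
  box <- frame_box(trajectory, 1)
  if (cutoff >= min(sqrt(rowSums(box^2))) / 2)
    stopf("geometry error: cutoff must be below half the shortest box vector")
  pro <- which(topology$mol_class == "protein")
  lip <- which(topology$mol_class == "lipid")
  if (!length(pro) || !length(lip))
    stopf("topology must contain protein and lipid beads")

  res_key <- paste(topology$subunit[pro], topology$resid[pro], sep = ":")
  res_groups <- split(pro, factor(res_key, levels = unique(res_key)))
  res_info <- data.frame(
    subunit = topology$subunit[vapply(res_groups, `[`, 0L, 1)],
    resid = topology$resid[vapply(res_groups, `[`, 0L, 1)],
    stringsAsFactors = FALSE)
  mol_groups <- split(lip, factor(topology$mol_id[lip],
                                  levels = unique(topology$mol_id[lip])))
  mol_info <- data.frame(
    mol_id = as.integer(names(mol_groups)),
    lipid_type = topology$lipid_type[vapply(mol_groups, `[`, 0L, 1)],
    stringsAsFactors = FALSE)
  nR <- length(res_groups); nM <- length(mol_groups)
  n_frames <- trajectory$n_frames
  cut2 <- cutoff^2
  binv <- solve(box)
  Ri <- match(res_key, names(res_groups))
  Mi <- match(topology$mol_id[lip], mol_info$mol_id)

  contact_frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    x <- frame_coords(trajectory, f)
    hit <- matrix(FALSE, nR, nM)
    if (method == "brute") {
      d2 <- pair_dist2_min_image(x[pro, , drop = FALSE], x[lip, , drop = FALSE],
                                 box, binv)
      close <- d2 <= cut2
      if (any(close)) {
        idx <- which(close, arr.ind = TRUE)
        hit[cbind(Ri[idx[, 1]], Mi[idx[, 2]])] <- TRUE
      }
    } else {
      resC <- t(vapply(res_groups, function(b) colMeans(x[b, , drop = FALSE]), numeric(3)))
      resR <- vapply(seq_len(nR), function(i)
        sqrt(max(rowSums(sweep(x[res_groups[[i]], , drop = FALSE], 2, resC[i, ])^2))), 0)
      molC <- t(vapply(mol_groups, function(b) colMeans(x[b, , drop = FALSE]), numeric(3)))
      molR <- vapply(seq_len(nM), function(i)
        sqrt(max(rowSums(sweep(x[mol_groups[[i]], , drop = FALSE], 2, molC[i, ])^2))), 0)
      d2 <- pair_dist2_min_image(resC, molC, box, binv)
      thr <- outer(resR, molR, "+") + cutoff
      cand <- which(d2 <= thr^2, arr.ind = TRUE)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        dd <- pair_dist2_min_image(x[res_groups[[i]], , drop = FALSE],
                                   x[mol_groups[[j]], , drop = FALSE], box, binv)
        if (min(dd) <= cut2) hit[i, j] <- TRUE
      }
    }
    contact_frames[[f]] <- which(hit)
  }

  pair_ids <- sort(unique(unlist(contact_frames)))
  mat <- matrix(FALSE, length(pair_ids), n_frames)
  for (f in seq_len(n_frames))
    mat[match(contact_frames[[f]], pair_ids), f] <- TRUE
  pi_res <- ((pair_ids - 1) %% nR) + 1
  pi_mol <- ((pair_ids - 1) %/% nR) + 1
  structure(list(
    pairs = data.frame(resid = res_info$resid[pi_res],
                       subunit = res_info$subunit[pi_res],
                       mol_id = mol_info$mol_id[pi_mol],
                       lipid_type = mol_info$lipid_type[pi_mol],
                       stringsAsFactors = FALSE),
    mat = mat,
    times = trajectory$times,
    dt = if (n_frames > 1) diff(trajectory$times)[1] else NA_real_,
    cutoff = cutoff,
    residues = res_info,
    lipid_types = sort(unique(mol_info$lipid_type)),
    n_frames = n_frames),
    class = "contact_series")
}

#' Continuous contact durations from a boolean series
#'
#' Maximal runs of consecutive TRUE frames; duration = run length x `dt`.
#' Runs touching either end of the window are included at their observed
#' length (no censoring correction).
#'
#' @param series logical vector over frames.
#' @param dt frame spacing (ns).
#' @return numeric vector of durations (ns); empty for an all-FALSE series.
#' @examples
#' durations_from_series(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE), dt = 10)
#' @export
durations_from_series <- function(series, dt) {
  stopifnot(dt > 0)
  if (!length(series)) return(numeric(0))
  r <- rle(as.logical(series))
  r$lengths[r$values] * dt
}

#' Per-residue contact-duration table
#'
#' For each (residue, lipid type), pools all continuous-contact event
#' durations across that type's molecules and across repeats, and reports
#' the pooled mean (the default; a per-molecule mean-of-means is available
#' via `average = "per-molecule"`), event count, maximum duration and
#' occupancy (fraction of frames with at least one molecule of the type in
#' contact). With `collapse_subunits = TRUE` events are additionally pooled
#' across the five aligned subunit copies of each residue.
#'
#' @param series_list one [contact_series()] or a list of them (repeats).
#' @param collapse_subunits pool across subunit copies of each residue.
#' @param average `"pooled"` (event-weighted) or `"per-molecule"`.
#' @return object of class `contact_table`: a data.frame with columns
#'   residue (and subunit unless collapsed), lipid_type, mean_duration_ns,
#'   n_events, max_duration_ns, occupancy.
#' @export
contact_table <- function(series_list, collapse_subunits = TRUE,
                          average = c("pooled", "per-molecule")) {
  average <- match.arg(average)
  if (inherits(series_list, "contact_series")) series_list <- list(series_list)
  ref <- series_list[[1]]
  for (s in series_list)
    if (!identical(s$residues, ref$residues))
      stopf("alignment error: repeats use inconsistent residue indexing")

  res_keys <- if (collapse_subunits) unique(ref$residues$resid)
              else unique(paste(ref$residues$subunit, ref$residues$resid, sep = ":"))
  types <- sort(unique(unlist(lapply(series_list, `[[`, "lipid_types"))))
  total_frames <- sum(vapply(series_list, function(s) as.numeric(s$n_frames), 0))

  rows <- list()
  for (ty in types) {
    ev <- list()           # pooled event durations, per residue key
    occ <- list()          # contact frames (any molecule), per residue key
    molmeans <- list()     # per-molecule mean durations, per residue key
    for (s in series_list) {
      sel <- which(s$pairs$lipid_type == ty)
      if (!length(sel)) next
      key <- if (collapse_subunits) as.character(s$pairs$resid[sel])
             else paste(s$pairs$subunit[sel], s$pairs$resid[sel], sep = ":")
      # occupancy is counted per (subunit, residue) copy, then pooled, so a
      # collapsed residue's occupancy is the mean over its five copies
      key_copy <- paste(s$pairs$subunit[sel], s$pairs$resid[sel], sep = ":")
      for (kc in unique(key_copy)) {
        rows_c <- sel[key_copy == kc]
        kk <- key[match(kc, key_copy)]
        occ[[kk]] <- c(occ[[kk]] %||% 0,
                       sum(colSums(s$mat[rows_c, , drop = FALSE]) > 0))
      }
      for (kk in unique(key)) {
        rows_k <- sel[key == kk]
        m <- s$mat[rows_k, , drop = FALSE]
        durs <- lapply(seq_len(nrow(m)), function(i) durations_from_series(m[i, ], s$dt))
        ev[[kk]] <- c(ev[[kk]], unlist(durs))
        molmeans[[kk]] <- c(molmeans[[kk]],
                            vapply(durs, function(d) if (length(d)) mean(d) else NA_real_, 0))
      }
    }
    for (kk in if (collapse_subunits) as.character(res_keys) else res_keys) {
      e <- ev[[kk]] %||% numeric(0)
      mm <- molmeans[[kk]]
      mean_dur <- if (!length(e)) 0
        else if (average == "pooled") mean(e) else mean(mm, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        residue = if (collapse_subunits) as.integer(kk)
                  else as.integer(sub(".*:", "", kk)),
        subunit = if (collapse_subunits) NA_character_ else sub(":.*", "", kk),
        lipid_type = ty,
        mean_duration_ns = mean_dur,
        n_events = length(e),
        max_duration_ns = if (length(e)) max(e) else 0,
        occupancy = sum(occ[[kk]] %||% 0) /
          (total_frames *
             if (collapse_subunits) length(unique(ref$residues$subunit)) else 1),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "cutoff") <- ref$cutoff
  attr(tab, "average") <- average
  attr(tab, "collapse_subunits") <- collapse_subunits
  attr(tab, "boundary_events") <- "uncensored"
  class(tab) <- c("contact_table", "data.frame")
  tab
}

#' Rank lipid types by contact duration
#'
#' Sorts lipid types in descending order of a per-type summary of the
#' per-residue mean contact durations: the maximum over residues
#' (`"max"`) or the mean of the 20 largest per-residue means
#' (`"mean-top-20"`). Exact ties keep input order and set a `ties` attribute.
#'
#' @param table a [contact_table()].
#' @param statistic `"max"` or `"mean-top-20"`.
#' @return character vector of lipid types, most persistent first; attribute
#'   `summary` holds the per-type statistic, `ties` flags exact ties.
#' @export
lipid_hierarchy <- function(table, statistic = c("max", "mean-top-20")) {
  statistic <- match.arg(statistic)
  if (!nrow(table)) stopf("empty contact table")
  types <- unique(table$lipid_type)
  if (length(types) < 2) stopf("hierarchy needs at least 2 lipid types")
  stat <- vapply(types, function(ty) {
    d <- table$mean_duration_ns[table$lipid_type == ty]
    if (statistic == "max") max(d) else mean(utils::head(sort(d, decreasing = TRUE), 20))
  }, 0)
  ord <- order(-stat)  # stable: ties keep input order
  out <- types[ord]
  attr(out, "summary") <- stat[ord]
  attr(out, "ties") <- anyDuplicated(stat) > 0
  out
}

#' Write per-residue mean contact durations into PDB B-factors
#'
#' Maps a contact table's mean durations for one lipid type onto a structure:
#' every atom's B-factor is set to its residue's mean contact duration
#' (ns, clamped to the PDB field range); residues absent from the table get 0
#' with a warning.
#'
#' @param table a [contact_table()].
#' @param lipid_type lipid type to map.
#' @param structure_path input PDB.
#' @param out_path output PDB.
#' @return `out_path`, invisibly; attribute `n_unmapped` counts residues
#'   without table entries.
#' @export
export_bfactor <- function(table, lipid_type, structure_path, out_path) {
  sub <- table[table$lipid_type == lipid_type, ]
  if (!nrow(sub)) stopf("no table entries for lipid type '%s'", lipid_type)
  pdb <- bio3d::read.pdb(structure_path)
  collapsed <- attr(table, "collapse_subunits") %||% TRUE
  key_atoms <- if (collapsed) as.character(pdb$atom$resno)
               else paste(pdb$atom$chain, pdb$atom$resno, sep = ":")
  key_tab <- if (collapsed) as.character(sub$residue)
             else paste(sub$subunit, sub$residue, sep = ":")
  b <- sub$mean_duration_ns[match(key_atoms, key_tab)]
  n_unmapped <- length(unique(key_atoms[is.na(b)]))
  if (!any(!is.na(b)))
    stopf("mapping error: no structure residues match the contact table")
  if (n_unmapped > 0)
    warnf("%d structure residue(s) missing from the contact table; B-factor set to 0",
          n_unmapped)
  b[is.na(b)] <- 0
  pdb$atom$b <- pmin(pmax(b, 0), 999.99)
  bio3d::write.pdb(pdb, file = out_path)
  out <- out_path
  attr(out, "n_unmapped") <- n_unmapped
  invisible(out)
}

#' Write a contact table as CSV
#'
#' @param table a [contact_table()].
#' @param path output CSV.
#' @export
write_contact_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
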