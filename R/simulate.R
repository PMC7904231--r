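# Toy lipid dynamics: overdamped Brownian motion of lipid anchors in the
# membrane plane, in the potential of the planted binding sites, with a hard
# protein core, hexagonal periodic wrapping, and Poisson cholesterol
# flip-flop between leaflets. The protein never moves.

# Boolean occupancy mask of the protein core on a fine in-plane grid, one per
# leaflet half (beads with z above/below the midplane). Proposed lipid moves
# landing on a masked cell are rejected (hard reflective core).
protein_core_mask <- function(system, core_radius = 0.35, h = 0.05) {
  top <- system$topology
  # hard core from backbone beads only: sidechain beads act as soft contact
  # antennae that lipids may approach freely
  pro <- which(top$mol_class == "protein" & top$role == "backbone")
  box <- system$box
  corners <- rbind(c(0, 0), box[1, 1:2], box[2, 1:2], box[1, 1:2] + box[2, 1:2])
  org <- apply(corners, 2, min) - h
  ext <- apply(corners, 2, max) + h
  nx <- ceiling((ext[1] - org[1]) / h)
  ny <- ceiling((ext[2] - org[2]) / h)
  zmid <- box_center(box)[3]
  masks <- list()
  for (lf in LEAFLETS) {
    m <- matrix(FALSE, nx, ny)
    if (length(pro)) {
      zb <- system$coords[pro, 3]
      sel <- if (lf == "extracellular") pro[zb >= zmid] else pro[zb < zmid]
      if (length(sel)) {
        xy <- unique(round(system$coords[sel, 1:2, drop = FALSE], 6))
        rad <- ceiling(core_radius / h)
        for (b in seq_len(nrow(xy))) {
          ix <- floor((xy[b, 1] - org[1]) / h) + 1
          iy <- floor((xy[b, 2] - org[2]) / h) + 1
          xs <- max(1, ix - rad):min(nx, ix + rad)
          ys <- max(1, iy - rad):min(ny, iy + rad)
          cx <- org[1] + (xs - 0.5) * h
          cy <- org[2] + (ys - 0.5) * h
          d2 <- outer((cx - xy[b, 1])^2, (cy - xy[b, 2])^2, "+")
          m[xs, ys] <- m[xs, ys] | (d2 <= core_radius^2)
        }
      }
    }
    masks[[lf]] <- m
  }
  list(masks = masks, origin = org, h = h, nx = nx, ny = ny)
}

mask_hits <- function(mask, xy, leaflet_is_ext) {
  ix <- floor((xy[, 1] - mask$origin[1]) / mask$h) + 1
  iy <- floor((xy[, 2] - mask$origin[2]) / mask$h) + 1
  inside <- ix >= 1 & ix <= mask$nx & iy >= 1 & iy <= mask$ny
  hit <- rep(FALSE, nrow(xy))
  for (is_ext in c(TRUE, FALSE)) {
    sel <- inside & (leaflet_is_ext == is_ext)
    if (!any(sel)) next
    m <- mask$masks[[if (is_ext) "extracellular" else "intracellular"]]
    hit[sel] <- m[cbind(ix[sel], iy[sel])]
  }
  hit
}

#' Simulate toy lipid dynamics
#'
#' Per step, each lipid anchor position is updated by overdamped Brownian
#' motion `dx = D F dt + sqrt(2 D dt) xi` (forces from the planted Gaussian
#' wells, in kT/nm so the mobility is D in kT units), wrapped periodically in
#' the triclinic cell. Moves into the hard protein core are rejected.
#' Cholesterol flips leaflet as a Poisson process at the truth's flip-flop
#' rate (its z teleports to the other leaflet plane). Protein beads never
#' move. Randomness uses one independent pre-seeded stream per molecule
#' derived from `seed`, so adding or removing molecules does not reshuffle
#' the noise of the others.
#'
#' @param system [build_membrane()] output.
#' @param truth [synthetic_truth()] ground truth (sites, diffusion, flip-flop,
#'   state).
#' @param n_steps number of integration steps.
#' @param step_dt time step (ns).
#' @param write_every write a frame every this many steps (the initial
#'   configuration is frame 1).
#' @param seed integer seed.
#' @param core_radius hard-core exclusion distance from protein beads (nm).
#' @return a [trajectory] object; attributes `leaflet_record` (frames x
#'   molecules leaflet labels), `flip_count` (total leaflet changes at step
#'   resolution) and `truth` carry simulator ground truth for validation.
#' @export
simulate_lipids <- function(system, truth, n_steps, step_dt = 0.1,
                            write_every = 20, seed = 1, core_radius = 0.2) {
  stopifnot(inherits(system, "membrane_system"), inherits(truth, "synthetic_truth"),
            n_steps >= 1, step_dt > 0, write_every >= 1)
  lip <- system$lipids
  n_mol <- nrow(lip)
  box <- system$box
  b2 <- box[1:2, 1:2]
  b2inv <- solve(b2)
  center <- box_center(box)

  sites <- active_sites(truth)
  D <- diffusion_of(truth, lip$lipid_type)
  if (length(sites)) {
    min_width <- min(vapply(sites, `[[`, 0, "width"))
    rms <- sqrt(4 * max(D) * step_dt)
    if (rms > min_width / 2)
      stopf("unstable step: RMS displacement %.3f nm exceeds half the smallest site width (%.3f nm); reduce step_dt",
            rms, min_width / 2)
  }
  if (truth$flipflop_rate * step_dt > 0.1)
    stopf("unstable step: flip probability per step exceeds 0.1")

  # Pre-resolved site instances restricted to matching lipids.
  site_inst <- lapply(sites, function(s) list(
    centers = site_centers(s, center[1:2]),
    idx_type = which(lip$lipid_type == s$selectivity),
    leaflet = s$leaflet, depth = s$well_depth, w2 = s$width^2))

  # Per-molecule noise streams (counter-based: stream seed from global seed
  # and molecule id).
  gx <- matrix(0, n_steps, n_mol)
  gy <- matrix(0, n_steps, n_mol)
  is_chol <- lip$lipid_type == "CHOL"
  fu <- if (any(is_chol) && truth$flipflop_rate > 0) matrix(1, n_steps, n_mol) else NULL
  for (i in seq_len(n_mol)) {
    with_private_seed(molecule_seed(seed, lip$mol_id[i]), {
      gx[, i] <- stats::rnorm(n_steps)
      gy[, i] <- stats::rnorm(n_steps)
      if (!is.null(fu) && is_chol[i]) fu[, i] <- stats::runif(n_steps)
    })
  }

  mask <- protein_core_mask(system, core_radius = core_radius)
  pos <- cbind(lip$x, lip$y)
  is_ext <- lip$leaflet == "extracellular"
  sig <- sqrt(2 * D * step_dt)
  p_flip <- 1 - exp(-truth$flipflop_rate * step_dt)

  wrap2 <- function(xy) {
    s <- xy %*% b2inv
    (s - floor(s)) %*% b2
  }
  mindisp <- function(xy, cen) {
    d <- sweep(xy, 2, cen, "-")
    s <- d %*% b2inv
    s <- s - round(s)
    s %*% b2
  }

  n_frames <- 1L + n_steps %/% write_every
  frame_pos <- array(NA_real_, c(n_frames, n_mol, 2))
  frame_ext <- matrix(NA, n_frames, n_mol)
  frame_step <- integer(n_frames)
  frame_pos[1, , ] <- pos
  frame_ext[1, ] <- is_ext
  fidx <- 1L
  flip_count <- 0L

  for (step in seq_len(n_steps)) {
    Fx <- numeric(n_mol)
    Fy <- numeric(n_mol)
    for (si in site_inst) {
      idx <- si$idx_type[is_ext[si$idx_type] == (si$leaflet == "extracellular")]
      if (!length(idx)) next
      for (ci in seq_len(nrow(si$centers))) {
        d <- mindisp(pos[idx, , drop = FALSE], si$centers[ci, ])
        r2 <- d[, 1]^2 + d[, 2]^2
        g <- si$depth * exp(-r2 / (2 * si$w2)) / si$w2
        Fx[idx] <- Fx[idx] - g * d[, 1]
        Fy[idx] <- Fy[idx] - g * d[, 2]
      }
    }
    prop <- wrap2(cbind(pos[, 1] + D * Fx * step_dt + sig * gx[step, ],
                        pos[, 2] + D * Fy * step_dt + sig * gy[step, ]))
    rej <- mask_hits(mask, prop, is_ext)
    if (any(rej)) prop[rej, ] <- pos[rej, , drop = FALSE]
    pos <- prop
    if (!is.null(fu)) {
      flips <- is_chol & fu[step, ] < p_flip
      if (any(flips)) {
        is_ext[flips] <- !is_ext[flips]
        flip_count <- flip_count + sum(flips)
      }
    }
    if (step %% write_every == 0L) {
      fidx <- fidx + 1L
      frame_pos[fidx, , ] <- pos
      frame_ext[fidx, ] <- is_ext
      frame_step[fidx] <- step
    }
  }

  # Expand molecule anchors to bead coordinates.
  top <- system$topology
  lip_beads <- which(top$mol_class == "lipid")
  pro_beads <- which(top$mol_class == "protein")
  bead_mol <- match(top$mol_id[lip_beads], lip$mol_id)
  bead_dz <- numeric(length(lip_beads))
  for (t in unique(lip$lipid_type)) {
    tmpl <- lipid_bead_template(t)
    sel <- top$lipid_type[lip_beads] == t
    bead_dz[sel] <- rep(tmpl$dz, length.out = sum(sel))
  }
  lz <- system$spec$leaflet_z

  n_beads <- nrow(top)
  coords <- array(NA_real_, c(n_frames, n_beads, 3))
  for (f in seq_len(n_frames)) {
    if (length(pro_beads)) coords[f, pro_beads, ] <- system$coords[pro_beads, ]
    ext_f <- frame_ext[f, bead_mol]
    zsign <- ifelse(ext_f, 1, -1)
    z_anchor <- center[3] + ifelse(ext_f, lz[["extracellular"]], lz[["intracellular"]]) +
      lip$z_noise[bead_mol]
    coords[f, lip_beads, 1] <- frame_pos[f, bead_mol, 1]
    coords[f, lip_beads, 2] <- frame_pos[f, bead_mol, 2]
    coords[f, lip_beads, 3] <- z_anchor + zsign * bead_dz
  }

  traj <- new_trajectory(times = frame_step * step_dt, coords = coords, box = box)
  lf_rec <- matrix(ifelse(frame_ext, "extracellular", "intracellular"),
                   n_frames, n_mol, dimnames = list(NULL, lip$mol_id))
  attr(traj, "leaflet_record") <- lf_rec
  attr(traj, "flip_count") <- flip_count
  attr(traj, "truth") <- truth
  traj
}

#' Monte-Carlo residence-time oracle for a planted site
#'
#' Independent first-passage estimate of the mean time a lipid initialized at
#' a site's centre takes to first leave the site radius (2 x width), by direct
#' Brownian simulation of the single-site potential in an open plane. Used as
#' ground truth for contact-duration recovery; it shares no code path with
#' the trajectory-based contact statistics.
#'
#' @param truth [synthetic_truth()] supplying the diffusion coefficient.
#' @param site [planted_site()] to probe.
#' @param n_samples number of independent walkers (>= 100).
#' @param seed integer seed.
#' @param step_dt integration step (ns).
#' @param max_steps step budget; walkers still inside after the budget raise
#'   a budget-exceeded error carrying the partial estimate in its `partial`
#'   field.
#' @return list with `mean` (ns), `se`, `n`.
#' @export
truth_residence_oracle <- function(truth, site, n_samples = 200, seed = 1,
                                   step_dt = 0.02, max_steps = 2e5) {
  stopifnot(n_samples >= 100)
  D <- diffusion_of(truth, site$selectivity)
  R2 <- (2 * site$width)^2
  w2 <- site$width^2
  with_private_seed(seed, {
    pos <- matrix(0, n_samples, 2)
    alive <- rep(TRUE, n_samples)
    exit_t <- rep(NA_real_, n_samples)
    sig <- sqrt(2 * D * step_dt)
    step <- 0L
    while (any(alive) && step < max_steps) {
      step <- step + 1L
      n_a <- sum(alive)
      p <- pos[alive, , drop = FALSE]
      r2 <- p[, 1]^2 + p[, 2]^2
      g <- site$well_depth * exp(-r2 / (2 * w2)) / w2
      p <- p - D * g * p * step_dt +
        matrix(stats::rnorm(2 * n_a, sd = sig), n_a, 2)
      pos[alive, ] <- p
      out <- p[, 1]^2 + p[, 2]^2 > R2
      if (any(out)) {
        idx <- which(alive)[out]
        exit_t[idx] <- step * step_dt
        alive[idx] <- FALSE
      }
    }
    if (any(alive)) {
      done <- exit_t[!is.na(exit_t)]
      partial <- list(mean = mean(done), se = stats::sd(done) / sqrt(length(done)),
                      n = length(done))
      cond <- structure(class = c("lipmap_budget_error", "error", "condition"),
                        list(message = sprintf(
                          "residence oracle: %d/%d walkers still bound after %g steps (partial mean %.1f ns)",
                          sum(alive), n_samples, max_steps, partial$mean),
                          call = sys.call(-1), partial = partial))
      stop(cond)
    }
    list(mean = mean(exit_t), se = stats::sd(exit_t) / sqrt(n_samples), n = n_samples)
  })
}
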