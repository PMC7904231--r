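test_that("simulation conserves molecules, is seed-deterministic, and freezes leaflets at zero flip rate", {
  sys <- small_protein_system(seed = 4, nominal = 15)
  truth <- synthetic_truth(flipflop_rate = 0)
  traj <- simulate_lipids(sys, truth, n_steps = 200, write_every = 10, seed = 4)
  lr <- attr(traj, "leaflet_record")
  expect_true(all(apply(lr, 2, function(col) all(col == col[1]))))
  expect_identical(attr(traj, "flip_count"), 0L)
  # count conservation: same molecules, same types in every frame
  asg <- assign_leaflets(traj, sys$topology)
  expect_identical(sort(asg$mol_ids), sort(sys$lipids$mol_id))

  traj2 <- simulate_lipids(sys, truth, n_steps = 200, write_every = 10, seed = 4)
  expect_identical(traj$coords, traj2$coords)
  traj3 <- simulate_lipids(sys, truth, n_steps = 200, write_every = 10, seed = 5)
  expect_false(identical(traj$coords, traj3$coords))
})

test_that("per-molecule noise streams are stable under molecule-count changes", {
  # same seed, one more lipid per leaflet: the shared molecules' noise must
  # not reshuffle, so early-time displacements of common molecule ids agree
  spec10 <- neuronal_membrane_spec(nominal_per_leaflet = 10)
  sys <- build_membrane(spec10, NULL, hexagonal_box(9), seed = 3)
  truth <- synthetic_truth(flipflop_rate = 0)
  trajA <- simulate_lipids(sys, truth, n_steps = 20, write_every = 20, seed = 11)
  sysB <- build_membrane(neuronal_membrane_spec(nominal_per_leaflet = 12),
                         NULL, hexagonal_box(9), seed = 99)
  trajB <- simulate_lipids(sysB, truth, n_steps = 20, write_every = 20, seed = 11)
  # molecule id 1 exists in both systems; with no sites its displacement is
  # pure noise from its own stream (compared minimum-image, wrap-safe)
  unwrap <- function(d, box) {
    s <- matrix(d, 1) %*% solve(box[1:2, 1:2])
    as.numeric((s - round(s)) %*% box[1:2, 1:2])
  }
  dA <- unwrap(trajA$coords[2, 1, 1:2] - trajA$coords[1, 1, 1:2], hexagonal_box(9))
  dB <- unwrap(trajB$coords[2, 1, 1:2] - trajB$coords[1, 1, 1:2], hexagonal_box(9))
  expect_equal(dA, dB, tolerance = 1e-12)
})

test_that("protein beads never move and lipids stay out of the hard core", {
  sys <- small_protein_system(seed = 8, nominal = 20)
  traj <- simulate_lipids(sys, synthetic_truth(), n_steps = 300,
                          write_every = 30, seed = 8)
  pro <- which(sys$topology$mol_class == "protein")
  for (f in seq_len(traj$n_frames))
    expect_identical(matrix(traj$coords[f, pro, ], ncol = 3), sys$coords[pro, ])
})

test_that("too-large steps raise a stability error", {
  sys <- small_protein_system(seed = 1, nominal = 5)
  truth <- synthetic_truth(sites = list(
    planted_site("s", "extracellular", "CHOL", 2, width = 0.1, radius = 2.5)))
  expect_error(simulate_lipids(sys, truth, n_steps = 10, step_dt = 1, seed = 1),
               "unstable step")
})

test_that("cholesterol flip count follows the Poisson expectation", {
  sys <- build_membrane(neuronal_membrane_spec(nominal_per_leaflet = 60),
                        NULL, hexagonal_box(10), seed = 12)
  lam <- 1e-3   # fast flipping for a compact unit test
  traj <- simulate_lipids(sys, synthetic_truth(flipflop_rate = lam),
                          n_steps = 2000, step_dt = 0.1, write_every = 10,
                          seed = 12)
  n_chol <- sum(sys$lipids$lipid_type == "CHOL")
  expected <- lam * n_chol * 200
  expect_lt(abs(attr(traj, "flip_count") - expected), 4 * sqrt(expected))
  # only CHOL ever flips
  lr <- attr(traj, "leaflet_record")
  flipped <- apply(lr, 2, function(col) any(col != col[1]))
  expect_true(all(sys$lipids$lipid_type[flipped] == "CHOL"))
})

test_that("a state-gated site raises occupancy only in its state", {
  truth_on <- interface_truth("active")
  truth_off <- interface_truth("inactive")
  sys <- build_membrane(neuronal_membrane_spec(nominal_per_leaflet = 60),
                        build_pentamer(), hexagonal_box(11), seed = 31)
  t_on <- simulate_lipids(sys, truth_on, n_steps = 2000, write_every = 20, seed = 31)
  t_off <- simulate_lipids(sys, truth_off, n_steps = 2000, write_every = 20, seed = 31)
  site <- site_from_planted(truth_on$sites[[1]], c(box_center(sys$box)))
  occupancy <- function(traj) {
    anch <- sys$lipids[sys$lipids$lipid_type == "CHOL", ]
    aid <- vapply(anch$mol_id, function(m)
      sys$topology$bead_id[sys$topology$mol_id == m &
                             sys$topology$role == "hydroxyl"], 0L)
    tot <- 0
    for (f in seq_len(traj$n_frames)) {
      xy <- matrix(traj$coords[f, aid, ], ncol = 3)
      d2 <- outer(xy[, 1], site$points[, 1], "-")^2 +
        outer(xy[, 2], site$points[, 2], "-")^2
      tot <- tot + sum(apply(d2, 1, min) < site$radius^2)
    }
    tot
  }
  expect_gt(occupancy(t_on), occupancy(t_off))
})

test_that("residence oracle matches free diffusion and scales correctly", {
  truth <- synthetic_truth(diffusion = c(CHOL = 0.05))
  site0 <- planted_site("free", "extracellular", "CHOL", 0, width = 0.4, radius = 2)
  o <- truth_residence_oracle(truth, site0, n_samples = 400, seed = 2)
  # independent check: mean first-exit time from a disc of radius R started
  # at the centre is R^2 / (4 D)
  analytic <- (2 * 0.4)^2 / (4 * 0.05)
  expect_lt(abs(o$mean - analytic), 3 * o$se + 0.05 * analytic)

  # monotone in depth
  site2 <- planted_site("s2", "extracellular", "CHOL", 2, width = 0.4, radius = 2)
  site5 <- planted_site("s5", "extracellular", "CHOL", 5, width = 0.4, radius = 2)
  o2 <- truth_residence_oracle(truth, site2, n_samples = 200, seed = 3)
  o5 <- truth_residence_oracle(truth, site5, n_samples = 200, seed = 3)
  expect_gt(o5$mean, o2$mean)

  # diffusive time scaling: 4x diffusion -> 1/4 residence at zero depth
  truth4 <- synthetic_truth(diffusion = c(CHOL = 0.2))
  o4 <- truth_residence_oracle(truth4, site0, n_samples = 400, seed = 4)
  expect_lt(abs(o4$mean - o$mean / 4), 3 * (o4$se + o$se / 4))

  # budget exhaustion carries a partial estimate
  deep <- planted_site("deep", "extracellular", "CHOL", 12, width = 0.4, radius = 2)
  err <- tryCatch(truth_residence_oracle(truth, deep, n_samples = 100, seed = 5,
                                         max_steps = 200),
                  lipmap_budget_error = function(e) e)
  expect_s3_class(err, "lipmap_budget_error")
})

test_that("free diffusion yields a flat stationary density away from the protein", {
  sys <- build_membrane(neuronal_membrane_spec(nominal_per_leaflet = 100),
                        NULL, hexagonal_box(10), seed = 17)
  traj <- simulate_lipids(sys, synthetic_truth(flipflop_rate = 0),
                          n_steps = 2500, step_dt = 0.2, write_every = 5,
                          seed = 17)
  # subsample to ~bin-decorrelated frames, then pool all types and leaflets
  sub <- select_window(traj, analysis_window(1.0, 25))
  asg <- assign_leaflets(sub, sys$topology)
  total <- NULL
  for (ty in c("POPC", "POPE", "DOPS", "SM", "CHOL"))
      for (lf in c("extracellular", "intracellular")) {
    g <- tryCatch(density2d(sub, sys$topology, asg, ty, lf, bin_size = 1),
                  error = function(e) NULL)
    if (is.null(g)) next
    total <- if (is.null(total)) g$values else total + g$values
    grid <- g
  }
  n <- dim(total)
  cx <- grid$origin[1] + (seq_len(n[1]) - 0.5) * grid$bin_size
  cy <- grid$origin[2] + (seq_len(n[2]) - 0.5) * grid$bin_size
  s <- cbind(rep(cx, n[2]), rep(cy, each = n[1])) %*% solve(sys$box[1:2, 1:2])
  inside <- s[, 1] > 0.12 & s[, 1] < 0.88 & s[, 2] > 0.12 & s[, 2] < 0.88
  counts <- as.numeric(total)[inside] * grid$bin_size^2 * sub$n_frames
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(0.999, df = sum(inside) - 1))
})
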