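test_that("leaflet assignment follows the anchor-bead sign convention", {
  sysf <- two_lipid_system(n_frames = 3)
  asg <- assign_leaflets(sysf$trajectory, sysf$topology)
  # POPC anchor at z = 6.8, CHOL hydroxyl at 3.2; midplane = 5.0
  expect_true(all(asg$leaflet[, "1"] == "extracellular"))
  expect_true(all(asg$leaflet[, "2"] == "intracellular"))
})

test_that("assignment is constant without flip-flop and tracks simulator truth", {
  sys <- small_protein_system(seed = 3, nominal = 12)
  traj <- simulate_lipids(sys, synthetic_truth(flipflop_rate = 0),
                          n_steps = 150, write_every = 15, seed = 3)
  asg <- assign_leaflets(traj, sys$topology)
  expect_true(all(apply(asg$leaflet, 2, function(c) all(c == c[1]))))
  expect_identical(unname(asg$leaflet),
                   unname(attr(traj, "leaflet_record")))
})

test_that("a lipid without an anchor bead is reported by molecule", {
  top <- two_lipid_system()$topology
  broken <- as.data.frame(top)
  broken$role[broken$role == "hydroxyl"] <- "tail"
  broken <- topology(broken)
  expect_error(assign_leaflets(two_lipid_system()$trajectory, broken),
               "without an anchor bead: 2")
})

test_that("density2d arithmetic: one immobile lipid, exact conservation", {
  sysf <- two_lipid_system(n_frames = 100)
  asg <- assign_leaflets(sysf$trajectory, sysf$topology)
  g <- density2d(sysf$trajectory, sysf$topology, asg, "POPC", "extracellular",
                 bin_size = 0.2)
  nz <- which(g$values != 0)
  expect_length(nz, 1)
  expect_equal(g$values[nz], 25)          # 1 / 0.04 nm^2
  expect_equal(grid_integral(g), 1, tolerance = 1e-12)
})

test_that("density integrals equal time-averaged molecule counts exactly", {
  sys <- small_protein_system(seed = 13, nominal = 15)
  traj <- simulate_lipids(sys, synthetic_truth(), n_steps = 200,
                          write_every = 20, seed = 13)
  asg <- assign_leaflets(traj, sys$topology)
  for (ty in c("CHOL", "POPC")) for (lf in c("extracellular", "intracellular")) {
    g <- tryCatch(density2d(traj, sys$topology, asg, ty, lf, bin_size = 0.3),
                  error = function(e) NULL)
    if (is.null(g)) next
    want <- mean(vapply(seq_len(traj$n_frames), function(f)
      sum(asg$leaflet[f, asg$lipid_type == ty] == lf), 0))
    expect_equal(grid_integral(g), want, tolerance = 1e-9)
  }
  g3 <- density3d(traj, sys$topology, "CHOL", "hydroxyl", voxel_size = 0.4)
  expect_equal(grid_integral(g3), sum(sys$lipids$lipid_type == "CHOL"),
               tolerance = 1e-9)
})

test_that("empty selections fail loudly instead of returning zero grids", {
  sysf <- two_lipid_system()
  asg <- assign_leaflets(sysf$trajectory, sysf$topology)
  expect_error(density2d(sysf$trajectory, sysf$topology, asg, "DOPS",
                         "intracellular", 0.2), "empty selection")
  # misconfigured leaflet: POPC never intracellular here
  expect_error(density2d(sysf$trajectory, sysf$topology, asg, "POPC",
                         "intracellular", 0.2), "empty selection")
  expect_error(density3d(sysf$trajectory, sysf$topology, "CHOL", "florp", 0.2),
               "selection error")
})

test_that("density3d arithmetic and bead-role normalization", {
  sysf <- two_lipid_system(n_frames = 50)
  g <- density3d(sysf$trajectory, sysf$topology, "CHOL", "hydroxyl",
                 voxel_size = 0.1)
  nz <- which(g$values != 0)
  expect_length(nz, 1)
  expect_equal(g$values[nz], 1000)        # 1 / 0.001 nm^3
  expect_equal(grid_integral(g), 1, tolerance = 1e-12)
  expect_equal(g$metadata$beads_per_molecule, 1)
  # tail selector on POPC picks 1 tail bead here: still a bead count
  gt <- density3d(sysf$trajectory, sysf$topology, "POPC", "tail", voxel_size = 0.1)
  expect_equal(grid_integral(gt), 1, tolerance = 1e-12)
  ga <- density3d(sysf$trajectory, sysf$topology, "POPC", "any", voxel_size = 0.1)
  expect_equal(grid_integral(ga), 2, tolerance = 1e-12)   # 2 beads/molecule
  expect_equal(ga$metadata$beads_per_molecule, 2)
})

test_that("equal-composition isovalue reweighting", {
  expect_equal(equal_composition_isovalue(7.3, 0.2, 5), 7.3)  # fixed point
  expect_equal(equal_composition_isovalue(5, 0.4, 5), 10)
  # cholesterol at its Table-style total abundance maps a 6.7 reference to ~15
  expect_equal(equal_composition_isovalue(6.7, 0.448, 5), 15.008, tolerance = 1e-12)
  expect_error(equal_composition_isovalue(5, 0.4, 0), "domain error")
})

test_that("half-window densities of a stationary run agree within noise", {
  sys <- build_membrane(neuronal_membrane_spec(nominal_per_leaflet = 60),
                        NULL, hexagonal_box(9), seed = 23)
  traj <- simulate_lipids(sys, synthetic_truth(flipflop_rate = 0),
                          n_steps = 2000, write_every = 10, seed = 23)
  half <- function(first) {
    idx <- if (first) 1:100 else 102:201
    tr <- new_trajectory(traj$times[idx], traj$coords[idx, , , drop = FALSE],
                         traj$box[idx, , , drop = FALSE])
    asg <- assign_leaflets(tr, sys$topology)
    density2d(tr, sys$topology, asg, "CHOL", "extracellular", bin_size = 1.5)
  }
  g1 <- half(TRUE); g2 <- half(FALSE)
  l1 <- sum(abs(g1$values - g2$values)) * g1$bin_size^2
  expect_lt(l1 / grid_integral(g1), 1)  # same stationary field, modest noise
})

test_that("2D CSV and 3D OpenDX exports roundtrip", {
  sysf <- two_lipid_system(n_frames = 10)
  asg <- assign_leaflets(sysf$trajectory, sysf$topology)
  g2 <- density2d(sysf$trajectory, sysf$topology, asg, "POPC", "extracellular", 0.5)
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_density(g2, f2)
  r2 <- read_density_csv(f2)
  expect_equal(r2$values, g2$values, tolerance = 1e-6)
  expect_equal(r2$origin, g2$origin, tolerance = 1e-6)

  g3 <- density3d(sysf$trajectory, sysf$topology, "CHOL", "any", voxel_size = 0.5)
  f3 <- withr::local_tempfile(fileext = ".dx")
  export_density(g3, f3)
  r3 <- read_density_dx(f3)
  expect_equal(r3$values, g3$values, tolerance = 1e-6)
  expect_equal(r3$origin, g3$origin, tolerance = 1e-6)
  expect_equal(r3$voxel_size, g3$voxel_size, tolerance = 1e-9)

  empty <- g3; empty$values <- array(0, c(0, 0, 0))
  expect_error(export_density(empty, f3), "empty")
})
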