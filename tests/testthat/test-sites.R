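write_dummy_ligand_pdb <- function(path, two_copies = FALSE) {
  pdb_line <- function(serial, name, res, chain, resno, x, y, z, type = "HETATM")
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            type, serial, name, res, chain, resno, x, y, z)
  lines <- c(pdb_line(1, "C1", "IVM", "A", 501, 10, 20, 30),
             pdb_line(2, "C2", "IVM", "A", 501, 11, 20, 30),
             pdb_line(3, "O1", "IVM", "A", 501, 10, 21, 30))
  if (two_copies)
    lines <- c(lines, pdb_line(4, "C1", "IVM", "B", 502, 40, 20, 30),
               pdb_line(5, "C2", "IVM", "B", 502, 41, 20, 30))
  writeLines(c(lines, "END"), path)
}

test_that("ligand sites load with Angstrom-to-nm conversion, one per copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_dummy_ligand_pdb(f)
  sites <- load_site_from_structure(f, "IVM")
  expect_length(sites, 1)
  expect_equal(nrow(sites[[1]]$points), 3)
  expect_equal(sites[[1]]$points[1, ], c(1, 2, 3), ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_dummy_ligand_pdb(f2, two_copies = TRUE)
  sites2 <- load_site_from_structure(f2, "IVM")
  expect_length(sites2, 2)
  expect_setequal(vapply(sites2, `[[`, "", "name"), c("IVM_A", "IVM_B"))

  expect_error(load_site_from_structure(f, "PIP"), "not found")
})

test_that("uniform fields give enrichment 1 for any site geometry", {
  vals <- array(2.5, c(40, 40, 20))
  g <- grid3d_from_array(vals, h = 0.25)
  site <- site_definition("s", points = c(5, 5, 2.5), radius = 0.7)
  rep <- site_enrichment(g, site, axis = c(5, 5, 2.5), footprint_radius = 1.5)
  expect_equal(rep$enrichment, 1)
  expect_equal(rep$occupancy, 2.5 * rep$n_site_voxels * 0.25^3)
  wsite <- site_definition("w", wedge = list(index = 2, half_width_deg = 15,
                                             leaflet = "extracellular"))
  wrep <- site_enrichment(g, wsite, axis = c(5, 5, 2.5), footprint_radius = 2,
                          leaflet_z = c(extracellular = 1, intracellular = -1))
  expect_equal(wrep$enrichment, 1)
})

test_that("zero density in the site gives enrichment 0; geometry errors are raised", {
  vals <- array(1, c(40, 40, 20))
  vals[18:22, 18:22, 8:12] <- 0
  g <- grid3d_from_array(vals, h = 0.25)
  site <- site_definition("hole", points = c(5, 5, 2.5), radius = 0.4)
  rep <- site_enrichment(g, site, axis = c(5, 5, 2.5), footprint_radius = 1.5)
  expect_equal(rep$enrichment, 0)
  far <- site_definition("far", points = c(100, 100, 100), radius = 0.5)
  expect_error(site_enrichment(g, far), "does not intersect")
})

test_that("site enrichment is invariant under joint rigid translation", {
  set.seed(8)
  vals <- array(runif(40 * 40 * 20), c(40, 40, 20))
  mk <- function(org) grid3d_from_array(vals, h = 0.25, org = org)
  s1 <- site_enrichment(mk(c(0, 0, 0)),
                        site_definition("s", points = c(5, 5, 2.5), radius = 0.8),
                        axis = c(5, 5, 2.5), footprint_radius = 1.5)
  s2 <- site_enrichment(mk(c(3, -2, 1)),
                        site_definition("s", points = c(8, 3, 3.5), radius = 0.8),
                        axis = c(8, 3, 3.5), footprint_radius = 1.5)
  expect_equal(s1$enrichment, s2$enrichment, tolerance = 1e-12)
  expect_equal(s1$occupancy, s2$occupancy, tolerance = 1e-12)
})

test_that("state_difference is exact, antisymmetric and locates the change", {
  a <- grid3d_from_array(array(1, c(10, 10, 5)), h = 0.5)
  b <- grid3d_from_array(array(1, c(10, 10, 5)), h = 0.5)
  d0 <- state_difference(a, b)
  expect_true(all(d0$values == 0))
  expect_equal(d0$l1, 0)
  b$values[3, 4, 2] <- 1 - 0.7
  dab <- state_difference(a, b)
  expect_equal(dab$max_signed, 0.7)
  expect_equal(dab$max_location, c(3, 4, 2) * 0.5 - 0.25, ignore_attr = TRUE)
  dba <- state_difference(b, a)
  expect_equal(dab$values, -dba$values)
  shifted <- grid3d_from_array(array(1, c(10, 10, 5)), h = 0.5, org = c(1, 0, 0))
  expect_error(state_difference(a, shifted), "commensurability")
})

test_that("interface penetration depth from a single supra-threshold voxel", {
  vals <- array(0, c(64, 64, 10))
  g <- grid3d_from_array(vals, h = 0.25, axis = c(8, 8))
  # one hot voxel at radius 3 in wedge 2 (centre angle 180 degrees)
  x <- 8 - 3; y <- 8
  idx <- c(ceiling((x - 0) / 0.25), ceiling((y - 0) / 0.25), 5)
  g$values[idx[1], idx[2], idx[3]] <- 10
  out <- interface_penetration(g, axis = c(8, 8), threshold = 1,
                               footprint_radius = 4)
  expect_false(out$empty[out$wedge == 2])
  expect_equal(out$depth_nm[out$wedge == 2], 4 - out$r_min_nm[out$wedge == 2])
  expect_equal(out$r_min_nm[out$wedge == 2], 3, tolerance = 0.2)
  expect_true(all(out$empty[out$wedge != 2]))
  expect_true(all(out$depth_nm[out$wedge != 2] == 0))

  zero <- interface_penetration(grid3d_from_array(vals, h = 0.25, axis = c(8, 8)),
                                axis = c(8, 8), threshold = 1, footprint_radius = 4)
  expect_true(all(zero$empty))
  expect_true(all(zero$depth_nm == 0))
})
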