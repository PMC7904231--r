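test_that("read_gro parses a minimal file and flags malformed input", {
  path <- withr::local_tempfile(fileext = ".gro")
  atom <- function(resid, resn, bead, id, x, y, z)
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resid, resn, bead, id, x, y, z)
  writeLines(c("three beads", "    3",
               atom(1, "POPC", "PO4", 1, 1, 2, 3),
               atom(1, "POPC", "C1A", 2, 1.1, 2.1, 2.5),
               atom(2, "CHOL", "ROH", 3, 4, 5, 6),
               "  10.00000  10.00000  10.00000"), path)
  g <- read_gro(path)
  expect_equal(nrow(g$atoms), 3)
  expect_equal(g$box, diag(c(10, 10, 10)))
  expect_equal(g$coords[1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(g$atoms$bead_name, c("PO4", "C1A", "ROH"))

  bad <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("five declared, four present", "    5",
               atom(1, "POPC", "PO4", 1, 1, 2, 3),
               atom(1, "POPC", "C1A", 2, 1.1, 2.1, 2.5),
               atom(2, "CHOL", "ROH", 3, 4, 5, 6),
               atom(2, "CHOL", "R1", 4, 4, 5, 5.6),
               "  10.00000  10.00000  10.00000"), bad)
  expect_error(read_gro(bad), "line 7")
})

test_that("GRO roundtrip preserves topology exactly and coordinates to 0.001 nm", {
  sys <- small_protein_system(seed = 5)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(sys$topology, sys$coords, sys$box, path)
  rs <- read_system(path)
  expect_identical(as.data.frame(rs$topology), as.data.frame(sys$topology))
  expect_lte(max(abs(rs$trajectory$coords[1, , ] - sys$coords)), 0.001 + 1e-12)
  expect_equal(matrix(rs$trajectory$box[1, , ], 3, 3), sys$box, tolerance = 1e-4)
})

test_that("DCD roundtrip is lossless to format precision and bio3d-readable", {
  sys <- small_protein_system(seed = 6, nominal = 10)
  traj <- simulate_lipids(sys, synthetic_truth(), n_steps = 100,
                          write_every = 10, seed = 6)
  path <- withr::local_tempfile(fileext = ".dcd")
  write_dcd_trajectory(traj, path)
  back <- read_dcd_trajectory(path)
  expect_equal(back$n_frames, traj$n_frames)
  expect_lte(max(abs(back$coords - traj$coords)), 0.001)
  expect_equal(back$times, traj$times, tolerance = 1e-5)
  expect_equal(matrix(back$box[1, , ], 3, 3), matrix(traj$box[1, , ], 3, 3),
               tolerance = 1e-9)
  # independent reader: bio3d agrees on the coordinates (Angstrom)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  for (f in c(1, traj$n_frames))
    expect_equal(matrix(xyz[f, ], ncol = 3, byrow = TRUE),
                 matrix(traj$coords[f, , ], ncol = 3) * 10, tolerance = 1e-3,
                 ignore_attr = TRUE)
})

test_that("write_system refuses empty trajectories and roundtrips annotation", {
  sys <- small_protein_system(seed = 2, nominal = 5)
  traj <- new_trajectory(0, array(sys$coords, c(1, nrow(sys$coords), 3)), sys$box)
  empty <- traj; empty$n_frames <- 0L
  gro <- withr::local_tempfile(fileext = ".gro")
  expect_error(write_system(sys$topology, empty, gro), "empty")
  expect_false(file.exists(gro))
  write_system(sys$topology, traj, gro)
  expect_identical(as.data.frame(read_system(gro)$topology),
                   as.data.frame(sys$topology))
})

test_that("select_window implements the half-open last-fraction convention", {
  # 40 us at 10 ns spacing, keep last half at 10 ns stride -> exactly 2000
  # frames spanning (20 us, 40 us]
  tr <- new_trajectory(seq(0, 40000, by = 10), array(0, c(4001, 1, 3)),
                       hexagonal_box(10))
  w <- select_window(tr, analysis_window(0.5, 10))
  expect_identical(w$n_frames, 2000L)
  expect_gt(min(w$times), 20000)
  expect_equal(max(w$times), 40000)

  # identity window
  id <- select_window(tr, analysis_window(1.0, 10))
  expect_identical(id$times, tr$times)

  # hand-enumerated: 10 frames at 1 ns, last half, stride 2 -> 6, 8, 10 ns
  tr10 <- new_trajectory(1:10, array(0, c(10, 1, 3)), hexagonal_box(5))
  expect_equal(select_window(tr10, analysis_window(0.5, 2))$times, c(6, 8, 10))

  # idempotence at equal parameters
  w2 <- select_window(w, analysis_window(1.0, 10))
  expect_identical(w2$times, w$times)

  expect_error(select_window(tr10, analysis_window(0.5, 0.5)), "resolution")
})

test_that("center_on_protein undoes per-frame drifts exactly", {
  sys <- small_protein_system(seed = 9, nominal = 8)
  n <- nrow(sys$coords)
  n_frames <- 6
  arr <- array(NA_real_, c(n_frames, n, 3))
  set.seed(1)
  for (f in seq_len(n_frames))
    arr[f, , ] <- sweep(sys$coords, 2, c(runif(2, -3, 3), 0), "+")
  drifted <- new_trajectory(seq_len(n_frames), arr, sys$box)
  centred <- center_on_protein(drifted, sys$topology)
  pro <- which(sys$topology$mol_class == "protein")
  cents <- t(vapply(seq_len(n_frames), function(f)
    colMeans(matrix(centred$coords[f, pro, ], ncol = 3)), numeric(3)))
  expect_lt(max(apply(cents, 2, stats::var)), 1e-12)
  expect_equal(cents[1, ], box_center(sys$box), tolerance = 1e-9)
  top_nolip <- sys$topology[sys$topology$mol_class == "lipid", ]
  expect_error(center_on_protein(drifted, topology(transform(
    as.data.frame(sys$topology)[sys$topology$mol_class == "lipid", ],
    bead_id = seq_len(sum(sys$topology$mol_class == "lipid"))))),
    "selection error")
})
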