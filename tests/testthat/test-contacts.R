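# Hand-built one-residue / one-lipid systems for exact cutoff checks.
contact_fixture <- function(dist, n_frames = 5, box = hexagonal_box(10)) {
  top <- topology(data.frame(
    bead_id = 1:2, bead_name = c("BB", "PO4"), mol_id = 1:2,
    mol_class = c("protein", "lipid"),
    lipid_type = c(NA, "POPC"), resid = c(1L, 2L),
    resname = c("ALA", "POPC"), subunit = c("A", NA),
    role = c("backbone", "phosphate"), stringsAsFactors = FALSE))
  arr <- array(NA_real_, c(n_frames, 2, 3))
  for (f in seq_len(n_frames))
    arr[f, , ] <- rbind(c(5, 5, 5), c(5 + dist, 5, 5))
  list(topology = top,
       trajectory = new_trajectory(seq_len(n_frames), arr, box))
}

test_that("the 0.6 nm cutoff separates contact from no-contact exactly", {
  inside <- contact_fixture(0.59)
  cs <- contact_series(inside$trajectory, inside$topology)
  expect_identical(dim(cs$mat), c(1L, 5L))
  expect_true(all(cs$mat))
  outside <- contact_fixture(0.61)
  cs2 <- contact_series(outside$trajectory, outside$topology)
  expect_identical(nrow(cs2$pairs), 0L)
  expect_error(contact_series(inside$trajectory, inside$topology, cutoff = 6),
               "geometry error")
})

test_that("pruned contact detection equals the brute-force all-pairs scan", {
  sys <- small_protein_system(seed = 19, nominal = 12, box_a = 8)
  traj <- simulate_lipids(sys, hierarchy_truth(), n_steps = 500,
                          write_every = 10, seed = 19)
  a <- contact_series(traj, sys$topology, method = "pruned")
  b <- contact_series(traj, sys$topology, method = "brute")
  expect_same_contacts(a, b)
})

test_that("durations_from_series implements run-length arithmetic", {
  d <- durations_from_series(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE), 10)
  expect_equal(d, c(20, 30))
  expect_equal(mean(d), 25)
  expect_identical(durations_from_series(logical(0), 1), numeric(0))
  expect_identical(durations_from_series(rep(FALSE, 10), 1), numeric(0))
  # boundary runs are counted uncensored
  expect_equal(durations_from_series(c(TRUE, TRUE, FALSE, TRUE), 2), c(4, 2))
})

test_that("durations match a brute-force scanner on random series", {
  scanner <- function(v, dt) {
    out <- numeric(0); run <- 0
    for (x in v) {
      if (x) run <- run + 1
      else if (run > 0) { out <- c(out, run * dt); run <- 0 }
    }
    if (run > 0) out <- c(out, run * dt)
    out
  }
  set.seed(99)
  for (i in 1:1000) {
    v <- runif(sample(1:30, 1)) < 0.5
    expect_identical(durations_from_series(v, 2.5), scanner(v, 2.5))
  }
})

test_that("mean duration is invariant under frame reversal", {
  set.seed(4)
  for (i in 1:200) {
    v <- runif(40) < 0.4
    expect_equal(mean(durations_from_series(v, 1)),
                 mean(durations_from_series(rev(v), 1)))
  }
})

test_that("coarsening frames (OR of pairs) never decreases mean duration", {
  set.seed(11)
  for (i in 1:200) {
    v <- runif(60) < 0.5
    coarse <- v[seq(1, 60, by = 2)] | v[seq(2, 60, by = 2)]
    d_fine <- durations_from_series(v, 1)
    d_coarse <- durations_from_series(coarse, 2)
    if (length(d_fine))
      expect_gte(mean(d_coarse), mean(d_fine))
  }
})

test_that("contact_table pools events and collapses subunits by pooling", {
  # five subunit copies with equal event counts and per-copy means 10..50
  pairs <- data.frame(resid = rep(1L, 5), subunit = LETTERS[1:5],
                      mol_id = 101:105, lipid_type = "CHOL",
                      stringsAsFactors = FALSE)
  # one run of k frames per copy at dt = 10 -> means 10, 20, 30, 40, 50
  n_frames <- 12
  mat <- matrix(FALSE, 5, n_frames)
  for (i in 1:5) mat[i, seq_len(i)] <- TRUE
  s <- structure(list(pairs = pairs, mat = mat, times = seq_len(n_frames) * 10,
                      dt = 10, cutoff = 0.6,
                      residues = data.frame(subunit = LETTERS[1:5],
                                            resid = rep(1L, 5),
                                            stringsAsFactors = FALSE),
                      lipid_types = "CHOL", n_frames = n_frames),
                 class = "contact_series")
  tab <- contact_table(s, collapse_subunits = TRUE)
  expect_equal(tab$mean_duration_ns[tab$lipid_type == "CHOL"], 30)
  expect_equal(tab$n_events[tab$lipid_type == "CHOL"], 5)
  expect_equal(tab$max_duration_ns[tab$lipid_type == "CHOL"], 50)
  # occupancy: copies contact 1..5 of 12 frames; mean over 5 copies
  expect_equal(tab$occupancy, sum(1:5) / (12 * 5))

  tab2 <- contact_table(s, collapse_subunits = FALSE)
  expect_equal(sort(tab2$mean_duration_ns), c(10, 20, 30, 40, 50))
})

test_that("single-molecule table equals the series mean and occupancy invariant holds", {
  fx <- contact_fixture(0.5, n_frames = 8)
  cs <- contact_series(fx$trajectory, fx$topology)
  cs$mat[1, ] <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)
  tab <- contact_table(cs, collapse_subunits = FALSE)
  row <- tab[tab$n_events > 0, ]
  durs <- durations_from_series(cs$mat[1, ], cs$dt)
  expect_equal(row$mean_duration_ns, mean(durs))
  # occupancy == sum of event durations / window length, exactly
  expect_equal(row$occupancy, sum(durs / cs$dt) / cs$n_frames)
})

test_that("lipid_hierarchy sorts by the chosen statistic and flags ties", {
  tab <- data.frame(residue = rep(1:30, 3), subunit = NA,
                    lipid_type = rep(c("CHOL", "DOPS", "POPC"), each = 30),
                    mean_duration_ns = c(seq(50, 21, -1), seq(30, 1, -1),
                                         rep(10, 30)),
                    n_events = 1, max_duration_ns = 1, occupancy = 0.1)
  class(tab) <- c("contact_table", "data.frame")
  h <- lipid_hierarchy(tab, "max")
  expect_identical(as.character(h), c("CHOL", "DOPS", "POPC"))
  expect_false(attr(h, "ties"))
  h2 <- lipid_hierarchy(tab, "mean-top-20")
  expect_identical(as.character(h2), c("CHOL", "DOPS", "POPC"))
  expect_equal(unname(attr(h2, "summary")), c(mean(50:31), mean(30:11), 10))
  # exact tie keeps input order and is flagged
  tab$mean_duration_ns[tab$lipid_type == "DOPS"] <-
    tab$mean_duration_ns[tab$lipid_type == "CHOL"]
  h3 <- lipid_hierarchy(tab, "max")
  expect_true(attr(h3, "ties"))
  expect_identical(as.character(h3)[1:2], c("CHOL", "DOPS"))
})

test_that("B-factor export writes durations and warns on unmapped residues", {
  sys <- small_protein_system(seed = 21, nominal = 8)
  pdbf <- withr::local_tempfile(fileext = ".pdb")
  pro <- sys$topology$mol_class == "protein"
  bio3d::write.pdb(xyz = as.numeric(t(sys$coords[pro, ])) * 10,
                   resno = sys$topology$resid[pro],
                   chain = sys$topology$subunit[pro],
                   resid = sys$topology$resname[pro],
                   elety = rep("CA", sum(pro)), file = pdbf)
  resids <- sort(unique(sys$topology$resid[pro]))
  tab <- data.frame(residue = resids[-1], subunit = NA_character_,
                    lipid_type = "CHOL",
                    mean_duration_ns = seq_along(resids[-1]) + 0.25,
                    n_events = 1, max_duration_ns = 2, occupancy = 0.1)
  class(tab) <- c("contact_table", "data.frame")
  attr(tab, "collapse_subunits") <- TRUE
  out <- withr::local_tempfile(fileext = ".pdb")
  expect_warning(export_bfactor(tab, "CHOL", pdbf, out), "1 structure residue")
  back <- bio3d::read.pdb(out)
  got <- back$atom$b[match(resids, back$atom$resno)]
  expect_equal(got[-1], tab$mean_duration_ns, tolerance = 0.01)
  expect_equal(got[1], 0)
  # all-zero table maps to all-zero B-factors
  tabz <- tab; tabz$mean_duration_ns <- 0
  tabz$residue <- tabz$residue  # keep mapping
  expect_warning(export_bfactor(tabz, "CHOL", pdbf, out))
  expect_true(all(bio3d::read.pdb(out)$atom$b == 0))
})
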