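# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

# Construct a density_grid2d directly from a function of (x, y).
grid2d_from_fn <- function(f, n = 100, h = 0.2, org = c(0, 0)) {
  cx <- org[1] + (seq_len(n) - 0.5) * h
  cy <- org[2] + (seq_len(n) - 0.5) * h
  structure(list(origin = org, bin_size = h, values = outer(cx, cy, f),
                 axis = c(org[1] + n * h / 2, org[2] + n * h / 2),
                 metadata = list(kind = "2d")),
            class = "density_grid2d")
}

# Construct a density_grid3d directly from an array.
grid3d_from_array <- function(values, h = 0.2, org = c(0, 0, 0), axis = NULL) {
  n <- dim(values)
  structure(list(origin = org, voxel_size = h, values = values,
                 axis = axis %||% c(org[1] + n[1] * h / 2, org[2] + n[2] * h / 2),
                 metadata = list(kind = "3d")),
            class = "density_grid3d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer matrix power (rotation composition in tests)
`%^%` <- function(m, k) Reduce(`%*%`, replicate(k, m, simplify = FALSE))

# Minimal two-lipid topology (one POPC extracellular, one CHOL intracellular)
# with a static trajectory; used by density and leaflet unit tests.
two_lipid_system <- function(n_frames = 100, box = hexagonal_box(10)) {
  top <- topology(data.frame(
    bead_id = 1:3,
    bead_name = c("PO4", "C1A", "ROH"),
    mol_id = c(1L, 1L, 2L),
    mol_class = "lipid",
    lipid_type = c("POPC", "POPC", "CHOL"),
    resid = c(1L, 1L, 2L),
    resname = c("POPC", "POPC", "CHOL"),
    subunit = NA_character_,
    role = c("phosphate", "tail", "hydroxyl"),
    stringsAsFactors = FALSE))
  coords <- rbind(c(3, 3, 6.8), c(3, 3, 6.3), c(6, 4, 3.2))
  arr <- array(NA_real_, c(n_frames, 3, 3))
  for (f in seq_len(n_frames)) arr[f, , ] <- coords
  list(topology = top,
       trajectory = new_trajectory(times = seq_len(n_frames), coords = arr,
                                   box = box))
}

# A toy protein + lipids system small enough for brute-force oracles.
small_protein_system <- function(seed = 1, nominal = 20, box_a = 9) {
  build_membrane(neuronal_membrane_spec(nominal_per_leaflet = nominal),
                 pentamer = build_pentamer(n_res_per_helix = 4),
                 box = hexagonal_box(box_a), seed = seed)
}

expect_same_contacts <- function(a, b) {
  key <- function(s) order(s$pairs$subunit, s$pairs$resid, s$pairs$mol_id)
  expect_equal(s_a <- a$pairs[key(a), ], s_b <- b$pairs[key(b), ],
               ignore_attr = TRUE)
  expect_identical(a$mat[key(a), , drop = FALSE], b$mat[key(b), , drop = FALSE])
}
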