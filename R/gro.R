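# GRO coordinate file reader/writer (GROMACS fixed-width format, nm).
# Hand-written because no installed R package handles GRO. Velocities are
# neither read nor written. Protein subunits are encoded in the residue
# number (subunit k occupies resid k*1000 + 1..999), since GRO has no chain
# field; the reader decodes this convention.

#' Read a GRO coordinate file
#'
#' @param path GRO file.
#' @return list with `atoms` (bead_name, resid, resname, chain), `coords`
#'   (n x 3 nm) and `box` (3x3 lattice vectors).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stopf("format error in %s: fewer than 3 lines", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0) stopf("format error in %s at line 2: bad atom count", path)
  if (length(lines) < n + 3) {
    # fewer lines than declared: report the first line that fails to parse
    # as an atom (often the box line arriving too early)
    avail <- lines[seq(3, min(2 + n, length(lines)))]
    short <- which(nchar(avail) < 44)
    at <- if (length(short)) short[1] + 2 else length(lines) + 1
    stopf("format error in %s at line %d: expected %d atom lines plus a box line",
          path, at, n)
  }
  al <- lines[3:(2 + n)]
  bad <- which(nchar(al) < 44)
  if (length(bad))
    stopf("format error in %s at line %d: truncated atom line", path, bad[1] + 2)
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  bead_name <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stopf("format error in %s at line %d: unparseable atom fields", path, bad[1] + 2)
  bv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  if (any(is.na(bv)) || !(length(bv) %in% c(3, 9)))
    stopf("format error in %s at line %d: bad box line", path, n + 3)
  box <- if (length(bv) == 3) diag(bv) else
    matrix(c(bv[1], bv[4], bv[5],
             bv[6], bv[2], bv[7],
             bv[8], bv[9], bv[3]), nrow = 3, byrow = TRUE)
  # Decode subunit chain labels from the resid offset convention.
  chain <- ifelse(resid > 1000 | (bead_name == "BB" | grepl("^SC", bead_name)),
                  LETTERS[1 + (pmax(resid, 1) - 1) %/% 1000], NA_character_)
  list(atoms = data.frame(bead_name = bead_name, resid = resid,
                          resname = resname, chain = chain,
                          stringsAsFactors = FALSE),
       coords = cbind(x, y, z), box = box)
}

#' Write a GRO coordinate file
#'
#' @param topology [topology()] object.
#' @param coords n x 3 coordinate matrix (nm).
#' @param box 3x3 lattice-vector matrix.
#' @param path output file.
#' @param title header line.
#' @export
write_gro <- function(topology, coords, box, path, title = "lipmap system") {
  stopifnot(nrow(topology) == nrow(coords))
  check_box(box)
  resid_out <- topology$resid
  pro <- topology$mol_class == "protein"
  resid_out[pro] <- topology$resid[pro] +
    1000L * (match(topology$subunit[pro], LETTERS) - 1L)
  resid_out <- resid_out %% 100000L
  lines <- c(title, sprintf("%5d", nrow(topology)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resid_out,
                     substr(topology$resname, 1, 5),
                     substr(topology$bead_name, 1, 5),
                     topology$bead_id %% 100000L,
                     coords[, 1], coords[, 2], coords[, 3]),
             paste(sprintf("%10.5f", c(box[1, 1], box[2, 2], box[3, 3],
                                       box[1, 2], box[1, 3], box[2, 1],
                                       box[2, 3], box[3, 1], box[3, 2])),
                   collapse = ""))
  tryCatch(writeLines(lines, path),
           error = function(e) stopf("I/O error writing %s: %s", path, conditionMessage(e)))
  invisible(path)
}

# PDB coordinate reading via bio3d (Angstrom -> nm). Returns the same shape
# as read_gro(). Box from CRYST1 when present, else a bounding cube.
read_pdb_system <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  coords <- cbind(a$x, a$y, a$z) / 10
  box <- NULL
  if (!is.null(pdb$cryst1) && !is.null(pdb$cryst1$abc) &&
      all(is.finite(pdb$cryst1$abc)) && all(pdb$cryst1$abc > 0)) {
    abc <- pdb$cryst1$abc / 10
    ang <- pdb$cryst1$ang * pi / 180
    box <- cell_to_box(abc[1], abc[2], abc[3], cos(ang[1]), cos(ang[2]), cos(ang[3]))
  }
  if (is.null(box)) {
    span <- apply(coords, 2, function(v) diff(range(v))) + 2
    box <- diag(pmax(span, 1))
  }
  list(atoms = data.frame(bead_name = a$elety, resid = a$resno,
                          resname = a$resid, chain = a$chain,
                          stringsAsFactors = FALSE),
       coords = coords, box = box)
}

# Lattice vectors from cell lengths and angle cosines, first vector along x,
# second in the xy-plane (the GROMACS/crystallographic convention).
cell_to_box <- function(a, b, c, cos_alpha, cos_beta, cos_gamma) {
  sin_gamma <- sqrt(max(0, 1 - cos_gamma^2))
  v2y <- b * sin_gamma
  v3x <- c * cos_beta
  v3y <- if (v2y > 0) c * (cos_alpha - cos_beta * cos_gamma) / sin_gamma else 0
  v3z <- sqrt(max(0, c^2 - v3x^2 - v3y^2))
  matrix(c(a, 0, 0, b * cos_gamma, v2y, 0, v3x, v3y, v3z), nrow = 3, byrow = TRUE)
}

box_to_cell <- function(box) {
  a <- sqrt(sum(box[1, ]^2)); b <- sqrt(sum(box[2, ]^2)); c <- sqrt(sum(box[3, ]^2))
  c(a = a, b = b, c = c,
    cos_alpha = sum(box[2, ] * box[3, ]) / (b * c),
    cos_beta = sum(box[1, ] * box[3, ]) / (a * c),
    cos_gamma = sum(box[1, ] * box[2, ]) / (a * b))
}
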