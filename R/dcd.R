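# DCD binary trajectory writer/reader (CHARMM-style Fortran records, with
# per-frame unit-cell records). Coordinates are stored in Angstrom as
# float32, the format's convention; lipmap converts to/from nm. Frame times
# are encoded through the header's first-step/save-interval/delta fields and
# must be uniformly spaced (the format cannot express anything else).
# bio3d::read.dcd reads these files and is used as an independent
# cross-check in the test-suite.

write_record <- function(con, payload_writer, nbytes) {
  writeBin(as.integer(nbytes), con, size = 4)
  payload_writer()
  writeBin(as.integer(nbytes), con, size = 4)
}

float_bits_as_int <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4), "integer", size = 4)
}

int_bits_as_float <- function(i) {
  readBin(writeBin(as.integer(i), raw(), size = 4), "numeric", size = 4)
}

#' Write a trajectory as DCD
#'
#' @param trajectory a [new_trajectory()] object; frame times must be
#'   uniformly spaced (warned and approximated otherwise).
#' @param path output file.
#' @export
write_dcd_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  n_frames <- trajectory$n_frames
  if (n_frames < 1) stopf("refusing to write an empty trajectory")
  n_atoms <- dim(trajectory$coords)[2]
  times <- trajectory$times
  delta <- if (n_frames > 1) diff(times)[1] else max(times[1], 1)
  if (n_frames > 2 && max(abs(diff(diff(times)))) > 1e-6 * max(delta, 1))
    warnf("DCD stores uniform frame spacing; non-uniform times approximated")
  if (delta <= 0) delta <- 1
  first_step <- round(times[1] / delta)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stopf("I/O error opening %s", path))
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- n_frames
  icntrl[2] <- first_step
  icntrl[3] <- 1                      # frames every save interval
  icntrl[4] <- first_step + n_frames - 1
  icntrl[10] <- float_bits_as_int(delta)   # time per step, ns
  icntrl[11] <- 1                     # unit-cell records present
  icntrl[20] <- 24                    # CHARMM version tag
  write_record(con, function() {
    writeBin(charToRaw("CORD"), con)
    writeBin(as.integer(icntrl), con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "lipmap trajectory (lengths Angstrom, times ns)")
  write_record(con, function() {
    writeBin(1L, con, size = 4)
    writeBin(charToRaw(title), con)
  }, 84)
  write_record(con, function() writeBin(as.integer(n_atoms), con, size = 4), 4)

  for (f in seq_len(n_frames)) {
    cell <- box_to_cell(frame_box(trajectory, f))
    xtl <- c(cell["a"], cell["cos_gamma"], cell["b"],
             cell["cos_beta"], cell["cos_alpha"], cell["c"]) *
      c(10, 1, 10, 1, 1, 10)
    write_record(con, function() writeBin(as.numeric(xtl), con, size = 8), 48)
    x <- frame_coords(trajectory, f) * 10
    for (d in 1:3)
      write_record(con, function() writeBin(as.numeric(x[, d]), con, size = 4),
                   4 * n_atoms)
  }
  invisible(path)
}

read_check_marker <- function(con, expected, what, path) {
  m <- readBin(con, "integer", 1, size = 4)
  if (!length(m) || m != expected)
    stopf("format error in %s: bad %s record marker (got %s, expected %d)",
          path, what, if (length(m)) m else "EOF", expected)
}

#' Read a DCD trajectory
#'
#' @param path DCD file written by [write_dcd_trajectory()] or another
#'   CHARMM-convention writer with unit-cell records.
#' @return a [new_trajectory()] object (nm, ns).
#' @export
read_dcd_trajectory <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  read_check_marker(con, 84, "header", path)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "CORD") stopf("format error in %s: not a DCD file", path)
  icntrl <- readBin(con, "integer", 20, size = 4)
  read_check_marker(con, 84, "header", path)
  n_frames <- icntrl[1]
  first_step <- icntrl[2]
  nsavc <- max(icntrl[3], 1)
  delta <- int_bits_as_float(icntrl[10])
  has_cell <- icntrl[11] != 0
  tlen <- readBin(con, "integer", 1, size = 4)
  readBin(con, "raw", tlen)
  readBin(con, "integer", 1, size = 4)
  read_check_marker(con, 4, "natoms", path)
  n_atoms <- readBin(con, "integer", 1, size = 4)
  read_check_marker(con, 4, "natoms", path)

  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  boxes <- array(NA_real_, c(n_frames, 3, 3))
  for (f in seq_len(n_frames)) {
    if (has_cell) {
      read_check_marker(con, 48, sprintf("cell (frame %d)", f), path)
      xtl <- readBin(con, "numeric", 6, size = 8)
      read_check_marker(con, 48, "cell", path)
      boxes[f, , ] <- cell_to_box(xtl[1] / 10, xtl[3] / 10, xtl[6] / 10,
                                  xtl[5], xtl[4], xtl[2])
    } else boxes[f, , ] <- diag(3)
    for (d in 1:3) {
      read_check_marker(con, 4 * n_atoms, sprintf("coordinates (frame %d)", f), path)
      coords[f, , d] <- readBin(con, "numeric", n_atoms, size = 4) / 10
      read_check_marker(con, 4 * n_atoms, "coordinates", path)
    }
  }
  if (!is.finite(delta) || delta <= 0) delta <- 1
  times <- (first_step + (seq_len(n_frames) - 1) * nsavc) * delta
  new_trajectory(times = times, coords = coords, box = boxes)
}
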