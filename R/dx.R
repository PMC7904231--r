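# Volumetric / map export: OpenDX scalar fields for 3D grids, CSV matrices
# with a metadata header for 2D grids. Lengths stay in nm (recorded in the
# header comments).

#' Export a density grid
#'
#' 3D grids are written in OpenDX scalar-field format (x slowest, z fastest,
#' the convention of common density tools); 2D grids as CSV matrices with
#' `#`-prefixed metadata header lines.
#'
#' @param grid `density_grid3d` (OpenDX) or `density_grid2d` (CSV).
#' @param path output file.
#' @export
export_density <- function(grid, path) {
  if (inherits(grid, "density_grid3d")) export_density_dx(grid, path)
  else if (inherits(grid, "density_grid2d")) export_density_csv(grid, path)
  else stopf("not a density grid")
}

export_density_dx <- function(grid, path) {
  n <- dim(grid$values)
  if (prod(n) == 0 || is.null(grid$values)) stopf("refusing to export an empty grid")
  h <- grid$voxel_size
  # DX order: x slowest, z fastest == column-major order of the [z, y, x]
  # permutation.
  vals <- as.numeric(aperm(grid$values, c(3, 2, 1)))
  meta <- grid$metadata
  header <- c(
    sprintf("# lipmap density export (units %s, lengths nm)", meta$units %||% ""),
    sprintf("# lipid_type=%s role=%s n_frames=%s", meta$lipid_type %||% "NA",
            meta$role_selector %||% "any", meta$n_frames %||% "NA"),
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1] + h / 2, grid$origin[2] + h / 2, grid$origin[3] + h / 2),
    sprintf("delta %.6f 0 0", h), sprintf("delta 0 %.6f 0", h),
    sprintf("delta 0 0 %.6f", h),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(n)))
  body <- vapply(split(vals, (seq_along(vals) - 1) %/% 3),
                 function(v) paste(sprintf("%.8g", v), collapse = " "), "")
  tryCatch(writeLines(c(header, body,
                        'attribute "dep" string "positions"',
                        'object "density" class field'), path),
           error = function(e) stopf("I/O error writing %s: %s", path, conditionMessage(e)))
  invisible(path)
}

#' Read an OpenDX scalar field written by [export_density()]
#'
#' @param path OpenDX file.
#' @return `density_grid3d` (metadata limited to what the format carries).
#' @export
read_density_dx <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines_nc <- lines[!startsWith(lines, "#")]
  gp <- grep("class gridpositions counts", lines_nc, value = TRUE)[1]
  if (is.na(gp)) stopf("format error in %s: no gridpositions object", path)
  n <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "\\s+")[[1]])
  org <- as.numeric(strsplit(trimws(sub("origin", "", grep("^origin", lines_nc, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- grep("^delta", lines_nc, value = TRUE)
  h <- as.numeric(strsplit(trimws(sub("delta", "", deltas[1])), "\\s+")[[1]])[1]
  data_at <- grep("data follows", lines_nc)[1]
  vals <- numeric(0)
  i <- data_at + 1
  while (i <= length(lines_nc) && !startsWith(lines_nc[i], "attribute") &&
         !startsWith(lines_nc[i], "object")) {
    vals <- c(vals, as.numeric(strsplit(trimws(lines_nc[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  if (length(vals) != prod(n))
    stopf("format error in %s: expected %d values, found %d", path, prod(n), length(vals))
  arr <- array(NA_real_, n)
  arr[cbind(rep(seq_len(n[1]), each = n[2] * n[3]),
            rep(rep(seq_len(n[2]), each = n[3]), n[1]),
            rep(seq_len(n[3]), n[1] * n[2]))] <- vals
  structure(list(origin = org - h / 2, voxel_size = h, values = arr,
                 axis = c(org[1] - h / 2 + n[1] * h / 2, org[2] - h / 2 + n[2] * h / 2),
                 metadata = list(kind = "3d", source = path)),
            class = "density_grid3d")
}

export_density_csv <- function(grid, path) {
  if (is.null(grid$values) || prod(dim(grid$values)) == 0)
    stopf("refusing to export an empty grid")
  meta <- grid$metadata
  header <- c(sprintf("# lipmap 2D density (units %s, lengths nm)", meta$units %||% ""),
              sprintf("# lipid_type=%s leaflet=%s n_frames=%s",
                      meta$lipid_type %||% "NA", meta$leaflet %||% "NA",
                      meta$n_frames %||% "NA"),
              sprintf("# origin=%.6f,%.6f bin_size=%.6f", grid$origin[1],
                      grid$origin[2], grid$bin_size))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(grid$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a 2D density CSV written by [export_density()]
#'
#' @param path CSV file.
#' @return `density_grid2d`.
#' @export
read_density_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^# origin=", lines, value = TRUE)[1]
  m <- regmatches(hdr, regexec("origin=([-0-9.eE]+),([-0-9.eE]+) bin_size=([-0-9.eE]+)", hdr))[[1]]
  vals <- as.matrix(utils::read.csv(text = lines[!startsWith(lines, "#")],
                                    header = FALSE))
  dimnames(vals) <- NULL
  structure(list(origin = as.numeric(m[2:3]), bin_size = as.numeric(m[4]),
                 values = vals,
                 axis = as.numeric(m[2:3]) + dim(vals) * as.numeric(m[4]) / 2,
                 metadata = list(kind = "2d", source = path)),
            class = "density_grid2d")
}
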