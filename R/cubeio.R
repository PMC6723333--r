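#' Write a voxel cube to disk
#'
#' Raw little-endian float64 in x-fastest order (`<prefix>.f64`) plus a
#' JSON sidecar (`<prefix>.json`) recording shape, extent, voxel size,
#' units, class and any run metadata.
#'
#' @param cube a [VoxelCube-class] (or subclass).
#' @param prefix output path without extension.
#' @return the sidecar path, invisibly.
#' @export
writeCube <- function(cube, prefix) {
  grid <- cube@grid
  meta <- list(class = class(cube)[1],
               shape = as.integer(grid@n_cells),
               extent_mm = list(lo = grid@extent[, 1], hi = grid@extent[, 2]),
               voxel_mm = voxelSize(grid),
               units = cube@units,
               order = "x-fastest")
  if (is(cube, "DepositionCube"))
    meta <- c(meta, list(power_W = cube@power, packets = cube@packets,
                         seed = cube@seed,
                         absorbed_weight = cube@absorbed_weight,
                         escaped_weight = cube@escaped_weight))
  if (is(cube, "TemperatureField")) meta$time_s <- cube@time
  bin <- paste0(prefix, ".f64")
  con <- file(bin, "wb")
  writeBin(as.numeric(cube@values), con, size = 8, endian = "little")
  close(con)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}

#' Read a voxel cube written by [writeCube()]
#'
#' @param prefix path without extension.
#' @return the cube, restored to its recorded class.
#' @export
readCube <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  n <- as.integer(meta$shape)
  con <- file(paste0(prefix, ".f64"), "rb")
  vals <- readBin(con, "numeric", prod(n), size = 8, endian = "little")
  close(con)
  grid <- voxelGridDef(cbind(meta$extent_mm$lo, meta$extent_mm$hi), n)
  values <- array(vals, dim = n)
  switch(meta$class,
    DepositionCube = new("DepositionCube", grid = grid, values = values,
                         units = meta$units, power = meta$power_W,
                         packets = meta$packets, seed = meta$seed,
                         absorbed_weight = meta$absorbed_weight,
                         escaped_weight = meta$escaped_weight),
    TemperatureField = new("TemperatureField", grid = grid, values = values,
                           units = meta$units, time = meta$time_s),
    DoseCube = new("DoseCube", grid = grid, values = values,
                   units = meta$units),
    KillMap = new("KillMap", grid = grid, values = values,
                  units = meta$units),
    new("VoxelCube", grid = grid, values = values, units = meta$units))
}

#' Export a cube as legacy VTK structured points
#'
#' ASCII legacy-VTK file for quick inspection in ParaView or similar.
#'
#' @param cube a [VoxelCube-class].
#' @param path output .vtk file.
#' @param name data-array name.
#' @return `path`, invisibly.
#' @export
writeVTK <- function(cube, path, name = "value") {
  grid <- cube@grid
  n <- grid@n_cells
  h <- voxelSize(grid)
  o <- grid@extent[, 1] + h / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "phototherm cube", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %g %g %g", o[1], o[2], o[3]),
               sprintf("SPACING %g %g %g", h[1], h[2], h[3]),
               sprintf("POINT_DATA %d", prod(n)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  vals <- as.numeric(cube@values)
  vals[is.na(vals)] <- -1
  writeLines(paste(formatC(vals, format = "g", digits = 9)), con)
  invisible(path)
}
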