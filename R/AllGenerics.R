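#' @rdname cubeValues
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' Extract the per-voxel value array of a cube
#'
#' @param x a [VoxelCube-class] (or subclass).
#' @return numeric array with dim = `nCells(voxelGrid(x))`.
#' @rdname cubeValues
#' @export
setMethod("cubeValues", "VoxelCube", function(x) x@values)

#' @rdname voxelGrid
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' Extract the voxel grid of an object
#'
#' @param x a cube or [ThermalHistory-class].
#' @return the [VoxelGrid-class].
#' @rdname voxelGrid
#' @export
setMethod("voxelGrid", "VoxelCube", function(x) x@grid)

#' @rdname voxelGrid
#' @export
setMethod("voxelGrid", "ThermalHistory", function(x) x@grid)

#' Voxel edge lengths, volume, counts and centres
#'
#' `voxelSize` returns the edge lengths (mm), `voxelVolume` the voxel
#' volume (mm^3), `nCells` the per-axis cell counts, and `voxelCenters`
#' the centre coordinates (mm) along one axis.
#'
#' @param grid a [VoxelGrid-class].
#' @param axis 1, 2, 3 or "x", "y", "z".
#' @return numeric vector (or scalar for `voxelVolume`).
#' @export
voxelSize <- function(grid) {
  as.numeric((grid@extent[, 2] - grid@extent[, 1]) / grid@n_cells)
}

#' @rdname voxelSize
#' @export
voxelVolume <- function(grid) prod(voxelSize(grid))

#' @rdname voxelSize
#' @export
nCells <- function(grid) grid@n_cells

#' @rdname voxelSize
#' @export
voxelCenters <- function(grid, axis) {
  a <- axisIndex(axis)
  h <- voxelSize(grid)[a]
  grid@extent[a, 1] + (seq_len(grid@n_cells[a]) - 0.5) * h
}

axisIndex <- function(axis) {
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  axis <- as.integer(axis)
  if (is.na(axis) || axis < 1 || axis > 3)
    stop("axis must be 1..3 or one of 'x', 'y', 'z'")
  axis
}

setMethod("show", "OpticalMaterial", function(object) {
  cat(sprintf(
    "OpticalMaterial '%s': mu_a=%g cm^-1, mu_s=%g cm^-1, g=%g, n=%g\n",
    object@name, object@mu_a, object@mu_s, object@g, object@n))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces, volume %.4g mm^3\n",
              nrow(object@vertices), nrow(object@faces),
              meshVolume(object)))
})

setMethod("show", "VoxelGrid", function(object) {
  h <- voxelSize(object)
  cat(sprintf("VoxelGrid: %d x %d x %d cells, voxel %.4g x %.4g x %.4g mm\n",
              object@n_cells[1], object@n_cells[2], object@n_cells[3],
              h[1], h[2], h[3]))
})

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d materials, %d entities (ambient '%s')\n",
              length(object@materials), length(object@entities),
              object@ambient))
  cat(sprintf("  source: disc r=%g mm, %g W\n", object@source@radius,
              object@source@power))
  show(object@grid)
})

setMethod("show", "VoxelCube", function(object) {
  v <- object@values
  cat(sprintf("%s [%s]: %d x %d x %d, range [%.4g, %.4g]\n",
              class(object), object@units, dim(v)[1], dim(v)[2], dim(v)[3],
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "DepositionCube", function(object) {
  callNextMethod()
  cat(sprintf("  N=%g packets, L=%g W, absorbed %.4g, escaped %.4g\n",
              object@packets, object@power, object@absorbed_weight,
              object@escaped_weight))
})

setMethod("show", "ThermalHistory", function(object) {
  cat(sprintf("ThermalHistory: %d snapshots over %g s\n",
              length(object@times), max(object@times)))
})
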