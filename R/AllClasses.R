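#' @import methods
NULL

#' Optical material
#'
#' A participating medium for photon transport: absorption coefficient
#' `mu_a` and scattering coefficient `mu_s` (both cm^-1, as conventionally
#' tabulated), Henyey-Greenstein anisotropy `g`, and refractive index `n`.
#' The interaction coefficient is `mu = mu_a + mu_s`.
#'
#' @slot name label.
#' @slot mu_a absorption coefficient (cm^-1).
#' @slot mu_s scattering coefficient (cm^-1).
#' @slot g scattering anisotropy (mean deflection cosine, -1..1).
#' @slot n refractive index (>= 1).
#' @exportClass OpticalMaterial
setClass("OpticalMaterial",
  representation(name = "character", mu_a = "numeric", mu_s = "numeric",
                 g = "numeric", n = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mu_a) != 1 || !is.finite(object@mu_a) || object@mu_a < 0)
      msg <- c(msg, "mu_a must be a single non-negative number")
    if (length(object@mu_s) != 1 || !is.finite(object@mu_s) || object@mu_s < 0)
      msg <- c(msg, "mu_s must be a single non-negative number")
    if (length(object@g) != 1 || !is.finite(object@g) || abs(object@g) > 1)
      msg <- c(msg, "g must lie in [-1, 1]")
    if (length(object@n) != 1 || !is.finite(object@n) || object@n < 1)
      msg <- c(msg, "n must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Pennes bioheat parameters
#'
#' Thermal constants of the perfused-tissue heat equation
#' \eqn{\rho c \, \partial T/\partial t = \nabla(k \nabla T) - B(T - T_a) + Q}
#' with the lumped perfusion coefficient \eqn{B = c_b w_b \rho_b}.
#'
#' @slot rho tissue density (kg/m^3).
#' @slot c tissue specific heat capacity (J/(kg K)).
#' @slot k thermal conductivity (W/(m K)).
#' @slot rho_b blood density (kg/m^3).
#' @slot c_b blood specific heat capacity (J/(kg K)).
#' @slot w_b blood perfusion rate (1/s).
#' @slot T_a blood (arterial) temperature (degrees C).
#' @exportClass BioheatParams
setClass("BioheatParams",
  representation(rho = "numeric", c = "numeric", k = "numeric",
                 rho_b = "numeric", c_b = "numeric", w_b = "numeric",
                 T_a = "numeric"),
  validity = function(object) {
    pos <- c(rho = object@rho, c = object@c, rho_b = object@rho_b,
             c_b = object@c_b)
    if (any(!is.finite(pos)) || any(pos <= 0))
      return("rho, c, rho_b, c_b must all be positive")
    if (!is.finite(object@k) || object@k < 0)
      return("k must be non-negative")
    if (!is.finite(object@w_b) || object@w_b < 0)
      return("w_b must be non-negative")
    if (!is.finite(object@T_a)) return("T_a must be finite")
    TRUE
  })

#' Triangle mesh
#'
#' Vertices in mm and 1-based vertex-index triplets. Volume entities must
#' be watertight and consistently outward-oriented (positive signed
#' volume); [isWatertight()] checks both.
#'
#' @slot vertices numeric matrix (n x 3), mm.
#' @slot faces integer matrix (m x 3), 1-based vertex indices.
#' @exportClass TriangleMesh
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    if (ncol(object@vertices) != 3) return("vertices must be n x 3")
    if (ncol(object@faces) != 3) return("faces must be m x 3")
    f <- object@faces
    if (any(f < 1) || any(f > nrow(object@vertices)))
      return("face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      return("degenerate faces (repeated vertex index)")
    TRUE
  })

#' Scene entity
#'
#' A geometric body bound to an optical material. Built-in shapes
#' ("cuboid", "ellipsoid") carry analytic parameters used by the transport
#' engine in addition to their triangle mesh; imported STL bodies use the
#' mesh alone. Nested entities (tumour inside flesh inside air) are
#' resolved by explicit priority: the highest-priority entity containing a
#' point supplies its material.
#'
#' @slot label entity name.
#' @slot shape "cuboid", "ellipsoid" or "mesh".
#' @slot params named list of analytic parameters (center, size/semi_axes).
#' @slot mesh [TriangleMesh-class] boundary representation.
#' @slot material name of the entity's [OpticalMaterial-class].
#' @slot priority integer; larger wins point queries.
#' @exportClass Entity
setClass("Entity",
  representation(label = "character", shape = "character", params = "list",
                 mesh = "TriangleMesh", material = "character",
                 priority = "integer"))

#' Light source
#'
#' A planar triangle-fan disc emitter. Packets are emitted from
#' area-uniform random points on the fan, travelling along the surface
#' normal.
#'
#' @slot mesh fan mesh ([TriangleMesh-class]).
#' @slot center disc centre (mm).
#' @slot radius disc radius (mm).
#' @slot n_fan number of fan triangles.
#' @slot direction unit emission direction.
#' @slot power radiant power L (W).
#' @exportClass LightSource
setClass("LightSource",
  representation(mesh = "TriangleMesh", center = "numeric",
                 radius = "numeric", n_fan = "integer",
                 direction = "numeric", power = "numeric"),
  validity = function(object) {
    if (object@radius <= 0) return("radius must be positive")
    if (object@power <= 0) return("power must be positive")
    if (object@n_fan < 3L) return("n_fan must be >= 3")
    TRUE
  })

#' Cartesian voxel grid
#'
#' Uniform partition of a cuboid domain.
#'
#' @slot extent 3 x 2 matrix of domain bounds (mm): rows x, y, z; columns
#'   lo, hi.
#' @slot n_cells integer cells per axis.
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(extent = "matrix", n_cells = "integer"),
  validity = function(object) {
    if (!all(dim(object@extent) == c(3, 2))) return("extent must be 3 x 2")
    if (any(object@extent[, 2] <= object@extent[, 1]))
      return("extent hi must exceed lo on every axis")
    if (length(object@n_cells) != 3 || any(object@n_cells < 1))
      return("n_cells must be 3 positive integers")
    TRUE
  })

#' Simulation scene
#'
#' Materials, nested entities, the light source and the recording grid.
#'
#' @slot materials named list of [OpticalMaterial-class].
#' @slot entities list of [Entity-class], any order.
#' @slot ambient name of the material filling unclaimed space (air).
#' @slot source [LightSource-class].
#' @slot grid [VoxelGrid-class].
#' @exportClass Scene
setClass("Scene",
  representation(materials = "list", entities = "list", ambient = "character",
                 source = "LightSource", grid = "VoxelGrid"),
  validity = function(object) {
    refd <- c(vapply(object@entities, function(e) e@material, ""),
              object@ambient)
    missing <- setdiff(refd, names(object@materials))
    if (length(missing))
      return(paste("entities reference undefined materials:",
                   paste(missing, collapse = ", ")))
    pri <- vapply(object@entities, function(e) e@priority, 1L)
    if (anyDuplicated(pri))
      return("entity priorities must be distinct")
    TRUE
  })

#' Voxel data cube
#'
#' Base class for per-voxel fields on a [VoxelGrid-class]; `values` is an
#' array with dim = n_cells (x, y, z).
#'
#' @slot grid [VoxelGrid-class].
#' @slot values numeric array.
#' @slot units unit string.
#' @exportClass VoxelCube
setClass("VoxelCube",
  representation(grid = "VoxelGrid", values = "array", units = "character"),
  validity = function(object) {
    if (!all(dim(object@values) == object@grid@n_cells))
      return("values dim must equal grid n_cells")
    TRUE
  })

#' Absorbed power density cube
#'
#' Track-length estimate of volumetric absorbed power (W/m^3) from a
#' transport run; the Q source term of the bioheat equation. Also records
#' the statistical-weight ledger of the run.
#'
#' @slot power source power L (W).
#' @slot packets packet count N.
#' @slot seed RNG seed of the run.
#' @slot absorbed_weight total statistical weight deposited.
#' @slot escaped_weight total weight that exited the domain.
#' @exportClass DepositionCube
setClass("DepositionCube", contains = "VoxelCube",
  representation(power = "numeric", packets = "numeric", seed = "numeric",
                 absorbed_weight = "numeric", escaped_weight = "numeric"),
  validity = function(object) {
    if (any(object@values < 0)) return("absorbed power density must be >= 0")
    TRUE
  })

#' Temperature field
#'
#' Per-voxel temperature (degrees C) at one instant of the heating run.
#'
#' @slot time elapsed heating time (s).
#' @exportClass TemperatureField
setClass("TemperatureField", contains = "VoxelCube",
  representation(time = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("temperatures must be finite")
    TRUE
  })

#' Thermal history
#'
#' Temperature snapshots at strictly increasing times, the record the
#' CEM43 dose integral is taken over.
#'
#' @slot grid [VoxelGrid-class].
#' @slot times snapshot times (s), starting at 0.
#' @slot snapshots list of temperature arrays (degrees C).
#' @slot labels integer array: 0 excluded (air), 1 active, 2 clamped.
#' @exportClass ThermalHistory
setClass("ThermalHistory",
  representation(grid = "VoxelGrid", times = "numeric", snapshots = "list",
                 labels = "array"),
  validity = function(object) {
    if (length(object@times) != length(object@snapshots))
      return("times and snapshots must have equal length")
    if (length(object@times) && object@times[1] != 0)
      return("history must start at t = 0")
    if (is.unsorted(object@times, strictly = TRUE))
      return("snapshot times must be strictly increasing")
    TRUE
  })

#' CEM43 thermal dose cube
#'
#' Cumulative equivalent minutes at 43 degrees C per voxel.
#'
#' @exportClass DoseCube
setClass("DoseCube", contains = "VoxelCube",
  validity = function(object) {
    if (any(object@values < 0, na.rm = TRUE)) return("CEM43 must be >= 0")
    TRUE
  })

#' Cell-kill map
#'
#' Estimated percentage cell death per voxel from the calibrated
#' exponential survival model.
#'
#' @exportClass KillMap
setClass("KillMap", contains = "VoxelCube",
  validity = function(object) {
    v <- object@values
    if (any(v < 0 | v > 100, na.rm = TRUE))
      return("death percentage must lie in [0, 100]")
    TRUE
  })
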