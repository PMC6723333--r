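#' Stability-bounded explicit time step
#'
#' Forward-Euler bound for the bioheat stencil,
#' `dt <= safety * rho c / (2 k (1/dx^2 + 1/dy^2 + 1/dz^2) + B)`.
#'
#' @param params a [BioheatParams-class].
#' @param voxel_mm voxel edge lengths (mm), scalar or 3-vector.
#' @param safety safety factor (default 0.9).
#' @param cap upper cap on dt (s), e.g. the record interval; used when
#'   conduction and perfusion are both absent.
#' @return dt in seconds.
#' @export
stableTimestep <- function(params, voxel_mm, safety = 0.9, cap = Inf) {
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  h <- voxel_mm * 1e-3
  B <- perfusionCoefficient(params)
  denom <- 2 * params@k * sum(1 / h^2) + B
  dt <- if (denom > 0) safety * params@rho * params@c / denom else Inf
  min(dt, cap)
}

#' Conduction labels for a scene
#'
#' Classifies voxels for the heat solver: air is excluded (interfaces to
#' it are adiabatic), tissue conducts, and -- in the default
#' "clamped-sides" mode -- the outermost tissue layer on the lateral and
#' bottom faces is clamped at the arterial temperature as a far-field
#' body-temperature condition. The top (skin) face borders air and is
#' left adiabatic. "insulated" clamps nothing.
#'
#' @param scn a [Scene-class].
#' @param grid a [VoxelGrid-class] (default the scene's).
#' @param boundary "clamped-sides" or "insulated".
#' @return integer array: 0 excluded, 1 active, 2 clamped.
#' @export
heatLabels <- function(scn, grid = scn@grid,
                       boundary = c("clamped-sides", "insulated")) {
  boundary <- match.arg(boundary)
  mg <- materialGrid(scn, grid)
  airIdx <- match(scn@ambient, attr(mg, "materials"))
  lab <- array(1L, dim = dim(mg))
  lab[mg == airIdx] <- 0L
  if (boundary == "clamped-sides" && any(lab == 1L)) {
    idx <- which(lab == 1L, arr.ind = TRUE)
    rx <- range(idx[, 1]); ry <- range(idx[, 2]); rz <- range(idx[, 3])
    side <- idx[, 1] == rx[1] | idx[, 1] == rx[2] |
            idx[, 2] == ry[1] | idx[, 2] == ry[2] |
            idx[, 3] == rz[1]  # bottom; the top face (skin) stays adiabatic
    lab[idx[side, , drop = FALSE]] <- 2L
  }
  lab
}

#' Advance the bioheat equation
#'
#' Low-level stepper: `nsteps` forward-Euler updates of
#' \eqn{\rho c \, \partial T/\partial t = k \nabla^2 T - B(T-T_a) + Q}
#' with a 7-point Laplacian. Voxels labelled 0 are excluded (adiabatic
#' interfaces), 2 are held fixed; grid edges are insulated. Perfusion
#' applies only in conducting (label 1) voxels.
#'
#' @param T0 temperature array (degrees C).
#' @param q absorbed power density array (W/m^3).
#' @param labels integer array (0/1/2), same dim.
#' @param voxel_mm voxel edges (mm), scalar or 3-vector.
#' @param params a [BioheatParams-class].
#' @param dt time step (s); must satisfy [stableTimestep()].
#' @param nsteps number of steps.
#' @return the updated temperature array.
#' @export
heatSteps <- function(T0, q, labels, voxel_mm, params, dt, nsteps) {
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  bound <- stableTimestep(params, voxel_mm, safety = 1)
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("dt = %g s exceeds the stability bound %g s", dt, bound))
  dims <- dim(T0)
  act <- which(labels != 0L, arr.ind = TRUE)
  bbox <- if (nrow(act)) {
    c(range(act[, 1]) - 1L, range(act[, 2]) - 1L, range(act[, 3]) - 1L)
  } else c(0L, -1L, 0L, -1L, 0L, -1L)
  out <- heatStepsC(as.numeric(T0), as.numeric(q), as.integer(labels),
                    as.integer(dims), voxel_mm * 1e-3, params@rho, params@c,
                    params@k, perfusionCoefficient(params), params@T_a, dt,
                    as.integer(nsteps),
                    as.integer(bbox[c(1, 2, 3, 4, 5, 6)]))
  array(out, dim = dims)
}

#' Run the heating simulation
#'
#' Integrates the bioheat equation under constant illumination (the
#' deposition cube held fixed), starting from a uniform body temperature,
#' and records temperature snapshots every `record_interval` seconds.
#'
#' @param qcube a [DepositionCube-class] (the Q term, W/m^3).
#' @param scn the [Scene-class] the cube was computed on (supplies the
#'   conduction labels).
#' @param params a [BioheatParams-class].
#' @param duration total heating time (s).
#' @param record_interval snapshot cadence (s, default 20 -- the usual
#'   probe cadence of photothermal experiments).
#' @param boundary boundary mode passed to [heatLabels()].
#' @param T_init initial temperature (degrees C; default `params@T_a`).
#' @param labels optional precomputed label array (overrides `scn`).
#' @return a [ThermalHistory-class] whose first snapshot is the uniform
#'   initial field at t = 0.
#' @export
runHeating <- function(qcube, scn = NULL, params = bioheatParams(),
                       duration, record_interval = 20,
                       boundary = c("clamped-sides", "insulated"),
                       T_init = params@T_a, labels = NULL) {
  stopifnot(duration > 0)
  grid <- qcube@grid
  if (is.null(labels)) {
    if (is.null(scn)) stop("either a scene or a label array is required")
    labels <- heatLabels(scn, grid, match.arg(boundary))
  }
  h <- voxelSize(grid)
  dt_max <- stableTimestep(params, h, cap = record_interval)
  times <- unique(c(seq(0, duration, by = record_interval), duration))
  Tcur <- array(T_init, dim = grid@n_cells)
  snaps <- vector("list", length(times))
  snaps[[1]] <- Tcur
  q <- qcube@values
  for (i in seq_along(times)[-1]) {
    span <- times[i] - times[i - 1]
    nsteps <- ceiling(span / dt_max)
    dt <- span / nsteps
    Tcur <- heatSteps(Tcur, q, labels, h, params, dt, nsteps)
    snaps[[i]] <- Tcur
  }
  new("ThermalHistory", grid = grid, times = times, snapshots = snaps,
      labels = labels)
}

#' Temperature field at a recorded time
#'
#' @param history a [ThermalHistory-class].
#' @param time a recorded snapshot time (s).
#' @return a [TemperatureField-class].
#' @export
temperatureAt <- function(history, time) {
  i <- match(time, history@times)
  if (is.na(i)) stop("time ", time, " s was not recorded")
  new("TemperatureField", grid = history@grid,
      values = history@snapshots[[i]], units = "degC", time = time)
}

#' Temperature-rise summary over a voxel mask
#'
#' Peak and centroid-probe temperature rise above the initial temperature
#' inside a region (typically the tumour), per snapshot.
#'
#' @param history a [ThermalHistory-class].
#' @param mask logical array selecting the region.
#' @param T_ref reference temperature (default: value at t = 0).
#' @return data.frame with `time_s`, `peak_rise_C`, `mean_rise_C`.
#' @export
riseSummary <- function(history, mask, T_ref = history@snapshots[[1]][1]) {
  data.frame(
    time_s = history@times,
    peak_rise_C = vapply(history@snapshots,
                         function(s) max(s[mask]) - T_ref, 0),
    mean_rise_C = vapply(history@snapshots,
                         function(s) mean(s[mask]) - T_ref, 0))
}
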