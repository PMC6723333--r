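#' CEM43 contribution of one exposure interval
#'
#' Cumulative equivalent minutes at 43 degrees C for an interval at
#' average temperature `T_avg`: `dt_min * R^(43 - T_avg)`, with R the
#' per-degree compensation factor above/below the 43 C threshold
#' (Sapareto-Dewey constants 0.5 and 0.25 by default).
#'
#' @param T_avg average temperature over the interval (degrees C); may be
#'   a vector or array.
#' @param dt_min interval length in minutes.
#' @param R_above R for `T_avg >= 43`.
#' @param R_below R for `T_avg < 43`.
#' @return equivalent minutes at 43 C, same shape as `T_avg`.
#' @examples
#' cem43Increment(44, 10) # 20 min
#' cem43Increment(42, 10) # 2.5 min
#' @export
cem43Increment <- function(T_avg, dt_min, R_above = 0.5, R_below = 0.25) {
  stopifnot(all(dt_min >= 0))
  R <- ifelse(T_avg >= 43, R_above, R_below)
  dt_min * R^(43 - T_avg)
}

#' Accumulate CEM43 over a thermal history
#'
#' Sums [cem43Increment()] over consecutive snapshot intervals, using the
#' trapezoidal (midpoint-of-endpoints) average temperature per interval,
#' so the dose represents the entire exposure history.
#'
#' @param history a [ThermalHistory-class] with at least 2 snapshots.
#' @param R_above,R_below per-degree compensation factors.
#' @param cutoff_C optional lower temperature cutoff: intervals with
#'   average temperature below it contribute nothing (default `NULL`, no
#'   cutoff).
#' @return a [DoseCube-class] (minutes).
#' @export
accumulateCem43 <- function(history, R_above = 0.5, R_below = 0.25,
                            cutoff_C = NULL) {
  nt <- length(history@times)
  if (nt < 2) stop("history needs at least two snapshots")
  dose <- array(0, dim = history@grid@n_cells)
  for (i in seq_len(nt - 1)) {
    Tavg <- (history@snapshots[[i]] + history@snapshots[[i + 1]]) / 2
    dt_min <- (history@times[i + 1] - history@times[i]) / 60
    inc <- cem43Increment(Tavg, dt_min, R_above, R_below)
    if (!is.null(cutoff_C)) inc[Tavg < cutoff_C] <- 0
    dose <- dose + inc
  }
  new("DoseCube", grid = history@grid, values = dose, units = "min")
}

#' Cell survival from CEM43 dose
#'
#' Single-exponential survival in equivalent minutes,
#' `S = exp(-lambda * CEM43)`, calibrated so that
#' `S(anchor_minutes) = anchor_fraction` (default: 10% survival after
#' 120 equivalent minutes, the behaviour of human cancer cell lines held
#' at 43 C for 2 h).
#'
#' @param cem43 dose in equivalent minutes (vector/array).
#' @param anchor_minutes calibration dose (min).
#' @param anchor_fraction surviving fraction at the anchor.
#' @return surviving fraction in `[0, 1]`, same shape.
#' @examples
#' survivalFraction(120) # 0.10
#' @export
survivalFraction <- function(cem43, anchor_minutes = 120,
                             anchor_fraction = 0.1) {
  stopifnot(all(cem43 >= 0, na.rm = TRUE))
  lambda <- -log(anchor_fraction) / anchor_minutes
  exp(-lambda * cem43)
}

#' Estimated percentage cell death per voxel
#'
#' @param dose a [DoseCube-class].
#' @param ... passed to [survivalFraction()].
#' @return a [KillMap-class] (percent, 0-100).
#' @export
killMap <- function(dose, ...) {
  pct <- 100 * (1 - survivalFraction(dose@values, ...))
  new("KillMap", grid = dose@grid, values = pct, units = "%")
}

#' Line profile through a cube
#'
#' Ordered samples of a cube along one axis through a fixed point, the
#' presentation used for depth profiles through the tumour centre.
#'
#' @param cube a [VoxelCube-class].
#' @param axis axis to run along (1..3 or "x","y","z").
#' @param at coordinates (mm) on the two fixed axes, in axis order with
#'   the profiled axis omitted.
#' @return data.frame with `position_mm` and `value`.
#' @export
lineProfile <- function(cube, axis = "z", at = c(0, 0)) {
  a <- axisIndex(axis)
  grid <- cube@grid
  others <- setdiff(1:3, a)
  idx <- integer(3)
  for (j in seq_along(others)) {
    o <- others[j]
    cc <- voxelCenters(grid, o)
    if (at[j] < grid@extent[o, 1] || at[j] > grid@extent[o, 2])
      stop("profile point lies outside the domain")
    idx[o] <- which.min(abs(cc - at[j]))
  }
  pos <- voxelCenters(grid, a)
  sel <- lapply(1:3, function(k) if (k == a) seq_len(grid@n_cells[k])
                else idx[k])
  vals <- do.call(`[`, c(list(cube@values), sel))
  data.frame(position_mm = pos, value = as.numeric(vals))
}

#' Mask an entity's voxels out of a cube
#'
#' Sets voxels whose centres fall inside the entity to a sentinel,
#' leaving the rest unchanged -- used to blank the tumour when mapping
#' collateral damage to normal tissue.
#'
#' @param cube a [VoxelCube-class].
#' @param e an [Entity-class].
#' @param sentinel value for masked voxels (default `NA`).
#' @return a cube of the same class with the entity region masked.
#' @export
maskRegion <- function(cube, e, sentinel = NA_real_) {
  m <- entityMask(e, cube@grid)
  v <- cube@values
  v[m] <- sentinel
  initialize(cube, values = v)
}
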