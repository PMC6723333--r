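# Closed-form oracles kept deliberately independent of the engine: they
# share no code with the C++ kernels, so agreement in the tests is a
# genuine cross-check rather than a tautology.

#' Beer-Lambert transmission oracle
#'
#' Transmitted fraction through a purely absorbing slab,
#' `exp(-mu_a * depth)` -- the analytic limit the transport engine must
#' reproduce when scattering is off.
#'
#' @param mu_a absorption coefficient (cm^-1).
#' @param depth slab thickness (cm).
#' @return transmitted fraction.
#' @export
beerLambertOracle <- function(mu_a, depth) {
  stopifnot(mu_a >= 0)
  exp(-mu_a * depth)
}

#' Free-space heat-kernel oracle
#'
#' Normalized Gaussian solution of the heat equation for a unit point
#' release: `(4 pi D t)^(-3/2) exp(-r^2 / (4 D t))` with diffusivity
#' `D = k / (rho c)` -- the analytic limit of the bioheat stepper with no
#' perfusion and no source.
#'
#' @param diffusivity D (m^2/s).
#' @param t time (s), > 0.
#' @param r radial distance (m); vectorized.
#' @return kernel value (1/m^3).
#' @export
heatKernelOracle <- function(diffusivity, t, r) {
  stopifnot(t > 0)
  (4 * pi * diffusivity * t)^(-3 / 2) * exp(-r^2 / (4 * diffusivity * t))
}

#' Perfusion-only heating oracle
#'
#' With conduction off (k = 0), every voxel obeys the ODE
#' `rho c dT/dt = -B (T - Ta) + Q`, whose solution from `T(0) = Ta` is
#' `Ta + (Q/B) (1 - exp(-B t / (rho c)))`.
#'
#' @param params a [BioheatParams-class].
#' @param Q volumetric heating (W/m^3).
#' @param t time (s); vectorized.
#' @return temperature (degrees C).
#' @export
perfusionOdeOracle <- function(params, Q, t) {
  B <- perfusionCoefficient(params)
  stopifnot(B > 0)
  params@T_a + (Q / B) * (1 - exp(-B * t / (params@rho * params@c)))
}

#' Scaled default-scenario run
#'
#' Runs the built-in skin-cancer scenario end to end at a chosen packet
#' count, grid preset and heating duration, and returns the headline
#' quantities: peak in-tumour absorbed power density, and the in-tumour
#' peak temperature rise at 1 s, at the final time, and its maximum over
#' the run.
#'
#' @param packets transport packet count (>= 1e5).
#' @param grid_preset "fast" (101^3) or "full" (201^3).
#' @param duration heating time (s).
#' @param gnr infused tumour (TRUE) or control (FALSE).
#' @param seed RNG seed.
#' @param record_interval snapshot cadence (s).
#' @return list with `q_peak_tumour_W_m3`, `rise_1s_C`, `rise_final_C`,
#'   `rise_max_C`, `rise_centroid_final_C`, the `history`, deposition
#'   cube `q`, tumour `mask` and `scene`.
#' @export
scaledDefaultRun <- function(packets = 1e7, grid_preset = "fast",
                             duration = 600, gnr = TRUE, seed = 1,
                             record_interval = 20) {
  stopifnot(packets >= 1e5)
  cfg <- defaultConfig(gnr = gnr, grid_preset = grid_preset,
                       packets = packets, seed = seed,
                       duration = duration,
                       record_interval = record_interval)
  scn <- buildScene(cfg)
  params <- configBioheatParams(cfg)
  q <- runTransport(scn, packets = packets, seed = seed)
  tum <- Find(function(e) e@label == "tumour", scn@entities)
  mask <- entityMask(tum, scn@grid)

  # short run to catch the 1 s field, then the full heating
  hist1 <- runHeating(q, scn, params, duration = 1, record_interval = 1)
  rise1 <- max(hist1@snapshots[[length(hist1@times)]][mask]) - params@T_a
  history <- runHeating(q, scn, params, duration = duration,
                        record_interval = record_interval)
  rs <- riseSummary(history, mask)
  list(q_peak_tumour_W_m3 = max(q@values[mask]),
       rise_1s_C = rise1,
       rise_final_C = rs$peak_rise_C[nrow(rs)],
       rise_max_C = max(rs$peak_rise_C),
       rise_centroid_final_C = {
         ctr <- tum@params$center
         g <- scn@grid
         idx <- vapply(1:3, function(a)
           which.min(abs(voxelCenters(g, a) - ctr[a])), 1L)
         history@snapshots[[length(history@times)]][idx[1], idx[2], idx[3]] -
           params@T_a
       },
       history = history, q = q, mask = mask, scene = scn, params = params)
}
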