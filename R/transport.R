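#' Sample a free path length
#'
#' Inverse-CDF sample of the exponential flight distance,
#' \eqn{l = -\ln(1-\xi)/\mu}.
#'
#' @param xi uniform deviate(s) in `[0, 1)`.
#' @param mu interaction coefficient (cm^-1), > 0.
#' @return distance(s) in cm.
#' @examples
#' sampleFreePath(1 - exp(-1), 23.5) # 1/23.5 cm
#' @export
sampleFreePath <- function(xi, mu) {
  if (mu <= 0)
    stop("mu must be positive; non-interacting media propagate boundary-to-boundary")
  -log(1 - xi) / mu
}

#' Sample a Henyey-Greenstein scattering direction
#'
#' Deflection cosine from the HG inverse CDF (isotropic when g = 0),
#' azimuth uniform; the mean deflection cosine equals g.
#'
#' @param incoming unit direction before scattering.
#' @param g anisotropy in `[-1, 1]`.
#' @param xi_pair two uniform deviates.
#' @return unit direction after scattering.
#' @export
scatterDirection <- function(incoming, g, xi_pair) {
  ct <- if (abs(g) < 1e-8) {
    1 - 2 * xi_pair[1]
  } else {
    s <- (1 - g^2) / (1 - g + 2 * g * xi_pair[1])
    min(1, max(-1, (1 + g^2 - s^2) / (2 * g)))
  }
  st <- sqrt(1 - ct^2)
  phi <- 2 * pi * xi_pair[2]
  w <- incoming / sqrt(sum(incoming^2))
  a <- if (abs(w[3]) > 0.99999) c(1, 0, 0) else c(0, 0, 1)
  u <- c(a[2] * w[3] - a[3] * w[2], a[3] * w[1] - a[1] * w[3],
         a[1] * w[2] - a[2] * w[1])
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  out <- st * cos(phi) * u + st * sin(phi) * v + ct * w
  out / sqrt(sum(out^2))
}

#' Unpolarized Fresnel reflectance
#'
#' Mean of the s- and p-polarized power reflectances; returns 1 beyond
#' the critical angle (total internal reflection).
#'
#' @param n1 refractive index on the incidence side.
#' @param n2 refractive index beyond the interface.
#' @param cos_incident cosine of the incidence angle, in `[0, 1]`.
#' @return reflection probability in `[0, 1]`.
#' @examples
#' fresnelUnpolarized(1, 1.38, 1) # (0.38/2.38)^2
#' @export
fresnelUnpolarized <- function(n1, n2, cos_incident) {
  if (n1 == n2) return(0)
  ci <- cos_incident
  st2 <- (n1 / n2)^2 * (1 - ci^2)
  if (st2 >= 1) return(1)
  ct <- sqrt(1 - st2)
  rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
  rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
  (rs^2 + rp^2) / 2
}

#' Reflect or refract a packet at a boundary
#'
#' With probability given by the unpolarized Fresnel reflectance the
#' packet is specularly reflected (medium unchanged); otherwise it is
#' refracted by Snell's law and takes on the far-side medium.
#'
#' @param packet list with `position`, `direction` (unit), `weight` and
#'   optionally `medium`.
#' @param normal interface normal oriented against the incoming ray.
#' @param n1,n2 refractive indices on the incidence and far side.
#' @param xi uniform deviate deciding reflection vs refraction.
#' @param medium_far value to assign to `packet$medium` on refraction.
#' @return the updated packet, with `$event` set to "reflect" or
#'   "refract".
#' @export
boundaryEvent <- function(packet, normal, n1, n2, xi, medium_far = NULL) {
  d <- packet$direction
  nrm <- normal / sqrt(sum(normal^2))
  if (sum(d * nrm) > 0) nrm <- -nrm
  ci <- -sum(d * nrm)
  R <- fresnelUnpolarized(n1, n2, ci)
  if (xi < R) {
    d2 <- d + 2 * ci * nrm
    packet$direction <- d2 / sqrt(sum(d2^2))
    packet$event <- "reflect"
  } else {
    if (n1 != n2) {
      r <- n1 / n2
      st2 <- r^2 * (1 - ci^2)
      ct <- sqrt(max(0, 1 - st2))
      d2 <- r * d + (r * ci - ct) * nrm
      packet$direction <- d2 / sqrt(sum(d2^2))
    }
    if (!is.null(medium_far)) packet$medium <- medium_far
    packet$event <- "refract"
  }
  packet
}

#' Russian roulette for low-weight packets
#'
#' Below `w_min` the packet survives with probability `p_survive` and is
#' boosted by `1/p_survive`, otherwise it is terminated (weight 0);
#' expected weight is conserved.
#'
#' @param weight current statistical weight.
#' @param w_min roulette threshold (default 1e-4).
#' @param p_survive survival probability (default 0.1).
#' @param xi uniform deviate.
#' @return the post-roulette weight (0 = terminated).
#' @export
roulette <- function(weight, w_min = 1e-4, p_survive = 0.1, xi) {
  if (p_survive <= 0 || p_survive >= 1)
    stop("p_survive must lie in (0, 1)")
  if (weight >= w_min) return(weight)
  if (xi < p_survive) weight / p_survive else 0
}

#' Run the Monte Carlo transport
#'
#' Traces `packets` photon packets from the scene's source through
#' emission, exponential free paths, Henyey-Greenstein scattering with
#' single-scattering-albedo survivor weighting, Fresnel
#' reflection/refraction at refractive-index mismatches, and Russian
#' roulette. Absorbed power density is tallied with the track-length
#' estimator: every traversed voxel accumulates `w * l * mu_a`, and the
#' per-voxel absorbed power density is `q = (L/N) * sum(w l mu_a) / V`
#' (W/m^3). Each packet draws its own RNG substream from `(seed, packet
#' index)`, so runs are bit-reproducible for a given seed.
#'
#' @param scn a [Scene-class].
#' @param packets number of packets N.
#' @param seed RNG seed (mandatory).
#' @param w_min roulette threshold; 0 disables roulette.
#' @param p_survive roulette survival probability.
#' @param max_events safety cap on events per packet.
#' @return a [DepositionCube-class] (units W/m^3) carrying the
#'   absorbed/escaped weight ledger.
#' @export
runTransport <- function(scn, packets, seed, w_min = 1e-4, p_survive = 0.1,
                         max_events = 1e6) {
  stopifnot(packets >= 1)
  if (missing(seed)) stop("transport requires an explicit RNG seed")
  validObject(scn)
  for (m in scn@materials) validObject(m)
  fs <- flattenScene(scn)
  res <- runTransportC(fs, sourceTriangles(scn@source),
                       scn@source@direction, as.numeric(packets),
                       scn@grid@n_cells, w_min, p_survive,
                       as.numeric(seed), max_events)
  L <- scn@source@power
  V_m3 <- voxelVolume(scn@grid) * 1e-9 # mm^3 -> m^3
  q <- array(res$tally, dim = scn@grid@n_cells) * (L / packets) / V_m3
  new("DepositionCube", grid = scn@grid, values = q, units = "W/m^3",
      power = L, packets = as.numeric(packets), seed = as.numeric(seed),
      absorbed_weight = res$absorbed, escaped_weight = res$escaped)
}
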