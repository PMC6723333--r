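#' Define an optical material
#'
#' @param name label.
#' @param mu_a absorption coefficient (cm^-1).
#' @param mu_s scattering coefficient (cm^-1).
#' @param g Henyey-Greenstein anisotropy (default 0.9, a typical
#'   soft-tissue value).
#' @param n refractive index (default 1.38 for soft tissue).
#' @return an [OpticalMaterial-class].
#' @examples
#' tumour <- opticalMaterial("tumour", mu_a = 2.3, mu_s = 21.2)
#' @export
opticalMaterial <- function(name, mu_a, mu_s, g = 0.9, n = 1.38) {
  new("OpticalMaterial", name = name, mu_a = as.numeric(mu_a),
      mu_s = as.numeric(mu_s), g = as.numeric(g), n = as.numeric(n))
}

#' Additive composite of two optical materials
#'
#' Models nanoparticle infusion of a host tissue: the absorption and
#' scattering coefficients add component-wise, while the anisotropy and
#' refractive index stay at the host (base) values -- the additive's
#' scattering is a small fraction of the composite total, so its angular
#' signature is negligible.
#'
#' @param base host material (supplies g and n).
#' @param additive infused material (e.g. gold nanorods).
#' @param name label for the composite; default pastes the two names.
#' @return an [OpticalMaterial-class] with summed mu_a and mu_s.
#' @examples
#' tumour <- opticalMaterial("tumour", 2.3, 21.2)
#' gnr <- opticalMaterial("gnr", 12, 1.2)
#' compositeMaterial(tumour, gnr) # mu_a 14.3, mu_s 22.4
#' @export
compositeMaterial <- function(base, additive,
                              name = paste(base@name, additive@name,
                                           sep = "+")) {
  opticalMaterial(name, base@mu_a + additive@mu_a, base@mu_s + additive@mu_s,
                  g = base@g, n = base@n)
}

#' Bioheat parameter set
#'
#' Defaults are the perfused-skin constants used throughout the package:
#' tissue rho = 1079 kg/m^3, c = 3540 J/(kg K), k = 0.53 W/(m K); blood
#' rho_b = 1060 kg/m^3, c_b = 3617 J/(kg K), perfusion w_b = 0.01 1/s,
#' arterial temperature 37 C.
#'
#' @param rho,c,k tissue density, specific heat, conductivity.
#' @param rho_b,c_b,w_b blood density, specific heat, perfusion rate.
#' @param T_a arterial (ambient blood) temperature, degrees C.
#' @return a [BioheatParams-class].
#' @export
bioheatParams <- function(rho = 1079, c = 3540, k = 0.53, rho_b = 1060,
                          c_b = 3617, w_b = 0.01, T_a = 37) {
  new("BioheatParams", rho = rho, c = c, k = k, rho_b = rho_b, c_b = c_b,
      w_b = w_b, T_a = T_a)
}

#' Lumped perfusion coefficient
#'
#' \eqn{B = c_b \, w_b \, \rho_b} in W/(m^3 K): the heat-sink strength of
#' blood flow in Pennes' equation.
#'
#' @param params a [BioheatParams-class].
#' @return B (W/(m^3 K)).
#' @examples
#' perfusionCoefficient(bioheatParams()) # 3617 * 0.01 * 1060
#' @export
perfusionCoefficient <- function(params) {
  params@c_b * params@w_b * params@rho_b
}

#' Single-scattering albedo
#'
#' The fraction mu_s / (mu_a + mu_s) of a packet's weight that survives a
#' scattering event; the complementary fraction is deposited locally.
#'
#' @param material an [OpticalMaterial-class].
#' @return survival fraction in `[0, 1]`.
#' @export
survivalAlbedo <- function(material) {
  mu <- material@mu_a + material@mu_s
  if (mu <= 0)
    stop("vacuum material (mu_a + mu_s = 0) has no scattering albedo")
  material@mu_s / mu
}
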