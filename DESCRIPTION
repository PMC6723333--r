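Package: phototherm
Title: Monte Carlo Photon Transport and Bioheat Modelling of Nanoparticle
    Photothermal Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled simulation of nanoparticle photothermal therapy in a
    voxelized skin-cancer model. A Monte Carlo photon-packet engine
    (Henyey-Greenstein scattering, Fresnel boundary events, Russian
    roulette, track-length absorption estimator) computes the volumetric
    absorbed power density delivered by a near-infrared source to a
    gold-nanorod-infused tumour embedded in normal tissue. The absorbed
    power drives an explicit finite-difference solver of Pennes' bioheat
    equation, and the resulting temperature history is converted to CEM43
    thermal dose and estimated percentage cell kill over the tumour and
    surrounding normal tissue. Includes triangle-mesh scene geometry with
    STL import, analytic validation oracles, and a scripted end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
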