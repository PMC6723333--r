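# phototherm

Coupled simulation of nanoparticle photothermal therapy in a voxelized
skin-cancer model, for researchers planning or analysing plasmonic
hyperthermia treatments. Gold nanorods tuned to the near-infrared are
injected into a shallow tumour; a laser heats the infused tissue; the
question is how much thermal dose the tumour and the surrounding normal
tissue actually receive. The package answers it in three coupled stages,
each testable against analytic oracles:

1. **Monte Carlo photon transport.** Photon packets of power L/N are
   emitted from a disc source and traced through scattering/absorbing
   media: exponential free paths `l = -ln(1-ξ)/μ` with
   `μ = μ_a + μ_s`, survivor weighting by the single-scattering albedo
   `μ_s/μ`, Henyey–Greenstein deflection with anisotropy g, unpolarized
   Fresnel reflection/refraction at refractive-index boundaries, and
   Russian roulette for low weights. A track-length estimator tallies
   the absorbed power density per voxel,
   `q = (L/NV) Σ w·l·μ_a` (W/m³).
2. **Pennes bioheat equation.**
   `ρc ∂T/∂t = ∇·(k∇T) − B(T − T_a) + Q` with `B = c_b·w_b·ρ_b`, solved
   by explicit finite differences on the same grid with the transport
   cube as the constant source Q.
3. **CEM43 thermal dose and cell kill.** Each voxel's temperature
   history is normalized to cumulative equivalent minutes at 43 °C,
   `CEM43 = Σ t_i R^(43−T_i)` (R = 0.5 above, 0.25 below 43 °C), and
   mapped to estimated % cell death through an exponential survival
   model anchored at 10 % survival per 120 equivalent minutes.

The built-in scenario is a 1 mm oblate-spheroid tumour 1 mm below the
skin surface of a 6 mm tissue cube, illuminated by a 1 W, 3 mm-radius
disc source; tumour optics with and without a gold-nanorod infusion
(μ_a/μ_s of 14.3/22.4 vs 2.3/21.2 cm⁻¹). Scene geometry is triangle-mesh
based (STL import supported), transport and heat kernels are in C++
(Rcpp), and every run is bit-reproducible from its seed.

## Worked example

```r
library(phototherm)

cfg <- defaultConfig(gnr = TRUE, packets = 1e6, seed = 1)
scn <- buildScene(cfg)

q <- runTransport(scn, packets = 1e6, seed = 1)
show(q)
#> DepositionCube [W/m^3]: 101 x 101 x 101, range [0, 6.579e+07]
#>   N=1e+06 packets, L=1 W, absorbed 4.092e+05, escaped 5.908e+05

mask <- entityMask(Find(function(e) e@label == "tumour", scn@entities),
                   scn@grid)
max(cubeValues(q)[mask])
#> 6.58e+07   # peak absorbed power density in the tumour, W/m^3

history <- runHeating(q, scn, bioheatParams(), duration = 60,
                      record_interval = 20)
riseSummary(history, mask)
#>   time_s peak_rise_C mean_rise_C
#> 1      0         0.0         0.0
#> 2     20        17.5        16.0
#> 3     40        19.4        17.9
#> 4     60        19.7        18.1

kill <- killMap(accumulateCem43(history))
min(cubeValues(kill)[mask])
#> 100   # estimated % cell death everywhere in the tumour after 60 s
```

The absorbed/escaped line is the weight-conservation ledger: 41 % of the
source power is absorbed in tissue, the rest leaves the domain
(backscatter and side losses). The temperature column shows the fast
initial rise toward a conduction/perfusion-limited plateau; after one
minute of 1 W illumination the infused tumour sits ~20 °C above body
temperature, far beyond the CEM43 dose needed to kill the tumour cells.

`runPipeline(cfg, out_dir)` runs all three stages and writes every cube
(raw float64 + JSON sidecar), probe CSVs, and a manifest with seeds,
timings and checksums. A thin CLI with `transport`, `heat`, `dose`,
`run`, `profile` and `validate` subcommands lives at
`inst/scripts/phototherm-cli.R`, with ready-made configs under
`inst/extdata/`.

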