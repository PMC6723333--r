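---
title: "Simulating nanoparticle photothermal therapy: model, assumptions and numerical choices"
author: "phototherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nanoparticle photothermal therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phototherm)
```

phototherm couples three physical models into one pipeline: Monte Carlo
photon-packet transport through turbid tissue, an explicit
finite-difference solver of Pennes' bioheat equation driven by the
absorbed optical power, and a CEM43 thermal-dose / cell-survival map of
the resulting temperature history. This vignette is the package's own
account of those models: what is being solved, which parameters matter,
where the design was genuinely open and what was decided, and what the
built-in scenario does and does not tell you about real tissue.

## The photon transport model

Light at a near-infrared wavelength is represented by $N$ statistical
packets that each carry a power $L/N$, where $L$ is the source power in
watts. A packet is emitted from an area-uniform random point on the
source disc, travelling along the surface normal. In a medium with
absorption coefficient $\mu_a$ and scattering coefficient $\mu_s$
(cm$^{-1}$; the interaction coefficient is $\mu = \mu_a + \mu_s$) it
moves a free path

$$ l = -\ln(1 - \xi) / \mu, \qquad \xi \sim U[0, 1), $$

and at the interaction point its weight is multiplied by the
single-scattering albedo $\mu_s/\mu$ (the surviving, scattered fraction),
while the complementary fraction $\mu_a/\mu$ is booked as absorbed. The
new direction is drawn from the Henyey–Greenstein phase function with
anisotropy $g$ (the mean deflection cosine), using the standard inverse
CDF for $\cos\theta$ and a uniform azimuth. If a material boundary lies
closer than the sampled interaction point, the packet is moved to the
boundary instead: with probability given by the unpolarized Fresnel
reflectance it reflects specularly, otherwise it refracts by Snell's law
and adopts the far-side medium (total internal reflection gives
reflectance 1). Because the exponential free path is memoryless,
re-sampling a fresh path after a boundary crossing is exact. Packets
whose weight falls below $w_{\min}$ undergo Russian roulette: they
survive with probability $p$ and are boosted by $1/p$, an unbiased
termination scheme. Weight that leaves the domain is tallied as escaped;
it is *not* re-injected into the source, since re-injection would bias
the fluence estimate upward. The absorbed/escaped ledger is reported on
every run and the test suite checks its conservation.

Absorbed power density is estimated with the track-length estimator:
every voxel a packet crosses accumulates $w\,l\,\mu_a$ for the in-voxel
path length $l$ (an incremental 3-D DDA walk), and

$$ q = \frac{L}{N\,V}\sum w\,l\,\mu_a \quad [\mathrm{W\,m^{-3}}] $$

with $V$ the voxel volume. This estimator is preferred over depositing
only at collision sites because every traversed voxel receives
information from every crossing, giving a markedly lower variance at
equal packet count; the two estimators agree in expectation, which the
tests verify against the collision-based ledger.

Media with $\mu = 0$ (air) are non-interacting: packets cross them
boundary-to-boundary without path sampling, and deposit nothing.

A note on estimator choice: the same track-length sums also estimate the
radiant energy density $U = (n/c)(L/NV)\sum w\,l$, which carries a
refractive-index/speed-of-light factor. That factor cancels in the
absorbed *power* density, and it is the absorbed power — not $U$ — that
sources the heat equation, so the pipeline feeds $q$ to the bioheat
stage and never needs $c$.

## The bioheat model

Heating is modelled by Pennes' equation

$$ \rho c \, \frac{\partial T}{\partial t}
   = \nabla\!\cdot\!(k \nabla T) - B\,(T - T_a) + Q, \qquad
   B = c_b\, w_b\, \rho_b, $$

with $Q$ the deposition cube from the transport stage, held constant
(constant illumination). The solver is explicit forward Euler with a
7-point Laplacian on the same voxel grid — the simplest scheme consistent
with the model and the easiest to verify: the package checks it against
the conduction-free perfusion ODE, the free-space Gaussian heat kernel
under grid refinement, exact discrete energy conservation on an insulated
grid, and the maximum principle. The time step obeys

$$ \Delta t \le \mathrm{safety} \cdot
   \frac{\rho c}{2k\left(\tfrac1{\Delta x^2}+\tfrac1{\Delta y^2}+
   \tfrac1{\Delta z^2}\right) + B}, \qquad \mathrm{safety} = 0.9 . $$

Boundary handling was genuinely open and was resolved as follows: air
voxels are excluded from conduction and every tissue–air interface is
adiabatic (an insulated skin surface); the outermost tissue layer on the
four lateral faces and the bottom face — the faces that in reality
connect to the rest of the body — is clamped at the arterial temperature
$T_a = 37\,°$C as a far-field condition. The skin (top) face is adiabatic
only. Perfusion acts only in tissue voxels. A fully insulated mode
(nothing clamped) exists for conservation testing. At 600 s of heating
the diffusion length $\sqrt{4 D t}$ with $D = k/\rho c \approx
1.39\times10^{-7}\,$m$^2$/s is about 18 mm — larger than the 6 mm flesh
cube — so the far-field choice is *not* a second-order detail for long
runs: clamped faces bound the bulk temperature, and an insulated domain
would heat without limit apart from perfusion. One thermal parameter set
is used for tumour and normal tissue alike (per-material overrides are
accepted in the config).

## Thermal dose and cell survival

A temperature history is converted to cumulative equivalent minutes at
43 °C per voxel:

$$ \mathrm{CEM43} = \sum_i t_i \, R^{\,43 - T_i}, $$

where $t_i$ is the interval length in minutes, $T_i$ the trapezoidal
average of the bounding snapshots, and $R$ the per-degree compensation
factor: $R = 0.5$ at or above 43 °C and $R = 0.25$ below — the standard
Sapareto–Dewey constants, configurable. No lower temperature cutoff is
applied by default ($R_{\text{below}}$ already makes sub-43 °C intervals
negligible); an optional cutoff flag exists. Survival is a single
exponential in equivalent minutes calibrated to one anchor — 10 %
survival at 120 equivalent minutes, the typical behaviour of human
cancer cell lines held at 43 °C for two hours — so
$S = \exp(-\lambda\,\mathrm{CEM43})$ with
$\lambda = \ln(10)/120\ \mathrm{min}^{-1}$, and the kill map is
$100\,(1-S)$. A single-anchor exponential is deliberately minimal: it
reproduces the anchor exactly and is monotone, but it is not a
cell-line-specific survival curve and no Arrhenius damage integral is
attempted.

## The built-in scenario

The packaged default (`defaultConfig()`) is a simplified skin-cancer
model: a 6 mm cube of normal tissue centred in a 10 mm air domain; an
oblate-spheroid tumour of diameter 1 mm and height 0.5 mm whose top lies
1 mm below the skin surface; and a 1 W disc source of radius 3 mm in the
air above the skin, emitting straight down. Optical coefficients
(cm$^{-1}$) are normal tissue 0.7/36.7, tumour 2.3/21.2 and gold
nanorods 12/1.2; infusing the tumour adds the nanorod coefficients to
the tumour's, giving 14.3/22.4. The nanorod scattering-to-absorption
ratio is fixed at 0.1, the measured value for rods with the aspect ratio
(about 4) whose plasmon resonance sits near 800 nm. Geometry follows the
configuration that produced the study's result figures; an alternative
with a 1 mm source radius and a 0.25 mm tumour depth appears elsewhere
in the source description and is expressible through the config, but is
not the default.

Two tabulated gaps had to be filled. The anisotropy $g$ is not given for
any material: all tissues default to $g = 0.9$, the typical soft-tissue
value in the optical-properties literature. Refractive indices are also
not given: tissue and tumour default to $n = 1.38$ with $n = 1$ for air,
so Fresnel events occur only at the skin and the cube's outer surface;
the tumour is index-matched to tissue. Nanorod infusion leaves $g$ and
$n$ at the host values, because the nanorod contribution to the
composite scattering is a few percent. All of these are per-material
config fields.

## Problem sizes, determinism and tolerances

The package's scaled study uses $10^7$ packets on a $101^3$ grid
(voxel 0.099 mm); these are the sizes the acceptance script and tests
run, chosen so a full two-scenario study completes on one CPU core in
roughly a quarter of an hour. A `grid_preset = "full"` ($201^3$) matches
the finest grid the scenario was originally run on; transport cost is
essentially independent of the grid, but the explicit heat solver's step
count grows as $\Delta x^{-2}$, so full-grid 600 s runs are several
times slower. Monte Carlo checks in the tests use 3-standard-error
bands; the scaled scenario checks use the ±30 % band that reflects the
(roughly 20 %) uncertainty of tabulated tissue optical properties.

Every random draw in the transport engine comes from a
counter-seeded generator: packet $i$ derives an xoshiro256++ substream
from (seed, $i$), so a run is bit-reproducible for a given seed under
any execution order, and doubling the source power doubles the cube
bit-for-bit. Lengths are millimetres internally; $\mu$ values are
accepted in cm$^{-1}$ and converted once when the scene is flattened for
the engine. Ray–surface intersections use an $\varepsilon = 10^{-9}$ mm
minimum-hit guard plus a $10^{-7}$ mm post-event advance to avoid
self-intersection after reflection; built-in cuboid and ellipsoid
entities are intersected analytically (exactly), imported STL meshes by
Möller–Trumbore triangle tests.

## What the scenario does and does not show

The geometry is an idealization: a watertight spheroid tumour in a
homogeneous cube, with no vasculature, hair follicles, or layered skin
structure, a spatially uniform nanorod load, and constant optical and
thermal properties (no temperature dependence, no nanorod sintering, no
clearance over the heating period). Passing the packaged checks shows
the transport, heat and dose machinery are each correct against
independent analytic oracles and mutually consistent — it does not show
that a real tumour would reach these temperatures.

One structural property of the coupled solution deserves emphasis
because it constrains what any parameter choice can produce: with
$k = 0.53$ W/(m K), a millimetre-scale hotspot cannot sustain a steady
temperature contrast above roughly $q a^2 / 2k$ over its surroundings
(about 6 °C for $q = 3\times10^7$ W/m$^3$ and $a = 0.5$ mm), and
conduction erases millimetre-scale temperature structure within a couple
of seconds. Long-exposure in-tumour temperatures are therefore dominated
by the bulk heating of the whole illuminated tissue volume, not by the
tumour's own absorption contrast, and the infused-versus-control
difference at 600 s is correspondingly modest. The 1 s fields, by
contrast, still mirror the deposition structure. Equivalently: the
tumour-to-control contrast is much larger in absorbed power than in
long-time temperature, and larger at 1 s than at 600 s.

## Worked example at reduced scale

```{r example, eval = FALSE}
library(phototherm)

cfg <- defaultConfig(gnr = TRUE, packets = 1e6, seed = 1,
                     duration = 60, record_interval = 20)
cfg$grid$n_cells <- 101L
res <- runPipeline(cfg, out_dir = tempfile("phototherm_"))

# in-tumour temperature over time
res$manifest$conservation
scn <- buildScene(cfg)
mask <- entityMask(Find(function(e) e@label == "tumour", scn@entities),
                   scn@grid)
riseSummary(res$history, mask)

# thermal dose and kill fall-off along the beam axis
lineProfile(res$kill, "z", at = c(0, 0))
```

The same pipeline is scriptable from a shell through
`inst/scripts/phototherm-cli.R` (subcommands `transport`, `heat`,
`dose`, `run`, `profile`, `validate`), which reads JSON configs like the
two packaged under `inst/extdata/`.

## Known limitations

* Single wavelength per run; no spectra, polarization, fluorescence or
  time-resolved transport.
* One thermal parameter set for all tissue by default; no
  temperature-dependent properties.
* The survival model is a one-anchor exponential, not a measured
  cell-line curve.
* Explicit time stepping only; stiff (fine-grid) heating runs pay the
  $\Delta x^{-2}$ step-count price.
* The clamped-face far-field condition is an approximation for "the rest
  of the body"; its influence grows with heating duration, as discussed
  above.
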