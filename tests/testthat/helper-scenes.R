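# Scene builders used across the tests. Everything is generated in code;
# no stored fixtures.

airMaterial <- function(n = 1) opticalMaterial("air", 0, 0, g = 0, n = n)

# A wide slab of a single material directly under a narrow disc source,
# refractive-index matched to the surroundings so no Fresnel events occur.
# Packets enter travelling straight down (-z); the slab occupies
# z in [-thickness, 0].
slabScene <- function(mu_a, mu_s = 0, g = 0, thickness_mm = 1,
                      half_width = 8) {
  mats <- list(air = airMaterial(),
               slab = opticalMaterial("slab", mu_a, mu_s, g = g, n = 1))
  slab <- entity("slab", "cuboid", "slab", priority = 1,
                 center = c(0, 0, -thickness_mm / 2),
                 size = c(2 * half_width, 2 * half_width, thickness_mm))
  src <- makeDiscSource(c(0, 0, 1), radius = 0.5, power = 1)
  ext <- rbind(c(-half_width, half_width), c(-half_width, half_width),
               c(-thickness_mm - 2, 2))
  # z spacing of 0.2 mm aligns voxel boundaries with the slab faces
  nz <- as.integer(round((thickness_mm + 4) / 0.2))
  grid <- voxelGridDef(ext, c(21L, 21L, nz))
  scene(mats, list(slab), src, grid, ambient = "air")
}

# Reduced default scenario for fast end-to-end checks.
tinyConfig <- function(gnr = TRUE, packets = 2e4, seed = 1, duration = 2,
                       record_interval = 1) {
  cfg <- defaultConfig(gnr = gnr, packets = packets, seed = seed,
                       duration = duration,
                       record_interval = record_interval)
  cfg$grid$n_cells <- 41L
  cfg
}

tumourEntityOf <- function(scn) Find(function(e) e@label == "tumour",
                                     scn@entities)

# deterministic uniform deviates for closed-form checks
fixedXi <- function(k) (seq_len(k) - 0.5) / k
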