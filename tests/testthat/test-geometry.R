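test_that("spheroid meshes are watertight and converge to the ellipsoid volume", {
  # sphere limit at high subdivision
  sph <- makeOblateSpheroid(c(0, 0, 0), c(0.5, 0.5, 0.5), subdivisions = 4)
  expect_true(isWatertight(sph))
  expect_equal(meshVolume(sph), 4 / 3 * pi * 0.5^3, tolerance = 0.01)

  # the oblate tumour shape: volume -> (4/3) pi a^2 c
  tum <- makeOblateSpheroid(c(1, -2, 3), c(0.5, 0.25), subdivisions = 4)
  expect_true(isWatertight(tum))
  expect_equal(meshVolume(tum), 4 / 3 * pi * 0.5^2 * 0.25, tolerance = 0.01)

  # refinement improves the volume estimate
  v_exact <- 4 / 3 * pi * 0.5^2 * 0.25
  err <- vapply(1:3, function(s)
    abs(meshVolume(makeOblateSpheroid(c(0, 0, 0), c(0.5, 0.25), s)) -
        v_exact), 0)
  expect_true(all(diff(err) < 0))

  expect_error(makeOblateSpheroid(c(0, 0, 0), c(-0.5, 0.25)), "positive")
  expect_error(makeOblateSpheroid(c(0, 0, 0), c(0.5, 0.25), 0), ">= 1")
})

test_that("cuboid meshes are watertight with positive signed volume", {
  m <- makeCuboidMesh(c(1, 2, 3), c(6, 6, 6))
  expect_true(isWatertight(m))
  expect_equal(meshVolume(m), 216)
})

test_that("disc source has the n-gon area and area-uniform emission", {
  src <- makeDiscSource(c(0, 0, 4), radius = 3, n_fan = 16, power = 1)
  a_fan <- 0.5 * 16 * 3^2 * sin(2 * pi / 16)
  expect_equal(meshArea(src@mesh), a_fan, tolerance = 1e-10)
  # polygon-vs-circle deficit
  expect_lt(abs(meshArea(src@mesh) - pi * 9) / (pi * 9),
            1 - sin(2 * pi / 16) * 16 / (2 * pi) + 1e-12)

  set.seed(42)
  p <- sampleSourcePoints(src, 1e5)
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  expect_true(all(r <= 3 + 1e-9))
  expect_true(all(abs(p[, 3] - 4) < 1e-9))
  # radial density uniform over annuli well inside the polygon
  edges <- seq(0, 2.7, length.out = 10)
  counts <- table(cut(r[r <= 2.7], edges))
  expect_gt(stats::chisq.test(counts,
                              p = diff(edges^2) / 2.7^2)$p.value, 1e-3)

  expect_error(makeDiscSource(c(0, 0, 0), radius = 3, n_fan = 2), "n_fan")
  expect_error(makeDiscSource(c(0, 0, 0), radius = -1), "radius")
})

test_that("mediumAt resolves nested entities by priority", {
  scn <- buildScene(defaultConfig(gnr = TRUE))
  expect_equal(mediumAt(scn, c(0, 0, 1.75))@name, "tumour_gnr")
  expect_equal(mediumAt(scn, c(0, 0, 4))@name, "air")       # above the skin
  expect_equal(mediumAt(scn, c(0, 0, -1.25))@name, "normal_tissue")
  expect_equal(mediumAt(scn, c(4.5, 4.5, 0))@name, "air")   # beside the cube
  expect_error(mediumAt(scn, c(0, 0, 11)), "outside")
})

test_that("rayIntersect finds the nearest mesh boundary with closed-form distances", {
  scn <- buildScene(defaultConfig(gnr = TRUE))
  # straight down from the air gap: the flesh top face at z = 3
  h <- rayIntersect(scn, c(0, 0, 4.5), c(0, 0, -1))
  expect_equal(h$distance, 1.5, tolerance = 1e-9)
  expect_equal(h$entity, "flesh")
  expect_equal(abs(h$normal[3]), 1)
  expect_equal(h$material_near@name, "air")
  expect_equal(h$material_far@name, "normal_tissue")

  # ray through a spherical entity: chord between the two hits equals 2r
  mats <- list(air = airMaterial(),
               ball = opticalMaterial("ball", 1, 1, n = 1))
  ball <- entity("ball", "ellipsoid", "ball", priority = 1,
                 center = c(0, 0, 0), semi_axes = c(1, 1, 1),
                 subdivisions = 4)
  scn2 <- scene(mats, list(ball),
                makeDiscSource(c(0, 0, 3), 0.5), voxelGridDef(c(-4, 4), 11),
                ambient = "air")
  h1 <- rayIntersect(scn2, c(0, 0, 3), c(0, 0, -1))
  expect_equal(h1$distance, 2, tolerance = 0.01)
  h2 <- rayIntersect(scn2, c(0, 0, 3 - h1$distance - 1e-6), c(0, 0, -1))
  expect_equal(h2$distance, 2, tolerance = 0.02) # the far side, 2r away

  # crossing a returned boundary flips the material (consistency with mediumAt)
  expect_false(identical(h1$material_near@name, h1$material_far@name))

  # ray parallel to and outside every entity face only leaves the domain
  h3 <- rayIntersect(scn2, c(0, 2, 2), c(1, 0, 0))
  expect_equal(h3$entity, "domain")
})

test_that("composite optics add coefficients and keep host g and n", {
  tumour <- opticalMaterial("tumour", 2.3, 21.2)
  gnr <- opticalMaterial("gnr", 12, 1.2)
  mix <- compositeMaterial(tumour, gnr)
  expect_identical(mix@mu_a, 14.3)
  expect_identical(mix@mu_s, 22.4)
  expect_identical(mix@g, tumour@g)
  expect_identical(mix@n, tumour@n)
  # the nanorod fitting ratio
  expect_equal(gnr@mu_s / gnr@mu_a, 0.1, tolerance = 1e-14)

  # identity under a zero-coefficient additive
  nothing <- opticalMaterial("none", 0, 0)
  same <- compositeMaterial(tumour, nothing)
  expect_identical(same@mu_a, tumour@mu_a)
  expect_identical(same@mu_s, tumour@mu_s)

  # order independence of the coefficient sums
  ba <- compositeMaterial(gnr, tumour)
  expect_identical(ba@mu_a, mix@mu_a)
  expect_identical(ba@mu_s, mix@mu_s)
})

test_that("STL round-trips preserve geometry, ASCII and binary", {
  m <- makeOblateSpheroid(c(0, 0, 0), c(0.5, 0.25), subdivisions = 2)
  path <- tempfile(fileext = ".stl")
  writeSTL(m, path)
  m2 <- readSTL(path)
  expect_true(isWatertight(m2))
  expect_equal(meshVolume(m2), meshVolume(m), tolerance = 1e-6)
  unlink(path)

  # binary STL reader: craft a one-triangle file in code
  bpath <- tempfile(fileext = ".stl")
  con <- file(bpath, "wb")
  writeBin(raw(80), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(0, 0, 1,  0, 0, 0,  1, 0, 0,  0, 1, 0), con, size = 4,
           endian = "little")
  writeBin(raw(2), con)
  close(con)
  tri <- readSTL(bpath)
  expect_equal(nrow(tri@faces), 1L)
  expect_equal(meshArea(tri), 0.5, tolerance = 1e-6)
  unlink(bpath)
})
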