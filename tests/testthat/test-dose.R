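test_that("CEM43 increments follow t R^(43 - T)", {
  expect_identical(cem43Increment(43, 30), 30)
  expect_equal(cem43Increment(44, 10), 20)
  expect_equal(cem43Increment(42, 10), 2.5)
  # vectorized over a field
  expect_equal(cem43Increment(c(43, 44, 42), 10), c(10, 20, 2.5))
})

constantHistory <- function(temps, times, n = c(3L, 3L, 3L)) {
  g <- voxelGridDef(c(0, 3), n)
  new("ThermalHistory", grid = g, times = times,
      snapshots = lapply(temps, function(tt) array(tt, n)),
      labels = array(1L, n))
}

test_that("dose accumulation is additive over history partitions", {
  # constant 43 C for one hour -> 60 equivalent minutes everywhere
  h <- constantHistory(c(43, 43), c(0, 3600))
  expect_equal(unique(as.numeric(cubeValues(accumulateCem43(h)))), 60)

  # piecewise 44 C then 42 C, ten minutes each -> 20 + 2.5
  d1 <- cem43Increment(44, 10) + cem43Increment(42, 10)
  expect_equal(d1, 22.5)

  # splitting an interval at constant temperature changes nothing
  whole <- constantHistory(c(44, 44), c(0, 1200))
  halves <- constantHistory(c(44, 44, 44), c(0, 600, 1200))
  expect_equal(cubeValues(accumulateCem43(whole)),
               cubeValues(accumulateCem43(halves)))

  # trapezoidal interval average: endpoints 42 and 44 average to 43
  ramp <- constantHistory(c(42, 44), c(0, 600))
  expect_equal(unique(as.numeric(cubeValues(accumulateCem43(ramp)))), 10)

  expect_error(accumulateCem43(constantHistory(list(43), 0)), "two")
})

test_that("raising any interval temperature never lowers the dose", {
  set.seed(4)
  for (rep in 1:10) {
    temps <- runif(5, 38, 47)
    h0 <- constantHistory(temps, seq(0, 2400, by = 600))
    base <- cubeValues(accumulateCem43(h0))
    i <- sample(5, 1)
    temps[i] <- temps[i] + runif(1, 0.1, 2)
    h1 <- constantHistory(temps, seq(0, 2400, by = 600))
    expect_true(all(cubeValues(accumulateCem43(h1)) >= base - 1e-12))
  }
})

test_that("the optional sub-threshold cutoff zeroes cool intervals only", {
  h <- constantHistory(c(38, 38, 45, 45), c(0, 600, 601, 1201))
  full <- accumulateCem43(h)
  cut <- accumulateCem43(h, cutoff_C = 39)
  expect_lt(cut@values[1], full@values[1])
  expect_gt(cut@values[1], 0) # the hot segment still counts
})

test_that("survival calibration anchors 10% at 120 equivalent minutes", {
  expect_identical(survivalFraction(0), 1)
  expect_equal(survivalFraction(120), 0.1, tolerance = 1e-12)
  expect_equal(survivalFraction(240), 0.01, tolerance = 1e-12)
  expect_error(survivalFraction(-5))
  # kill map is the monotone complement in percent
  g <- voxelGridDef(c(0, 1), c(2L, 2L, 2L))
  d <- new("DoseCube", grid = g,
           values = array(c(0, 10, 120, 240, 0, 0, 0, 1e6), c(2, 2, 2)),
           units = "min")
  km <- killMap(d)
  expect_s4_class(km, "KillMap")
  expect_identical(km@values[1, 1, 1], 0)
  expect_equal(km@values[1, 2, 1], 90, tolerance = 1e-10)
  expect_true(all(diff(km@values[order(d@values)]) >= -1e-12))
})

test_that("line profiles slice a cube along one axis through a point", {
  g <- voxelGridDef(c(-5, 5), 41L)
  const <- new("VoxelCube", grid = g, values = array(7, nCells(g)),
               units = "a.u.")
  prof <- lineProfile(const, "z", at = c(0, 0))
  expect_equal(nrow(prof), 41)
  expect_true(all(prof$value == 7))
  expect_false(is.unsorted(prof$position_mm))

  # a tumour mask profiled through its centre shows a run of about
  # height / dz voxels
  cfg <- tinyConfig()
  scn <- buildScene(cfg)
  tum <- tumourEntityOf(scn)
  mask <- entityMask(tum, scn@grid)
  mc <- new("VoxelCube", grid = scn@grid, values = mask + 0, units = "")
  pm <- lineProfile(mc, "z", at = c(0, 0))
  run <- sum(pm$value)
  expect_equal(run, 0.5 / voxelSize(scn@grid)[3], tolerance = 0.5)
  expect_error(lineProfile(mc, "z", at = c(40, 0)), "outside")
})

test_that("masking a region is idempotent and counts the entity volume", {
  cfg <- tinyConfig()
  cfg$grid$n_cells <- 101L # fine grid so surface voxels are a small fraction
  scn <- buildScene(cfg)
  tum <- tumourEntityOf(scn)
  cube <- new("VoxelCube", grid = scn@grid,
              values = array(1, nCells(scn@grid)), units = "")
  m1 <- maskRegion(cube, tum)
  n_masked <- sum(is.na(m1@values))
  v_expected <- 4 / 3 * pi * 0.5^2 * 0.25 / voxelVolume(scn@grid)
  expect_equal(n_masked, v_expected, tolerance = 0.15) # surface voxels
  m2 <- maskRegion(m1, tum)
  expect_identical(m1@values, m2@values)

  # an entity that overlaps nothing masks nothing
  far <- entity("far", "ellipsoid", "air", priority = 9,
                center = c(4.5, 4.5, -4.5), semi_axes = c(0.01, 0.01, 0.01))
  expect_identical(maskRegion(cube, far)@values, cube@values)
})
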