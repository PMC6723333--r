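test_that("perfusion coefficient is the product of the blood constants", {
  expect_equal(perfusionCoefficient(bioheatParams()), 3617 * 0.01 * 1060)
  expect_identical(perfusionCoefficient(bioheatParams(w_b = 0)), 0)
  expect_equal(perfusionCoefficient(bioheatParams(w_b = 0.02)),
               2 * perfusionCoefficient(bioheatParams(w_b = 0.01)))
})

test_that("stable timestep follows the explicit-scheme bound", {
  p <- bioheatParams()
  B <- perfusionCoefficient(p)
  dt <- stableTimestep(p, 0.1)
  expect_equal(dt, 0.9 * p@rho * p@c / (6 * p@k / 1e-8 + B))
  # halving dx quarters dt when B is negligible
  p0 <- bioheatParams(w_b = 0)
  expect_equal(stableTimestep(p0, 0.05), stableTimestep(p0, 0.1) / 4)
  # no conduction, no perfusion: unbounded dt capped by the record interval
  expect_identical(stableTimestep(bioheatParams(k = 0, w_b = 0), 0.1,
                                  cap = 20), 20)
})

test_that("uniform body temperature with no source is an equilibrium", {
  p <- bioheatParams()
  n <- c(9L, 9L, 9L)
  T0 <- array(37, n)
  q0 <- array(0, n)
  lab <- array(1L, n)
  T1 <- heatSteps(T0, q0, lab, 0.1, p, dt = stableTimestep(p, 0.1),
                  nsteps = 10)
  expect_identical(T1, T0)
})

test_that("the stepper rejects unstable time steps", {
  p <- bioheatParams()
  n <- c(5L, 5L, 5L)
  expect_error(heatSteps(array(37, n), array(0, n), array(1L, n), 0.1, p,
                         dt = 1, nsteps = 1), "stability")
})

test_that("conduction-free heating follows the perfusion ODE", {
  p <- bioheatParams(k = 0)
  B <- perfusionCoefficient(p)
  n <- c(5L, 5L, 5L)
  Q <- 3e4
  # one step equals the Euler discretization exactly
  dt <- 0.05
  T1 <- heatSteps(array(37, n), array(Q, n), array(1L, n), 0.1, p, dt, 1)
  expect_equal(T1[1, 1, 1], 37 + dt / (p@rho * p@c) * Q, tolerance = 1e-12)
  # many steps approach the closed-form relaxation toward Ta + Q/B
  T2 <- heatSteps(array(37, n), array(Q, n), array(1L, n), 0.1, p, dt,
                  nsteps = 2000)
  expect_equal(T2[3, 3, 3], perfusionOdeOracle(p, Q, 2000 * dt),
               tolerance = 1e-4)
})

test_that("a point release converges to the Gaussian heat kernel", {
  p <- bioheatParams(w_b = 0) # pure conduction
  D <- p@k / (p@rho * p@c)
  t_end <- 2
  err <- vapply(c(21L, 41L), function(nv) {
    h_mm <- 4 / nv
    n <- rep(nv, 3)
    T0 <- array(0, n)
    mid <- (nv + 1) / 2
    T0[mid, mid, mid] <- 1
    lab <- array(1L, n)
    dt <- stableTimestep(p, h_mm)
    ns <- ceiling(t_end / dt)
    T1 <- heatSteps(T0, array(0, n), lab, h_mm, p, t_end / ns, ns)
    g <- voxelGridDef(c(-2, 2), nv)
    r2 <- outer(outer(voxelCenters(g, 1)^2, voxelCenters(g, 2)^2, "+"),
                voxelCenters(g, 3)^2, "+")
    vol_m3 <- (h_mm * 1e-3)^3
    exact <- vol_m3 * heatKernelOracle(D, t_end, sqrt(r2) * 1e-3)
    sqrt(sum((T1 - exact)^2) / sum(exact^2))
  }, 0)
  expect_lt(err[2], err[1])   # refinement shrinks the L2 error
  expect_lt(err[2], 0.05)
})

test_that("insulated conduction conserves discrete thermal energy exactly", {
  p <- bioheatParams(w_b = 0)
  n <- c(11L, 11L, 11L)
  set.seed(1)
  T0 <- array(37 + runif(prod(n)), n)
  Q <- array(runif(prod(n), 0, 1e5), n)
  lab <- array(1L, n)
  h_mm <- 0.1
  dt <- stableTimestep(p, h_mm)
  v_m3 <- (h_mm * 1e-3)^3
  for (s in 1:5) {
    T1 <- heatSteps(T0, Q, lab, h_mm, p, dt, 1)
    dE <- sum(p@rho * p@c * (T1 - T0)) * v_m3
    expect_equal(dE, sum(Q) * v_m3 * dt, tolerance = 1e-9)
    T0 <- T1
  }
})

test_that("source-free conduction obeys the maximum principle", {
  p <- bioheatParams(w_b = 0)
  n <- c(9L, 9L, 9L)
  set.seed(2)
  T0 <- array(runif(prod(n), 30, 50), n)
  lab <- array(1L, n)
  dt <- stableTimestep(p, 0.1)
  Tn <- T0
  for (s in 1:20) {
    Tn <- heatSteps(Tn, array(0, n), lab, 0.1, p, dt, 1)
    expect_lte(max(Tn), max(T0) + 1e-12)
    expect_gte(min(Tn), min(T0) - 1e-12)
  }
})

test_that("heat labels exclude air, clamp the far-field faces, keep the skin adiabatic", {
  cfg <- tinyConfig()
  scn <- buildScene(cfg)
  lab <- heatLabels(scn)
  mg <- materialGrid(scn)
  airIdx <- match("air", attr(mg, "materials"))
  expect_true(all(lab[mg == airIdx] == 0L))
  expect_true(all(lab[mg != airIdx] %in% c(1L, 2L)))
  idx <- which(lab != 0L, arr.ind = TRUE)
  rz <- range(idx[, 3])
  top <- idx[idx[, 3] == rz[2], , drop = FALSE]     # skin layer
  bottom <- idx[idx[, 3] == rz[1], , drop = FALSE]  # deep face
  expect_true(all(lab[bottom] == 2L))
  # the interior of the skin face stays active (adiabatic, not clamped)
  interior <- top[top[, 1] > min(top[, 1]) & top[, 1] < max(top[, 1]) &
                  top[, 2] > min(top[, 2]) & top[, 2] < max(top[, 2]), ,
                  drop = FALSE]
  expect_true(all(lab[interior] == 1L))
  # insulated mode clamps nothing
  expect_true(all(heatLabels(scn, boundary = "insulated") != 2L))
})

test_that("runHeating records a uniform start and strictly increasing times", {
  cfg <- tinyConfig(packets = 5e3, duration = 3, record_interval = 1)
  scn <- buildScene(cfg)
  q <- runTransport(scn, packets = 5e3, seed = 2)
  hist <- runHeating(q, scn, bioheatParams(), duration = 3,
                     record_interval = 1)
  expect_identical(hist@times, c(0, 1, 2, 3))
  expect_true(all(hist@snapshots[[1]] == 37))
  expect_false(is.unsorted(hist@times, strictly = TRUE))
  # heating monotone under constant illumination at the tumour centre
  g <- voxelGrid(q)
  iz <- which.min(abs(voxelCenters(g, 3) - 1.75))
  ctr <- vapply(hist@snapshots, function(s) s[21, 21, iz], 0)
  expect_true(all(diff(ctr) >= 0))
  tf <- temperatureAt(hist, 2)
  expect_s4_class(tf, "TemperatureField")
  expect_identical(tf@time, 2)
  expect_error(temperatureAt(hist, 2.5), "not recorded")
})
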