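test_that("Beer-Lambert oracle closed forms", {
  expect_identical(beerLambertOracle(12, 0), 1)
  expect_equal(beerLambertOracle(12, 0.1), exp(-1.2))
  # doubling depth squares the fraction
  expect_equal(beerLambertOracle(5, 0.4), beerLambertOracle(5, 0.2)^2)
})

test_that("heat-kernel oracle is normalized and decays as t^(-3/2)", {
  D <- 0.53 / (1079 * 3540)
  expect_equal(D, 1.388e-7, tolerance = 1e-3)
  # amplitude at the origin scales as t^(-3/2)
  expect_equal(heatKernelOracle(D, 4, 0) / heatKernelOracle(D, 1, 0),
               4^(-3 / 2))
  # radial shell integral equals one
  r <- seq(0, 0.05, length.out = 20001)
  dr <- r[2] - r[1]
  for (t in c(0.5, 2)) {
    integral <- sum(4 * pi * r^2 * heatKernelOracle(D, t, r)) * dr
    expect_equal(integral, 1, tolerance = 1e-3)
  }
})

test_that("perfusion ODE oracle fixes its endpoints", {
  p <- bioheatParams()
  B <- perfusionCoefficient(p)
  expect_identical(perfusionOdeOracle(p, 1e5, 0), 37)
  expect_equal(perfusionOdeOracle(p, 1e5, 1e9), 37 + 1e5 / B)
  # scale check: the plateau for the peak nanorod deposition is far above
  # any physical tissue temperature, so conduction, not perfusion, must
  # set the real plateau
  expect_gt(3e7 / B, 700)
  expect_lt(3e7 / B, 900)
})
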