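# Forward model: sphere geometry, phase conversion, blur, stack synthesis.

test_that("sphere thickness follows the chord law", {
  cfg <- testOptics(pixelSizeNm = 50)
  scene <- ParticleScene(c(41L, 41L),
                         data.frame(x_px = 20, y_px = 20, diameter_nm = 300))
  h <- sphereThicknessProfile(scene, cfg)
  # apex equals the diameter
  expect_equal(h[21, 21], 300)
  # closed-form chord at rho = d/4 (two pixels = 100 nm is not d/4; probe
  # at 1 px = 50 nm in-plane distance)
  rho <- 50
  expect_equal(h[21, 22], 2 * sqrt(150^2 - rho^2))
  # quarter-diameter probe: chord = 0.8660 d, via a pixel at rho = d/4
  cfg75 <- testOptics(pixelSizeNm = 75)
  h75 <- sphereThicknessProfile(scene, cfg75)
  expect_equal(h75[21, 22], sqrt(3) / 2 * 300, tolerance = 1e-12)
  # zero outside the footprint
  expect_equal(h[21, 25], 0)  # rho = 200 nm > 150 nm
  expect_equal(sum(h[1, ]), 0)
})

test_that("sphere thickness matches a numeric vertical-line integration oracle", {
  # independent oracle: integrate the sphere indicator along z
  cfg <- testOptics(pixelSizeNm = 30)
  d <- 400
  scene <- ParticleScene(c(31L, 31L),
                         data.frame(x_px = 15, y_px = 15, diameter_nm = d))
  h <- sphereThicknessProfile(scene, cfg)
  zs <- seq(-d / 2, d / 2, length.out = 20001)
  dz <- zs[2] - zs[1]
  for (off in 0:5) {
    rho <- off * 30
    inside <- sum(zs^2 + rho^2 < (d / 2)^2) * dz
    expect_equal(h[16, 16 + off], inside, tolerance = 1e-3)
  }
})

test_that("overlapping particles add and out-of-grid centers error", {
  cfg <- testOptics(pixelSizeNm = 50)
  two <- ParticleScene(c(21L, 21L),
                       data.frame(x_px = c(10, 10), y_px = c(10, 10),
                                  diameter_nm = c(200, 300)))
  h <- sphereThicknessProfile(two, cfg)
  expect_equal(h[11, 11], 500)
  # the offending particle is named at construction already
  expect_error(
    ParticleScene(c(21L, 21L),
                  data.frame(x_px = 30, y_px = 10, diameter_nm = 100)),
    "particle\\(s\\) 1")
})

test_that("height-to-phase is the optical path length relation and is linear", {
  cfg <- testOptics()  # 660 nm, delta n 0.04, pass 1
  h <- matrix(660, 2, 2)
  expect_equal(phaseValues(heightToPhase(h, cfg))[1, 1], 2 * pi * 0.04,
               tolerance = 1e-12)
  cfg2 <- testOptics(passFactor = 2)
  expect_equal(phaseValues(heightToPhase(h, cfg2))[1, 1], 4 * pi * 0.04,
               tolerance = 1e-12)
  expect_true(all(phaseValues(heightToPhase(matrix(0, 3, 3), cfg)) == 0))
  # linearity to floating rounding
  hr <- matrix(runif(64, 0, 800), 8, 8)
  for (alpha in c(0, 0.3, 2.5)) {
    expect_equal(phaseValues(heightToPhase(alpha * hr, cfg)),
                 alpha * phaseValues(heightToPhase(hr, cfg)),
                 tolerance = 1e-14)
  }
  expect_error(heightToPhase(matrix(-1, 2, 2), cfg), "non-negative")
})

test_that("phase round-trips through height across optics grids", {
  h <- matrix(runif(256, 0, 1200), 16, 16)
  for (lam in c(488, 660)) for (dn in c(0.02, 0.04, 0.1)) for (p in c(1, 2)) {
    cfg <- testOptics(wavelengthNm = lam, deltaN = dn, passFactor = p)
    back <- phaseToHeight(heightToPhase(h, cfg), cfg)
    expect_lt(max(abs(back - h)) / max(h), 1e-9)
  }
})

test_that("diffraction blur: identity, fixed point, and brute-force oracle", {
  cfg0 <- testOptics(psfFwhmNm = 0)
  p <- PhaseMap(matrix(runif(100, 0, 0.3), 10, 10), cfg0)
  expect_identical(phaseValues(applyDiffractionBlur(p)), phaseValues(p))

  cfgB <- testOptics(psfFwhmNm = 500)
  uni <- PhaseMap(matrix(0.1, 16, 16), cfgB)
  expect_equal(phaseValues(applyDiffractionBlur(uni)),
               matrix(0.1, 16, 16), tolerance = 1e-12)

  # brute-force replicate-boundary convolution of the complex field
  scene <- ParticleScene(c(25L, 25L),
                         data.frame(x_px = 12, y_px = 12, diameter_nm = 100))
  phi <- phaseValues(heightToPhase(sphereThicknessProfile(scene, cfgB), cfgB))
  blurred <- phaseValues(applyDiffractionBlur(PhaseMap(phi, cfgB)))
  sigmaPx <- 500 / (2 * sqrt(2 * log(2))) / 86
  half <- ceiling(4 * sigmaPx)
  ax <- -half:half
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigmaPx^2))
  k <- k / sum(k)
  oracle <- matrix(0, 25, 25)
  clampIdx <- function(i) pmin(pmax(i, 1L), 25L)
  f <- exp(1i * phi)
  for (r in 1:25) for (cc in 1:25) {
    patch <- f[clampIdx(r + ax), clampIdx(cc + ax)]
    oracle[r, cc] <- Arg(sum(k * patch))
  }
  expect_equal(blurred, oracle, tolerance = 1e-10)
  # isolated-particle max is strictly reduced and non-increasing in FWHM
  prev <- max(phi)
  for (fw in c(250, 500, 750)) {
    cfgF <- testOptics(psfFwhmNm = fw)
    b <- max(phaseValues(applyDiffractionBlur(PhaseMap(phi, cfgF))))
    expect_lt(b, prev + 1e-12)
    prev <- b
  }
  expect_warning(
    applyDiffractionBlur(PhaseMap(phi, testOptics(psfFwhmNm = 50))),
    "below one pixel")
})

test_that("interferogram synthesis satisfies the fringe equation exactly", {
  cfg <- testOptics()
  cases <- list(list(phi = 0, delta = 0, expect = 150),
                list(phi = pi / 2, delta = 0, expect = 100),
                list(phi = 0, delta = pi, expect = 50))
  for (cs in cases) {
    p <- PhaseMap(matrix(cs$phi, 4, 4), cfg)
    st <- synthesizeInterferogramStack(p, cs$delta, A = 100, B = 50)
    expect_equal(stackFrames(st)[[1]], matrix(cs$expect, 4, 4),
                 tolerance = 1e-12)
  }
  # noiseless stacks reproduce A + B cos(phi + delta) with zero residual
  phi <- smoothRandomPhase(c(12L, 12L), 0.5, seed = 3)
  sh <- c(0, 1.1, 2.7)
  st <- synthesizeInterferogramStack(PhaseMap(phi, cfg), sh, A = 200, B = 80)
  for (r in 1:3) {
    expect_equal(stackFrames(st)[[r]], 200 + 80 * cos(phi + sh[r]),
                 tolerance = 1e-12)
  }
  expect_error(synthesizeInterferogramStack(PhaseMap(phi, cfg), numeric(0)),
               "at least one")
  expect_error(synthesizeInterferogramStack(PhaseMap(phi, cfg), 0,
                                            noiseSigma = -1), "non-negative")
  expect_error(synthesizeInterferogramStack(PhaseMap(phi, cfg), 0,
                                            A = 10, B = 50), "A >= B")
})

test_that("scene simulation is seeded, separated and consistent", {
  s1 <- simulateScene(2, list(type = "point", value_nm = 300),
                      gridShape = c(128L, 128L), minSeparationPx = 50, seed = 11)
  s2 <- simulateScene(2, list(type = "point", value_nm = 300),
                      gridShape = c(128L, 128L), minSeparationPx = 50, seed = 11)
  expect_identical(particles(s1$scene), particles(s2$scene))
  expect_identical(stackFrames(s1$stack), stackFrames(s2$stack))
  p <- particles(s1$scene)
  expect_equal(nrow(p), 2)
  expect_gte(sqrt(diff(p$x_px)^2 + diff(p$y_px)^2), 50)
  # empty scene: flat phase, pure background fringes
  s0 <- simulateScene(0, gridShape = c(32L, 32L), seed = 1)
  expect_equal(max(abs(phaseValues(s0$phase))), 0)
  expect_equal(stackFrames(s0$stack)[[1]], matrix(200 + 100, 32, 32),
               tolerance = 1e-12)
  # stack is the composition of the forward operations
  expect_equal(stackFrames(s1$stack)[[2]],
               200 + 100 * cos(phaseValues(s1$phase) + 2 * pi / 5),
               tolerance = 1e-12)
  # placement failure reports achieved count
  expect_error(
    simulateScene(10, list(type = "point", value_nm = 100),
                  gridShape = c(24L, 24L), minSeparationPx = 200, seed = 1),
    "placement failed")
})
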