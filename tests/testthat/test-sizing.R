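# Sizing: phase-to-height, detection, diameter estimation, distributions.

test_that("phase-to-height inverts the optical path relation", {
  cfg <- testOptics()
  expect_equal(phaseToHeight(2 * pi * 0.04, cfg), 660, tolerance = 1e-12)
  expect_equal(phaseToHeight(0, cfg), 0)
  # doubling delta n halves the height
  cfg2 <- testOptics(deltaN = 0.08)
  expect_equal(phaseToHeight(0.1, cfg2), phaseToHeight(0.1, cfg) / 2,
               tolerance = 1e-12)
  expect_error(OpticalConfig(deltaN = 0))
  # exact inverse of the forward conversion
  h <- matrix(runif(64, 0, 900), 8, 8)
  for (p in c(1, 2)) {
    cfgP <- testOptics(passFactor = p)
    expect_lt(max(abs(phaseToHeight(heightToPhase(h, cfgP), cfgP) - h)) /
                max(h), 1e-9)
  }
})

test_that("detection finds well-separated particles at true centroids", {
  cfg <- testOptics()
  scene <- ParticleScene(c(96L, 96L),
                         data.frame(x_px = c(20, 80), y_px = c(30, 60),
                                    diameter_nm = c(400, 600)))
  phase <- heightToPhase(sphereThicknessProfile(scene, cfg), cfg)
  det <- detectParticles(phase, minAreaPx = 1L)
  expect_equal(nrow(det), 2)
  # sorted by descending max phase: the 600 nm particle first
  expect_equal(det$particle_id, c(1L, 2L))
  expect_equal(det$max_phase_rad[1], phaseValues(heightToPhase(600, cfg))[1])
  ord <- order(det$x_px)
  expect_lt(max(abs(det$x_px[ord] - c(20, 80))), 1)
  expect_lt(max(abs(det$y_px[ord] - c(30, 60))), 1)
  # empty scene, zero noise: nothing above threshold
  flat <- PhaseMap(matrix(0, 32, 32), cfg)
  expect_equal(nrow(detectParticles(flat)), 0)
})

test_that("pure-noise maps yield almost no false detections", {
  cfg <- testOptics()
  hits <- vapply(1:100, function(seed) {
    m <- withr::with_seed(seed, matrix(rnorm(64 * 64, 0, 0.005), 64, 64))
    nrow(detectParticles(PhaseMap(m, cfg), kSigma = 5, minAreaPx = 2L))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("diameters recover truth unblurred and underestimate under blur", {
  cfg <- testOptics()
  sim <- simulateScene(1, list(type = "point", value_nm = 200),
                       gridShape = c(64L, 64L), seed = 3, config = cfg)
  res <- retrievePhaseKnownShifts(sim$stack)
  cl <- removeBackground(new("PhaseMap",
                             values = phaseValues(retrievedPhase(res)),
                             optics = cfg), "median")
  det <- estimateDiameters(detectParticles(cl, minAreaPx = 1L), cfg)
  expect_equal(nrow(det), 1)
  expect_equal(det$diameter_nm, 200, tolerance = 4 / 200)
  expect_equal(det$height_nm, det$diameter_nm)

  cfgB <- testOptics(psfFwhmNm = 500)
  simB <- simulateScene(1, list(type = "point", value_nm = 100),
                        gridShape = c(64L, 64L), seed = 3, config = cfgB)
  resB <- retrievePhaseKnownShifts(simB$stack)
  clB <- removeBackground(new("PhaseMap",
                              values = phaseValues(retrievedPhase(resB)),
                              optics = cfgB), "median")
  detB <- estimateDiameters(detectParticles(clB, minAreaPx = 1L), cfgB)
  expect_gte(nrow(detB), 1)
  expect_lt(max(detB$diameter_nm), 100)
})

test_that("size distributions weight by number or by d^6 intensity", {
  d <- c(100, 200)
  di <- buildSizeDistribution(d, weighting = "intensity")
  w <- distWeights(di)
  expect_equal(w[2] / w[1], 64, tolerance = 1e-12)
  expect_equal(sum(w), 1)
  # monodisperse: PdI 0, mean = mode = the common diameter
  dm <- buildSizeDistribution(rep(300, 7), binWidthNm = 20)
  s <- sizeSummary(dm)
  expect_equal(s$pdi, 0)
  expect_equal(s$mean_nm, 300)
  expect_equal(s$mode_nm, 290)  # center of the (280, 300] bin
  expect_equal(sum(binCounts(dm)), 7)
  # intensity-weighted mean dominates the number-weighted mean
  withr::with_seed(9, {
    for (i in 1:20) {
      dd <- rlnorm(30, log(150), 0.5)
      mn <- sizeSummary(buildSizeDistribution(dd, "number"))$mean_nm
      mi <- sizeSummary(buildSizeDistribution(dd, "intensity"))$mean_nm
      expect_gte(mi, mn)
    }
  })
  # empty input is flagged, not an error
  e <- buildSizeDistribution(numeric(0))
  expect_equal(sizeSummary(e)$n, 0L)
  expect_true(is.na(sizeSummary(e)$mean_nm))
})

test_that("diameter estimates fall with the assumed index contrast", {
  cfg <- testOptics()
  tab <- refractiveIndexSensitivity(2 * pi * 0.04, cfg,
                                    deltaNGrid = c(0.02, 0.04, 0.08))
  expect_equal(tab$diameter_nm, c(1320, 660, 330), tolerance = 1e-12)
  expect_true(all(diff(tab$diameter_nm) < 0))
  expect_error(refractiveIndexSensitivity(0.1, cfg, deltaNGrid = c(0.04, 0)),
               "positive")
})
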