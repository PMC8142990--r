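# Phase retrieval: known-shift least squares, shift estimation, the AIA
# alternation, and background removal.

test_that("four-step quarter-wave retrieval equals the closed form", {
  cfg <- testOptics()
  for (seed in 1:5) {
    phi <- smoothRandomPhase(c(32L, 32L), 0.7, seed = seed)
    st <- synthesizeInterferogramStack(PhaseMap(phi, cfg),
                                       c(0, pi / 2, pi, 3 * pi / 2),
                                       A = 120, B = 60)
    I <- stackFrames(st)
    closedForm <- atan2(I[[4]] - I[[2]], I[[1]] - I[[3]])
    got <- phaseValues(retrievedPhase(retrievePhaseKnownShifts(st)))
    expect_lt(max(abs(got - closedForm)), 1e-9)
  }
})

test_that("noiseless known-shift retrieval recovers truth and modulation", {
  cfg <- testOptics()
  for (seed in 1:3) {
    M <- 3 + seed %% 3
    sh <- randomShifts(M, seed = seed + 10)
    phi <- smoothRandomPhase(c(24L, 24L), 0.6, seed = seed)
    st <- synthesizeInterferogramStack(PhaseMap(phi, cfg), sh, A = 150, B = 70)
    res <- retrievePhaseKnownShifts(st)
    expect_lt(max(abs(phaseValues(retrievedPhase(res)) - phi)), 1e-9)
    abc <- abcMaps(res)
    Bhat <- sqrt(abc@b^2 + abc@c^2)
    expect_lt(max(abs(Bhat - 70)) / 70, 0.01)
    expect_lt(max(abs(abc@a - 150)), 1e-8)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  cfg <- testOptics()
  phi <- smoothRandomPhase(c(8L, 8L), 0.5, seed = 1)
  st2 <- synthesizeInterferogramStack(PhaseMap(phi, cfg), c(0, 1))
  expect_error(retrievePhaseKnownShifts(st2), "underdetermined")
  st3 <- synthesizeInterferogramStack(PhaseMap(phi, cfg), c(0, pi, 2 * pi))
  expect_error(retrievePhaseKnownShifts(st3), "singular")
  # spatially uniform phase cannot identify the shifts
  stU <- synthesizeInterferogramStack(PhaseMap(matrix(0.2, 8, 8), cfg),
                                      c(0, 1, 2))
  expect_error(estimateShiftsGivenPhase(stU, PhaseMap(matrix(0.2, 8, 8), cfg)),
               "degenerate phase")
})

test_that("shift estimation from the true phase recovers anchored shifts", {
  cfg <- testOptics()
  phi <- smoothRandomPhase(c(32L, 32L), 0.8, seed = 5)
  st <- synthesizeInterferogramStack(PhaseMap(phi, cfg), c(0, 1.0, 2.2),
                                     A = 100, B = 50)
  est <- estimateShiftsGivenPhase(st, PhaseMap(phi, cfg))
  expect_lt(max(abs(est - c(0, 1.0, 2.2))), 1e-9)
  # anchoring subtracts the first shift
  st2 <- synthesizeInterferogramStack(PhaseMap(phi, cfg), c(0.5, 1.5),
                                      A = 100, B = 50)
  est2 <- estimateShiftsGivenPhase(st2, PhaseMap(phi, cfg))
  expect_lt(max(abs(est2 - c(0, 1.0))), 1e-9)
})

test_that("AIA recovers phase and shifts on noiseless stacks", {
  cfg <- testOptics()
  phi <- smoothRandomPhase(c(48L, 48L), 2, seed = 21)
  sh <- c(0, 1.3, 2.1, 4.0, 5.5)
  st <- synthesizeInterferogramStack(PhaseMap(phi, cfg), sh, A = 150, B = 70)
  res <- aiaRetrieve(st, tolRad = 1e-6)
  expect_true(converged(res))
  al <- alignRetrieval(phaseValues(retrievedPhase(res)), frameShifts(res),
                       phi, sh)
  expect_lt(al$shiftRmse, 1e-4)
  expect_lt(al$phaseRmse, 1e-4)

  # initializing at the truth is a fixed point: one iteration, tiny change
  res2 <- aiaRetrieve(st, initShiftsRad = sh, tolRad = 1e-6)
  expect_equal(iterations(res2), 1L)
  expect_lt(shiftHistory(res2)[1], 1e-6)
})

test_that("AIA parameter recovery holds across seeds and frame counts", {
  cfg <- testOptics()
  for (seed in 1:8) {
    M <- 3 + (seed %% 3)
    sh <- randomShifts(M, seed = 100 + seed)
    phi <- smoothRandomPhase(c(32L, 32L), 3, seed = 200 + seed)
    st <- synthesizeInterferogramStack(PhaseMap(phi, cfg), sh, A = 150, B = 70)
    res <- aiaRetrieve(st, maxIter = 300L)
    al <- alignRetrieval(phaseValues(retrievedPhase(res)), frameShifts(res),
                         phi, sh)
    expect_lt(al$shiftRmse, 1e-3)
    expect_lt(al$phaseRmse, 1e-3)
    # shift-change history ends below tolerance in noiseless runs
    expect_lt(tail(shiftHistory(res), 1), 1e-6)
  }
})

test_that("AIA tolerates 1% camera noise on three-frame stacks", {
  cfg <- testOptics()
  rmses <- vapply(1:5, function(seed) {
    phi <- smoothRandomPhase(c(48L, 48L), 3, seed = 300 + seed)
    sh <- c(0, 2 * pi / 3, 4 * pi / 3)
    st <- synthesizeInterferogramStack(PhaseMap(phi, cfg), sh, A = 150, B = 70,
                                       noiseSigma = 0.7, seed = seed)
    res <- aiaRetrieve(st)
    alignRetrieval(phaseValues(retrievedPhase(res)), frameShifts(res),
                   phi, sh)$phaseRmse
  }, numeric(1))
  expect_lt(max(rmses), 0.02)
})

test_that("background removal: reference, polynomial and median modes", {
  cfg <- testOptics()
  phi <- smoothRandomPhase(c(24L, 24L), 0.4, seed = 7)
  p <- PhaseMap(phi, cfg)
  # self-subtraction is exactly zero
  expect_equal(phaseValues(removeBackground(p, "reference", reference = p)),
               matrix(0, 24, 24))
  expect_error(removeBackground(p, "reference"), "requires a reference")
  expect_error(removeBackground(p, "reference",
                                reference = matrix(0, 3, 3)), "shape")
  # a pure tilted plane is removed to rounding by an order-1 fit
  plane <- outer(seq(-0.5, 0.5, length.out = 24), rep(1, 24)) * 0.8 +
           outer(rep(1, 24), seq(-0.5, 0.5, length.out = 24)) * -0.3
  res <- removeBackground(PhaseMap(plane, cfg), "polynomial", order = 1L)
  expect_lt(max(abs(phaseValues(res))), 1e-9)
  expect_error(removeBackground(p, "polynomial", order = -1L), "non-negative")
  # plane + one particle: the particle apex survives within 2%
  scene <- ParticleScene(c(64L, 64L),
                         data.frame(x_px = 32, y_px = 32, diameter_nm = 400))
  bump <- phaseValues(heightToPhase(sphereThicknessProfile(scene, cfg), cfg))
  tilt <- outer(seq(-0.4, 0.4, length.out = 64), rep(1, 64))
  cl <- removeBackground(PhaseMap(bump + tilt, cfg), "polynomial", order = 2L)
  expect_equal(max(phaseValues(cl)), max(bump), tolerance = 0.02)
  # median mode zeroes the median
  md <- removeBackground(p, "median")
  expect_equal(median(phaseValues(md)), 0)
})

test_that("labeling agrees with an independent 4-connectivity oracle", {
  withr::with_seed(42, {
    for (i in 1:5) {
      m <- matrix(runif(400) < 0.3, 20, 20)
      mine <- qpmsizer:::labelComponents(m, connectivity = 4)
      ref <- EBImage::bwlabel(m)
      # same partition: compare co-membership via cross-tabulation
      expect_equal(max(mine), max(ref))
      tab <- table(mine[m], ref[m])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
  })
  # 8-connectivity joins diagonals
  m <- matrix(FALSE, 5, 5); m[cbind(c(1, 2), c(1, 2))] <- TRUE
  expect_equal(max(qpmsizer:::labelComponents(m, 8)), 1)
  expect_equal(max(qpmsizer:::labelComponents(m, 4)), 2)
})
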