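# End-to-end experiments: simulate -> retrieve -> remove background ->
# size, with ground-truth recovery reports and parameter sweeps.

#' Create an experiment configuration
#'
#' Assembles the full specification of a seeded end-to-end run. Any subset
#' of the list arguments may be given; missing entries take the defaults
#' below.
#'
#' @param optics an \linkS4class{OpticalConfig}
#' @param scene list with n_particles (10), diameter sampler spec
#'   (list(type = "point", value_nm = 200); types "point", "lognormal",
#'   "bimodal"), grid_shape (c(128, 128)), min_separation_px (20), and
#'   background (list(tilt_x_rad = 0.6, tilt_y_rad = -0.4,
#'   curvature_rad = 0.2) or NULL) -- a smooth background phase emulating
#'   residual interferometer tilt/curvature, removed numerically downstream
#' @param acquisition list with n_frames (5; used when shifts is NULL),
#'   shifts (NULL = equally spaced over [0, 2pi)), A (200), B (100),
#'   noise_sigma (0)
#' @param retrieval list with mode ("known" or "aia"; default "known"),
#'   tol_rad (1e-6), max_iter (100), background_method ("polynomial"),
#'   background_order (2)
#' @param sizing list with k_sigma (3), min_area_px (2), connectivity (8),
#'   min_phase_rad (2e-4), smooth_fwhm_nm (0), bin_width_nm (20),
#'   weighting ("number"), match_radius_px (5)
#' @param seed integer master seed
#' @return an \linkS4class{ExperimentConfig}
#' @export
ExperimentConfig <- function(optics = OpticalConfig(), scene = list(),
                             acquisition = list(), retrieval = list(),
                             sizing = list(), seed = 1L) {
  fill <- function(given, defaults) {
    for (nm in names(defaults))
      if (is.null(given[[nm]])) given[[nm]] <- defaults[[nm]]
    given
  }
  scene <- fill(scene, list(
    n_particles = 10L,
    diameter = list(type = "point", value_nm = 200),
    grid_shape = c(128L, 128L),
    min_separation_px = 20,
    background = list(tilt_x_rad = 0.6, tilt_y_rad = -0.4, curvature_rad = 0.2)))
  acquisition <- fill(acquisition, list(
    n_frames = 5L, shifts = NULL, A = 200, B = 100, noise_sigma = 0))
  retrieval <- fill(retrieval, list(
    mode = "known", tol_rad = 1e-6, max_iter = 100L,
    background_method = "polynomial", background_order = 2L))
  sizing <- fill(sizing, list(
    k_sigma = 3, min_area_px = 2L, connectivity = 8, min_phase_rad = 2e-4,
    smooth_fwhm_nm = 0, bin_width_nm = 20, weighting = "number",
    match_radius_px = 5))
  if (retrieval$mode == "aia" &&
      (if (is.null(acquisition$shifts)) acquisition$n_frames else length(acquisition$shifts)) < 3L)
    stop("AIA retrieval requires at least 3 frames")
  new("ExperimentConfig", optics = optics, scene = scene,
      acquisition = acquisition, retrieval = retrieval, sizing = sizing,
      seed = as.integer(seed))
}

setMethod("show", "ExperimentConfig", function(object) {
  cat(sprintf(
    "ExperimentConfig: %d particle(s), %s retrieval, seed %d\n",
    object@scene$n_particles, object@retrieval$mode, object@seed))
  show(object@optics)
})

# Greedy nearest-centroid pairing of truth and detections within a radius.
matchDetections <- function(truth, det, radiusPx) {
  if (!nrow(truth) || !nrow(det)) {
    return(data.frame(true_id = integer(0), det_id = integer(0),
                      dist_px = numeric(0), true_diameter_nm = numeric(0),
                      est_diameter_nm = numeric(0)))
  }
  D <- sqrt(outer(truth$y_px, det$y_px, "-")^2 +
            outer(truth$x_px, det$x_px, "-")^2)
  pairs <- which(D <= radiusPx, arr.ind = TRUE)
  if (!nrow(pairs)) {
    return(data.frame(true_id = integer(0), det_id = integer(0),
                      dist_px = numeric(0), true_diameter_nm = numeric(0),
                      est_diameter_nm = numeric(0)))
  }
  ord <- order(D[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  usedT <- logical(nrow(truth)); usedD <- logical(nrow(det))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ti <- pairs[i, 1L]; di <- pairs[i, 2L]
    if (!usedT[ti] && !usedD[di]) {
      usedT[ti] <- TRUE; usedD[di] <- TRUE; keep[i] <- TRUE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(true_id = pairs[, 1L],
             det_id = det$particle_id[pairs[, 2L]],
             dist_px = D[pairs],
             true_diameter_nm = truth$diameter_nm[pairs[, 1L]],
             est_diameter_nm = det$diameter_nm[pairs[, 2L]])
}

#' Run a complete simulated sizing experiment
#'
#' Executes the six pipeline stages in order: synthesize the phase-shifted
#' stack of a random particle field, retrieve the phase (known shifts or
#' AIA), remove the background phase, convert to height, detect and size the
#' particles, and build the size distribution. Deterministic per seed. When
#' an output directory is given, every intermediate artifact is written
#' (stack, raw and cleaned phase, height map, truth and particle CSVs,
#' distribution CSV, summary and manifest JSON).
#'
#' @param config an \linkS4class{ExperimentConfig}
#' @param outDir optional output directory
#' @return list with scene, stack, retrieval, phase (cleaned), height,
#'   particleTable, distribution and report (a
#'   \linkS4class{RecoveryReport})
#' @export
runEndToEnd <- function(config, outDir = NULL) {
  stopifnot(is(config, "ExperimentConfig"))
  opt <- config@optics
  sc <- config@scene
  aq <- config@acquisition
  rt <- config@retrieval
  sz <- config@sizing
  shifts <- if (is.null(aq$shifts)) 2 * pi * (seq_len(aq$n_frames) - 1L) / aq$n_frames
            else as.numeric(aq$shifts)

  sim <- simulateScene(sc$n_particles, diameter = sc$diameter,
                       gridShape = sc$grid_shape,
                       minSeparationPx = sc$min_separation_px,
                       seed = config@seed, config = opt,
                       shiftsRad = shifts, A = aq$A, B = aq$B,
                       noiseSigma = aq$noise_sigma,
                       background = sc$background)

  ret <- if (rt$mode == "aia") {
    aiaRetrieve(sim$stack, tolRad = rt$tol_rad, maxIter = rt$max_iter)
  } else {
    retrievePhaseKnownShifts(sim$stack, shifts)
  }
  rawPhase <- new("PhaseMap", values = phaseValues(retrievedPhase(ret)),
                  optics = opt)
  # AIA phase is defined up to a global sign flip; orient it so the field
  # skews positive (particles are positive bumps).
  if (rt$mode == "aia") {
    v <- phaseValues(rawPhase)
    r <- v - fitPolynomialSurface(v, rt$background_order)
    if (mean(r^3) < 0)
      rawPhase <- new("PhaseMap", values = -v, optics = opt)
  }
  cleaned <- removeBackground(rawPhase, method = rt$background_method,
                              order = rt$background_order)
  height <- phaseToHeight(cleaned, opt)
  det <- detectParticles(cleaned, kSigma = sz$k_sigma,
                         minAreaPx = sz$min_area_px,
                         connectivity = sz$connectivity,
                         minPhaseRad = sz$min_phase_rad,
                         smoothFwhmNm = sz$smooth_fwhm_nm)
  det <- estimateDiameters(det, opt)
  dist <- buildSizeDistribution(det, weighting = sz$weighting,
                                binWidthNm = sz$bin_width_nm)

  truth <- particles(sim$scene)
  matches <- matchDetections(truth, det, sz$match_radius_px)
  err <- matches$est_diameter_nm - matches$true_diameter_nm
  shiftRmse <- NA_real_
  if (rt$mode == "aia" && length(frameShifts(sim$stack))) {
    true <- wrapPi(frameShifts(sim$stack) - frameShifts(sim$stack)[1L])
    est <- frameShifts(ret)
    errPlus <- wrapPi(est - true)
    errMinus <- wrapPi(-est - true)
    shiftRmse <- min(sqrt(mean(errPlus^2)), sqrt(mean(errMinus^2)))
  }
  report <- new("RecoveryReport",
    nTrue = nrow(truth), nDetected = nrow(det), nMatched = nrow(matches),
    falsePositives = nrow(det) - nrow(matches),
    countError = nrow(det) - nrow(truth),
    diameterBiasNm = if (length(err)) mean(err) else NA_real_,
    diameterRmseNm = if (length(err)) sqrt(mean(err^2)) else NA_real_,
    shiftRmseRad = shiftRmse,
    converged = converged(ret),
    matches = matches)

  result <- list(scene = sim$scene, stack = sim$stack, retrieval = ret,
                 rawPhase = rawPhase, phase = cleaned, height = height,
                 particleTable = det, distribution = dist, report = report)
  if (!is.null(outDir)) writeRunArtifacts(result, config, outDir)
  result
}

#' Sweep one parameter of an experiment over a grid of values and seeds
#'
#' Runs \code{\link{runEndToEnd}} once per (value, seed) combination and
#' collects recovery metrics in a tidy table. A failing run is recorded in
#' its row's \code{failure} column and the sweep continues.
#'
#' @param config base \linkS4class{ExperimentConfig}
#' @param param one of "diameter_nm", "psf_fwhm_nm", "noise_sigma",
#'   "n_particles"
#' @param values grid of parameter values
#' @param nSeeds seeds 1..nSeeds are added to the base seed
#' @return data.frame, one row per (value, seed): n_true, n_detected,
#'   count_error, bias_nm, rmse_nm, converged, failure
#' @export
runRecoverySweep <- function(config, param, values, nSeeds = 1L) {
  stopifnot(length(values) >= 1L, nSeeds >= 1L)
  param <- match.arg(param,
                     c("diameter_nm", "psf_fwhm_nm", "noise_sigma", "n_particles"))
  rows <- list()
  for (valIdx in seq_along(values)) {
    val <- values[valIdx]
    for (s in seq_len(nSeeds)) {
      cfg <- config
      cfg@seed <- as.integer(config@seed + (s - 1L))
      cfg <- switch(param,
        diameter_nm = { cfg@scene$diameter <- list(type = "point", value_nm = val); cfg },
        psf_fwhm_nm = { cfg@optics@psfFwhmNm <- as.numeric(val); cfg },
        noise_sigma = { cfg@acquisition$noise_sigma <- as.numeric(val); cfg },
        n_particles = { cfg@scene$n_particles <- as.integer(val); cfg })
      row <- tryCatch({
        r <- runEndToEnd(cfg)$report
        data.frame(param = param, value = val, seed = cfg@seed,
                   n_true = r@nTrue, n_detected = r@nDetected,
                   count_error = r@countError, bias_nm = r@diameterBiasNm,
                   rmse_nm = r@diameterRmseNm, converged = r@converged,
                   failure = NA_character_)
      }, error = function(e) {
        data.frame(param = param, value = val, seed = cfg@seed,
                   n_true = NA_integer_, n_detected = NA_integer_,
                   count_error = NA_integer_, bias_nm = NA_real_,
                   rmse_nm = NA_real_, converged = NA,
                   failure = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
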