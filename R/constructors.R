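#' Create an optical configuration
#'
#' @param wavelengthNm vacuum wavelength in nm. Default 660 nm.
#' @param deltaN refractive-index contrast between particle and medium.
#'   Default 0.04, the value assumed for lipid vesicles in aqueous medium.
#' @param passFactor 1 for transmission, 2 for reflection (double pass).
#'   Default 1, matching the phase-height relation as written.
#' @param pixelSizeNm object-plane sampling in nm per pixel. Default 86 nm,
#'   which Nyquist-samples a 500 nm PSF comfortably.
#' @param psfFwhmNm FWHM of the Gaussian diffraction blur in nm; 0 disables
#'   blurring. Default 0.
#'
#' @return an \linkS4class{OpticalConfig}
#' @examples
#' cfg <- OpticalConfig()
#' wavelengthNm(cfg)
#' @export
OpticalConfig <- function(wavelengthNm = 660, deltaN = 0.04, passFactor = 1,
                          pixelSizeNm = 86, psfFwhmNm = 0) {
  new("OpticalConfig",
      wavelengthNm = as.numeric(wavelengthNm),
      deltaN = as.numeric(deltaN),
      passFactor = as.numeric(passFactor),
      pixelSizeNm = as.numeric(pixelSizeNm),
      psfFwhmNm = as.numeric(psfFwhmNm))
}

#' Create a ground-truth particle scene
#'
#' @param gridShape integer (rows, cols) of the pixel grid
#' @param particles data.frame with columns x_px, y_px (0-based pixel
#'   coordinates, x = column, y = row) and diameter_nm; may be empty
#' @param seed integer seed used for any randomized placement (NA if none)
#'
#' @return a \linkS4class{ParticleScene}
#' @export
ParticleScene <- function(gridShape,
                          particles = data.frame(x_px = numeric(0),
                                                 y_px = numeric(0),
                                                 diameter_nm = numeric(0)),
                          seed = NA_integer_) {
  new("ParticleScene",
      gridShape = as.integer(gridShape),
      particles = as.data.frame(particles),
      seed = as.integer(seed))
}

#' Create a phase map
#'
#' Warns when the small-phase operating assumption |phi| < pi is violated.
#'
#' @param values numeric matrix of phase in radians
#' @param optics an \linkS4class{OpticalConfig}
#'
#' @return a \linkS4class{PhaseMap}
#' @export
PhaseMap <- function(values, optics = OpticalConfig()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(abs(values) >= pi)) {
    warning("phase map contains |phi| >= pi; the no-wrapping assumption is violated",
            call. = FALSE)
  }
  new("PhaseMap", values = values, optics = optics)
}

#' Create an interferogram stack
#'
#' @param frames list of same-shape numeric matrices
#' @param shiftsRad per-frame phase shifts in radians, or NULL when unknown
#' @param backgroundA scalar or matrix background (default NA, unknown)
#' @param modulationB scalar or matrix modulation (default NA, unknown)
#' @param noiseSigma additive Gaussian noise sd used at generation (0 if
#'   noiseless or unknown)
#' @param seed integer noise seed (NA if none)
#'
#' @return an \linkS4class{InterferogramStack}
#' @export
InterferogramStack <- function(frames, shiftsRad = NULL, backgroundA = NA_real_,
                               modulationB = NA_real_, noiseSigma = 0,
                               seed = NA_integer_) {
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "double"; f
  })
  new("InterferogramStack",
      frames = frames,
      shiftsRad = if (is.null(shiftsRad)) numeric(0) else as.numeric(shiftsRad),
      backgroundA = backgroundA,
      modulationB = modulationB,
      noiseSigma = as.numeric(noiseSigma),
      seed = as.integer(seed))
}

## ---- accessors ----

#' @describeIn OpticalConfig-class vacuum wavelength in nm
#' @param x object
#' @export
wavelengthNm <- function(x) x@wavelengthNm

#' @describeIn OpticalConfig-class refractive-index contrast
#' @export
deltaN <- function(x) x@deltaN

#' @describeIn OpticalConfig-class pass factor (1 or 2)
#' @export
passFactor <- function(x) x@passFactor

#' @describeIn OpticalConfig-class object-plane pixel size in nm
#' @export
pixelSizeNm <- function(x) x@pixelSizeNm

#' @describeIn OpticalConfig-class blur FWHM in nm
#' @export
psfFwhmNm <- function(x) x@psfFwhmNm

#' Extract the optical configuration of an object
#' @param x a PhaseMap or ExperimentConfig
#' @return an \linkS4class{OpticalConfig}
#' @export
optics <- function(x) x@optics

#' Phase values of a phase map
#' @param x a \linkS4class{PhaseMap}
#' @return numeric matrix in radians
#' @export
phaseValues <- function(x) x@values

#' Frames of an interferogram stack
#' @param x an \linkS4class{InterferogramStack}
#' @return list of matrices
#' @export
stackFrames <- function(x) x@frames

#' Number of frames in a stack
#' @param x an \linkS4class{InterferogramStack}
#' @export
nFrames <- function(x) length(x@frames)

#' Per-frame phase shifts of a stack or retrieval result
#' @param x an \linkS4class{InterferogramStack} or
#'   \linkS4class{RetrievalResult}
#' @return numeric vector in radians (length 0 when unknown)
#' @export
frameShifts <- function(x) x@shiftsRad

#' Ground-truth particle table of a scene
#' @param x a \linkS4class{ParticleScene}
#' @return data.frame with x_px, y_px, diameter_nm
#' @export
particles <- function(x) x@particles

#' Grid shape of a scene
#' @param x a \linkS4class{ParticleScene}
#' @return integer (rows, cols)
#' @export
gridShape <- function(x) x@gridShape

#' Recovered phase map of a retrieval result
#' @param x a \linkS4class{RetrievalResult}
#' @export
retrievedPhase <- function(x) x@phase

#' Coefficient maps of a retrieval result
#' @param x a \linkS4class{RetrievalResult}
#' @export
abcMaps <- function(x) x@abc

#' Convergence flag of a retrieval result
#' @param x a \linkS4class{RetrievalResult}
#' @export
converged <- function(x) x@converged

#' Number of AIA iterations performed
#' @param x a \linkS4class{RetrievalResult}
#' @export
iterations <- function(x) x@iterations

#' Per-iteration maximum shift change
#' @param x a \linkS4class{RetrievalResult}
#' @return numeric vector in radians (empty for the direct solve)
#' @export
shiftHistory <- function(x) x@shiftHistory

#' Diameters of a size distribution
#' @param x a \linkS4class{SizeDistribution}
#' @export
diameters <- function(x) x@diametersNm

#' Normalized weights of a size distribution
#' @param x a \linkS4class{SizeDistribution}
#' @export
distWeights <- function(x) x@weights

#' Summary statistics of a size distribution
#' @param x a \linkS4class{SizeDistribution}
#' @return list(n, mean_nm, mode_nm, sd_nm, pdi, weighting)
#' @export
sizeSummary <- function(x) x@summary

#' Histogram bin edges of a size distribution
#' @param x a \linkS4class{SizeDistribution}
#' @export
binEdges <- function(x) x@binEdgesNm

#' Histogram bin counts of a size distribution
#' @param x a \linkS4class{SizeDistribution}
#' @export
binCounts <- function(x) x@binCounts

## ---- show methods ----

setMethod("show", "OpticalConfig", function(object) {
  cat(sprintf(
    "OpticalConfig: lambda=%g nm, delta_n=%g, pass=%g, pixel=%g nm, PSF FWHM=%g nm\n",
    object@wavelengthNm, object@deltaN, object@passFactor,
    object@pixelSizeNm, object@psfFwhmNm))
})

setMethod("show", "ParticleScene", function(object) {
  cat(sprintf("ParticleScene: %d x %d px, %d particle(s)\n",
              object@gridShape[1L], object@gridShape[2L],
              nrow(object@particles)))
  if (nrow(object@particles)) {
    d <- object@particles$diameter_nm
    cat(sprintf("  diameters [nm]: min %.0f, median %.0f, max %.0f\n",
                min(d), stats::median(d), max(d)))
  }
})

setMethod("show", "PhaseMap", function(object) {
  v <- object@values
  cat(sprintf("PhaseMap: %d x %d px, range [%.4g, %.4g] rad\n",
              nrow(v), ncol(v), min(v), max(v)))
})

setMethod("show", "InterferogramStack", function(object) {
  d <- dim(object@frames[[1L]])
  sh <- if (length(object@shiftsRad))
    paste(sprintf("%.3f", object@shiftsRad), collapse = ", ") else "unknown"
  cat(sprintf("InterferogramStack: %d frame(s) of %d x %d px, shifts [rad]: %s\n",
              length(object@frames), d[1L], d[2L], sh))
})

setMethod("show", "RetrievalResult", function(object) {
  cat(sprintf(
    "RetrievalResult: %d iteration(s), converged: %s\n  shifts [rad]: %s\n",
    object@iterations, object@converged,
    paste(sprintf("%.4f", object@shiftsRad), collapse = ", ")))
})

setMethod("show", "SizeDistribution", function(object) {
  s <- object@summary
  if (identical(s$n, 0L)) {
    cat("SizeDistribution: empty (no particles)\n")
  } else {
    cat(sprintf(
      "SizeDistribution (%s-weighted): n=%d, mean=%.1f nm, mode=%.1f nm, sd=%.1f nm, PdI=%.3f\n",
      s$weighting, s$n, s$mean_nm, s$mode_nm, s$sd_nm, s$pdi))
  }
})

setMethod("show", "RecoveryReport", function(object) {
  cat(sprintf(
    paste0("RecoveryReport: true=%d detected=%d matched=%d falsePos=%d\n",
           "  diameter bias=%.2f nm, RMSE=%.2f nm\n"),
    object@nTrue, object@nDetected, object@nMatched, object@falsePositives,
    object@diameterBiasNm, object@diameterRmseNm))
})
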