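#' @import methods
NULL

#' Optical configuration of the interferometric microscope
#'
#' Bundles the optical constants needed to convert between phase and physical
#' height: the vacuum wavelength, the refractive-index contrast
#' \eqn{\Delta n = n_2 - n_1} between particle and medium, the number of
#' passes the light makes through the specimen (1 in transmission, 2 in
#' reflection), the object-plane sampling, and the full width at half maximum
#' of the diffraction blur kernel (0 disables blurring).
#'
#' The defaults describe the imaging conditions assumed throughout the
#' package: 660 nm illumination, \eqn{\Delta n = 0.04} for lipid vesicles in
#' aqueous medium, single-pass geometry, and 86 nm object-plane pixels.
#'
#' @slot wavelengthNm vacuum wavelength in nm (> 0)
#' @slot deltaN refractive-index contrast (dimensionless, > 0)
#' @slot passFactor 1 or 2 optical passes through the sample
#' @slot pixelSizeNm object-plane sampling in nm per pixel (> 0)
#' @slot psfFwhmNm FWHM of the Gaussian diffraction blur in nm (>= 0)
#'
#' @export
setClass("OpticalConfig",
  representation(
    wavelengthNm = "numeric",
    deltaN = "numeric",
    passFactor = "numeric",
    pixelSizeNm = "numeric",
    psfFwhmNm = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  sc <- function(x) length(x) == 1L && is.finite(x)
  if (!sc(object@wavelengthNm) || object@wavelengthNm <= 0)
    msg <- c(msg, "wavelengthNm must be a single positive number")
  if (!sc(object@deltaN) || object@deltaN <= 0)
    msg <- c(msg, "deltaN must be a single positive number")
  if (!sc(object@passFactor) || !object@passFactor %in% c(1, 2))
    msg <- c(msg, "passFactor must be 1 (transmission) or 2 (reflection)")
  if (!sc(object@pixelSizeNm) || object@pixelSizeNm <= 0)
    msg <- c(msg, "pixelSizeNm must be a single positive number")
  if (!sc(object@psfFwhmNm) || object@psfFwhmNm < 0)
    msg <- c(msg, "psfFwhmNm must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Ground-truth scene of spherical particles on a pixel grid
#'
#' Holds the particle field a simulation was generated from: grid shape in
#' pixels and one row per particle with its center (0-based pixel
#' coordinates, x = column, y = row) and diameter in nm.
#'
#' @slot gridShape integer (rows, cols)
#' @slot particles data.frame with columns x_px, y_px, diameter_nm
#' @slot seed integer seed used for randomized placement (NA if none)
#'
#' @export
setClass("ParticleScene",
  representation(
    gridShape = "integer",
    particles = "data.frame",
    seed = "integer"
  )
)

setValidity("ParticleScene", function(object) {
  msg <- character()
  gs <- object@gridShape
  if (length(gs) != 2L || any(gs < 1L))
    msg <- c(msg, "gridShape must be two positive integers (rows, cols)")
  p <- object@particles
  need <- c("x_px", "y_px", "diameter_nm")
  if (!all(need %in% names(p))) {
    msg <- c(msg, sprintf("particles must have columns %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(p)) {
    if (any(p$diameter_nm <= 0))
      msg <- c(msg, "all particle diameters must be positive")
    bad <- which(p$x_px < 0 | p$x_px > gs[2L] - 1L |
                 p$y_px < 0 | p$y_px > gs[1L] - 1L)
    if (length(bad))
      msg <- c(msg, sprintf("particle(s) %s have centers outside the grid",
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Two-dimensional spatial phase map
#'
#' The retrieved or simulated phase \eqn{\phi(x, y)} in radians together with
#' the optical configuration that gives it physical meaning. The package
#' operates in the unwrapped small-phase regime \eqn{|\phi| < \pi}; maps that
#' violate it are accepted with a warning at construction.
#'
#' @slot values numeric matrix of phase in radians
#' @slot optics an \linkS4class{OpticalConfig}
#'
#' @export
setClass("PhaseMap",
  representation(values = "matrix", optics = "OpticalConfig")
)

setValidity("PhaseMap", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (!all(is.finite(v))) return("phase values must all be finite")
  TRUE
})

#' Stack of phase-shifted interferograms
#'
#' M same-shape intensity images \eqn{I_r(x,y) = A + B\cos(\phi + \delta_r)}
#' (plus optional Gaussian camera noise). The per-frame phase shifts
#' \eqn{\delta_r} may be recorded (length M) or unknown (length 0). The
#' background A and modulation B are scalars or matrices matching the frame
#' shape; they are assumed not to vary between frames.
#'
#' @slot frames list of numeric matrices, all the same shape
#' @slot shiftsRad per-frame phase shifts in radians, or numeric(0) if unknown
#' @slot backgroundA scalar or matrix background
#' @slot modulationB scalar or matrix fringe modulation
#' @slot noiseSigma additive Gaussian noise sd in counts (>= 0)
#' @slot seed integer noise seed (NA if noiseless or unknown)
#'
#' @export
setClass("InterferogramStack",
  representation(
    frames = "list",
    shiftsRad = "numeric",
    backgroundA = "ANY",
    modulationB = "ANY",
    noiseSigma = "numeric",
    seed = "integer"
  )
)

setValidity("InterferogramStack", function(object) {
  msg <- character()
  fr <- object@frames
  if (length(fr) < 1L) msg <- c(msg, "stack must hold at least one frame")
  if (!all(vapply(fr, is.matrix, logical(1))))
    msg <- c(msg, "all frames must be matrices")
  if (length(fr) > 1L) {
    d1 <- dim(fr[[1L]])
    same <- vapply(fr, function(f) identical(dim(f), d1), logical(1))
    if (!all(same)) msg <- c(msg, "all frames must share one shape")
  }
  ns <- length(object@shiftsRad)
  if (ns != 0L && ns != length(fr))
    msg <- c(msg, "shiftsRad must be absent or have one entry per frame")
  if (length(object@noiseSigma) != 1L || object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Per-pixel least-squares coefficient maps
#'
#' The reparameterisation of the fringe model used by the retrieval step:
#' \eqn{I_r = a + b\cos\delta_r + c\sin\delta_r} with
#' \eqn{a = A}, \eqn{b = B\cos\phi}, \eqn{c = -B\sin\phi}, so that
#' \eqn{\phi = \mathrm{atan2}(-c, b)} and \eqn{\sqrt{b^2 + c^2}} estimates
#' the modulation B.
#'
#' @slot a background map
#' @slot b \eqn{B\cos\phi} map
#' @slot c \eqn{-B\sin\phi} map
#'
#' @export
setClass("ABCMaps",
  representation(a = "matrix", b = "matrix", c = "matrix")
)

setValidity("ABCMaps", function(object) {
  if (!all(is.finite(object@a), is.finite(object@b), is.finite(object@c)))
    return("a, b, c maps must all be finite")
  if (!identical(dim(object@a), dim(object@b)) ||
      !identical(dim(object@a), dim(object@c)))
    return("a, b, c maps must share one shape")
  TRUE
})

#' Result of a phase-retrieval run
#'
#' @slot phase recovered \linkS4class{PhaseMap} (values in (-pi, pi])
#' @slot abc the \linkS4class{ABCMaps} of the final pixel solve
#' @slot shiftsRad the shifts used or estimated; AIA results are anchored so
#'   the first shift is 0
#' @slot iterations number of AIA alternations performed (0 for the
#'   known-shift direct solve)
#' @slot shiftHistory per-iteration max absolute shift change in radians
#' @slot converged whether the shift change fell below tolerance
#'
#' @export
setClass("RetrievalResult",
  representation(
    phase = "PhaseMap",
    abc = "ABCMaps",
    shiftsRad = "numeric",
    iterations = "integer",
    shiftHistory = "numeric",
    converged = "logical"
  )
)

#' Single-particle size distribution
#'
#' Per-particle diameters with number or intensity (d^6) weights, a histogram
#' and weighted summary statistics. The polydispersity index is the squared
#' coefficient of variation \eqn{(\sigma/\mu)^2} under the selected
#' weighting.
#'
#' @slot diametersNm per-particle diameters in nm
#' @slot weights normalized weights (sum to 1 when any particle exists)
#' @slot weighting "number" or "intensity"
#' @slot binEdgesNm histogram bin edges in nm
#' @slot binCounts unweighted per-bin particle counts
#' @slot binWeights per-bin summed normalized weights
#' @slot summary list(n, mean_nm, mode_nm, sd_nm, pdi, weighting); the
#'   numeric fields are NA (flagged by n = 0) for an empty distribution
#'
#' @export
setClass("SizeDistribution",
  representation(
    diametersNm = "numeric",
    weights = "numeric",
    weighting = "character",
    binEdgesNm = "numeric",
    binCounts = "numeric",
    binWeights = "numeric",
    summary = "list"
  )
)

setValidity("SizeDistribution", function(object) {
  msg <- character()
  n <- length(object@diametersNm)
  if (length(object@weights) != n)
    msg <- c(msg, "weights must match diameters in length")
  if (n > 0) {
    if (any(object@diametersNm <= 0))
      msg <- c(msg, "diameters must be positive")
    if (abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "weights must sum to 1")
  }
  if (!object@weighting %in% c("number", "intensity"))
    msg <- c(msg, "weighting must be 'number' or 'intensity'")
  if (length(msg)) msg else TRUE
})

#' End-to-end experiment configuration
#'
#' Everything needed for a seeded simulate-retrieve-size run: the optics, the
#' scene specification (particle count, diameter distribution, grid,
#' separation, background phase), the acquisition (frame count or explicit
#' shifts, background/modulation/noise), the retrieval settings and the
#' sizing settings. See \code{\link{ExperimentConfig}} for the fields and
#' defaults.
#'
#' @slot optics an \linkS4class{OpticalConfig}
#' @slot scene named list scene specification
#' @slot acquisition named list acquisition specification
#' @slot retrieval named list retrieval specification
#' @slot sizing named list sizing specification
#' @slot seed integer master seed
#'
#' @export
setClass("ExperimentConfig",
  representation(
    optics = "OpticalConfig",
    scene = "list",
    acquisition = "list",
    retrieval = "list",
    sizing = "list",
    seed = "integer"
  )
)

#' Ground-truth recovery report for one experiment
#'
#' @slot nTrue number of ground-truth particles
#' @slot nDetected number of detections
#' @slot nMatched detections paired to a true particle within the match radius
#' @slot falsePositives unmatched detections
#' @slot countError nDetected - nTrue
#' @slot diameterBiasNm mean (estimated - true) diameter over matches
#' @slot diameterRmseNm root-mean-square diameter error over matches
#' @slot shiftRmseRad anchored shift RMSE vs truth (NA when shifts were known)
#' @slot converged retrieval convergence flag
#' @slot matches data.frame pairing truth and detections
#'
#' @export
setClass("RecoveryReport",
  representation(
    nTrue = "integer",
    nDetected = "integer",
    nMatched = "integer",
    falsePositives = "integer",
    countError = "integer",
    diameterBiasNm = "numeric",
    diameterRmseNm = "numeric",
    shiftRmseRad = "numeric",
    converged = "logical",
    matches = "data.frame"
  )
)
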