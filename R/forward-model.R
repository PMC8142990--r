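# Forward model: ground-truth scenes, phase maps and phase-shifted
# interferogram stacks emulating QPM acquisition of immobilized spherical
# vesicles.

#' Thickness map of a field of spherical particles
#'
#' For a sphere of diameter d the optical path samples the vertical chord:
#' thickness at in-plane distance rho from the center is
#' \eqn{2\sqrt{(d/2)^2 - \rho^2}} for rho < d/2 and 0 outside, so the apex
#' thickness of an isolated particle equals its diameter. Overlapping
#' particles add (thin-specimen additivity: phase is linear in optical path).
#'
#' @param scene a \linkS4class{ParticleScene}
#' @param config an \linkS4class{OpticalConfig} (pixel size is used)
#' @return numeric matrix of thickness in nm, one value per pixel
#' @export
sphereThicknessProfile <- function(scene, config = OpticalConfig()) {
  validObject(scene)
  validObject(config)
  gs <- gridShape(scene)
  h <- matrix(0, gs[1L], gs[2L])
  p <- particles(scene)
  if (!nrow(p)) return(h)
  px <- pixelSizeNm(config)
  for (i in seq_len(nrow(p))) {
    xc <- p$x_px[i]; yc <- p$y_px[i]; d <- p$diameter_nm[i]
    if (xc < 0 || xc > gs[2L] - 1 || yc < 0 || yc > gs[1L] - 1)
      stop(sprintf("particle %d center (%.1f, %.1f) lies outside the grid", i, xc, yc))
    rPx <- (d / 2) / px
    rows <- max(1L, floor(yc + 1 - rPx)):min(gs[1L], ceiling(yc + 1 + rPx))
    cols <- max(1L, floor(xc + 1 - rPx)):min(gs[2L], ceiling(xc + 1 + rPx))
    dy <- (rows - 1 - yc) * px
    dx <- (cols - 1 - xc) * px
    rho2 <- outer(dy^2, dx^2, "+")
    chord <- 2 * sqrt(pmax((d / 2)^2 - rho2, 0))
    h[rows, cols] <- h[rows, cols] + chord
  }
  h
}

#' Convert a height map to phase
#'
#' The optical path length relation: \eqn{\phi = p \cdot (2\pi/\lambda)
#' \Delta n \, h} with p the pass factor (1 transmission, 2 reflection).
#' Exact inverse of \code{\link{phaseToHeight}} for the same configuration.
#'
#' @param height numeric matrix of heights in nm (>= 0)
#' @param config an \linkS4class{OpticalConfig}
#' @return a \linkS4class{PhaseMap}
#' @export
heightToPhase <- function(height, config = OpticalConfig()) {
  validObject(config)
  height <- as.matrix(height)
  if (any(height < 0)) stop("heights must be non-negative")
  phi <- passFactor(config) * 2 * pi * deltaN(config) * height / wavelengthNm(config)
  PhaseMap(phi, config)
}

#' Apply diffraction-limited blurring to a phase map
#'
#' Diffraction acts on the optical field, not on the phase directly: the
#' complex field exp(i phi) is convolved with a normalized Gaussian kernel of
#' the configured FWHM and the principal-value argument is returned. A zero
#' FWHM is the identity; a spatially uniform phase is a fixed point; the
#' maximum phase of an isolated particle can only decrease. This is the
#' mechanism behind the systematic size underestimation of sub-diffraction
#' particles.
#'
#' @param phase a \linkS4class{PhaseMap} whose optics carry psfFwhmNm
#' @return a blurred \linkS4class{PhaseMap} with the same optics
#' @export
applyDiffractionBlur <- function(phase) {
  cfg <- optics(phase)
  fwhm <- psfFwhmNm(cfg)
  if (fwhm == 0) return(phase)
  px <- pixelSizeNm(cfg)
  if (fwhm < px) {
    warning(sprintf(
      "PSF FWHM (%g nm) is below one pixel (%g nm); kernel still applied", fwhm, px),
      call. = FALSE)
  }
  sigmaPx <- fwhm / (2 * sqrt(2 * log(2))) / px
  v <- phaseValues(phase)
  re <- convolveGaussian(cos(v), sigmaPx)
  im <- convolveGaussian(sin(v), sigmaPx)
  PhaseMap(atan2(im, re), cfg)
}

#' Synthesize a phase-shifted interferogram stack
#'
#' Generates \eqn{I_r = A + B\cos(\phi + \delta_r) + \epsilon} with
#' \eqn{\epsilon \sim N(0, \sigma^2)} camera noise drawn under the given
#' seed. Noiseless frames are exactly reproducible; the stack records the
#' true shifts and generation parameters.
#'
#' @param phase a \linkS4class{PhaseMap}
#' @param shiftsRad per-frame phase shifts in radians (one per frame)
#' @param A scalar (or matrix) background, A >= B >= 0 for scalars
#' @param B scalar (or matrix) fringe modulation
#' @param noiseSigma additive Gaussian noise sd in counts (>= 0)
#' @param seed integer noise seed (ignored when noiseSigma is 0)
#' @return an \linkS4class{InterferogramStack}
#' @export
synthesizeInterferogramStack <- function(phase, shiftsRad, A = 200, B = 100,
                                         noiseSigma = 0, seed = 1L) {
  if (length(shiftsRad) < 1L) stop("at least one phase shift is required")
  if (noiseSigma < 0) stop("noiseSigma must be non-negative")
  if (is.numeric(A) && length(A) == 1L && is.numeric(B) && length(B) == 1L) {
    if (!(A >= B && B >= 0))
      stop("scalar background/modulation must satisfy A >= B >= 0")
  }
  v <- phaseValues(phase)
  frames <- lapply(shiftsRad, function(d) A + B * cos(v + d))
  if (noiseSigma > 0) {
    frames <- withSeed(seed, lapply(frames, function(f) {
      f + matrix(stats::rnorm(length(f), 0, noiseSigma), nrow(f), ncol(f))
    }))
  }
  InterferogramStack(frames, shiftsRad = shiftsRad, backgroundA = A,
                     modulationB = B, noiseSigma = noiseSigma,
                     seed = if (noiseSigma > 0) seed else NA_integer_)
}

# Diameter samplers for simulated scenes. spec is a named list:
#   list(type = "point",     value_nm)
#   list(type = "lognormal", meanlog, sdlog)           [log of nm]
#   list(type = "bimodal",   value1_nm, value2_nm, prob1, sdlog)
sampleDiameters <- function(n, spec) {
  type <- spec$type %||% "point"
  switch(type,
    point = rep(spec$value_nm, n),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    bimodal = {
      pick <- stats::runif(n) < (spec$prob1 %||% 0.5)
      mu <- ifelse(pick, log(spec$value1_nm), log(spec$value2_nm))
      stats::rlnorm(n, mu, spec$sdlog %||% 0.05)
    },
    stop(sprintf("unknown diameter sampler type '%s'", type))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Smooth polynomial background phase (tilt + curvature) over the grid, in
# radians; spec list(tilt_x_rad, tilt_y_rad, curvature_rad) gives the
# peak-to-peak tilt along each axis and a centered quadratic bowl amplitude.
backgroundPhaseField <- function(gridShape, spec) {
  if (is.null(spec)) return(matrix(0, gridShape[1L], gridShape[2L]))
  u <- seq(-0.5, 0.5, length.out = gridShape[2L])   # x, columns
  v <- seq(-0.5, 0.5, length.out = gridShape[1L])   # y, rows
  tx <- spec$tilt_x_rad %||% 0
  ty <- spec$tilt_y_rad %||% 0
  cv <- spec$curvature_rad %||% 0
  outer(v * ty, rep(1, length(u))) +
    outer(rep(1, length(v)), u * tx) +
    cv * outer(v^2, rep(1, length(u))) + cv * outer(rep(1, length(v)), u^2)
}

#' Simulate a complete synthetic scene
#'
#' Places particles at random integer pixel centers by rejection sampling
#' (hard cap of 10000 attempts per particle), samples their diameters,
#' composes thickness -> phase (+ optional smooth background phase),
#' applies diffraction blur when the optics request it, and synthesizes the
#' phase-shifted stack. Deterministic for a fixed seed.
#'
#' @param nParticles number of particles to place
#' @param diameter sampler spec, e.g. list(type = "point", value_nm = 200);
#'   see Details of \code{\link{ExperimentConfig}} for the supported types
#' @param gridShape integer (rows, cols)
#' @param minSeparationPx minimum center-to-center distance in pixels
#' @param seed integer seed controlling placement, diameters and noise
#' @param config an \linkS4class{OpticalConfig}
#' @param shiftsRad per-frame shifts; default 5 equally spaced over [0, 2pi)
#' @param A,B scalar background and modulation
#' @param noiseSigma camera noise sd in counts
#' @param background NULL or list(tilt_x_rad, tilt_y_rad, curvature_rad)
#'   smooth background phase added to the particle phase
#' @return list(scene, phase, stack) where phase is the (blurred) phase map
#'   the stack was generated from
#' @export
simulateScene <- function(nParticles, diameter = list(type = "point", value_nm = 200),
                          gridShape = c(128L, 128L), minSeparationPx = 20,
                          seed = 1L, config = OpticalConfig(),
                          shiftsRad = 2 * pi * (0:4) / 5, A = 200, B = 100,
                          noiseSigma = 0, background = NULL) {
  validObject(config)
  gridShape <- as.integer(gridShape)
  px <- pixelSizeNm(config)
  placed <- withSeed(seed, {
    d <- if (nParticles > 0) sampleDiameters(nParticles, diameter) else numeric(0)
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(nParticles)) {
      margin <- ceiling((d[i] / 2) / px) + 1L
      loX <- margin; hiX <- gridShape[2L] - 1L - margin
      loY <- margin; hiY <- gridShape[1L] - 1L - margin
      if (hiX < loX || hiY < loY)
        stop(sprintf("grid too small for particle %d (diameter %.0f nm)", i, d[i]))
      ok <- FALSE
      for (att in seq_len(10000L)) {
        cx <- loX + floor(stats::runif(1) * (hiX - loX + 1L))
        cy <- loY + floor(stats::runif(1) * (hiY - loY + 1L))
        if (!length(xs) ||
            all((xs - cx)^2 + (ys - cy)^2 >= minSeparationPx^2)) {
          xs <- c(xs, cx); ys <- c(ys, cy); ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf(
          "placement failed: %d of %d particles placed at separation %g px",
          i - 1L, nParticles, minSeparationPx))
    }
    data.frame(x_px = xs, y_px = ys, diameter_nm = d)
  })
  scene <- ParticleScene(gridShape, placed, seed = seed)
  h <- sphereThicknessProfile(scene, config)
  phi <- phaseValues(heightToPhase(h, config)) +
    backgroundPhaseField(gridShape, background)
  phase <- PhaseMap(phi, config)
  if (psfFwhmNm(config) > 0) phase <- applyDiffractionBlur(phase)
  stack <- synthesizeInterferogramStack(phase, shiftsRad, A = A, B = B,
                                        noiseSigma = noiseSigma,
                                        seed = seed + 1L)
  list(scene = scene, phase = phase, stack = stack)
}
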