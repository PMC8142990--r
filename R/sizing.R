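# Sizing: phase -> height conversion, particle detection on the
# background-removed phase map, diameter estimation under the spherical
# assumption, and number-/intensity-weighted size distributions.

#' Convert a phase map to a height map
#'
#' Inverts the optical path length relation:
#' \eqn{h = \phi\lambda / (p \cdot 2\pi \Delta n)} with p the pass factor.
#' Exact inverse of \code{\link{heightToPhase}} for the same configuration.
#'
#' @param phase a \linkS4class{PhaseMap} or numeric matrix/scalar of phase
#'   in radians
#' @param config an \linkS4class{OpticalConfig}; defaults to the optics of
#'   the phase map
#' @return numeric matrix (or scalar) of heights in nm
#' @export
phaseToHeight <- function(phase, config = NULL) {
  if (is(phase, "PhaseMap")) {
    if (is.null(config)) config <- optics(phase)
    phase <- phaseValues(phase)
  }
  if (is.null(config)) config <- OpticalConfig()
  validObject(config)
  if (deltaN(config) <= 0) stop("deltaN must be positive")
  phase * wavelengthNm(config) / (passFactor(config) * 2 * pi * deltaN(config))
}

#' Detect particles in a background-removed phase map
#'
#' Thresholds the map at \code{median + kSigma * robust sigma} (robust sigma
#' = 1.4826 x MAD), with an absolute floor of \code{minPhaseRad} above the
#' median representing the instrument phase sensitivity (without the floor a
#' noiseless map would be thresholded at numerical-rounding level). Pixels
#' above threshold are grouped into connected components; components smaller
#' than \code{minAreaPx} are discarded. One record per surviving component
#' carries its maximum phase, phase-weighted centroid and pixel area;
#' records are sorted by descending maximum phase with stable ids.
#'
#' An optional Gaussian pre-smoothing (\code{smoothFwhmNm} > 0) acts as a
#' matched filter against camera noise for particles at the detection limit;
#' both the threshold and the reported maximum phase then refer to the
#' smoothed map.
#'
#' @param phase a background-removed \linkS4class{PhaseMap}
#' @param kSigma threshold in robust sigmas above the median (default 3)
#' @param minAreaPx minimum component area in pixels (default 2)
#' @param connectivity 4 or 8 (default 8)
#' @param minPhaseRad absolute threshold floor above the median, in radians
#'   (default 2e-4)
#' @param smoothFwhmNm FWHM of the matched-filter pre-smoothing in nm
#'   (default 0 = none)
#' @return data.frame with columns particle_id, x_px, y_px (0-based,
#'   x = column), area_px, max_phase_rad
#' @export
detectParticles <- function(phase, kSigma = 3, minAreaPx = 2L, connectivity = 8,
                            minPhaseRad = 2e-4, smoothFwhmNm = 0) {
  if (kSigma <= 0) stop("kSigma must be positive")
  cfg <- optics(phase)
  v <- phaseValues(phase)
  if (smoothFwhmNm > 0) {
    sigmaPx <- smoothFwhmNm / (2 * sqrt(2 * log(2))) / pixelSizeNm(cfg)
    v <- convolveGaussian(v, sigmaPx)
  }
  med <- stats::median(v)
  thr <- med + max(kSigma * robustSigma(as.vector(v)), minPhaseRad)
  mask <- v > thr
  empty <- data.frame(particle_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = integer(0),
                      max_phase_rad = numeric(0))
  if (!any(mask)) return(empty)
  lab <- labelComponents(mask, connectivity)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  area <- tabulate(comp)
  keep <- which(area >= minAreaPx)
  if (!length(keep)) return(empty)
  w <- v[idx]
  rows <- ((idx - 1L) %% nrow(v))        # 0-based y
  cols <- ((idx - 1L) %/% nrow(v))       # 0-based x
  maxPhase <- vapply(keep, function(k) max(w[comp == k]), numeric(1))
  sw <- vapply(keep, function(k) sum(w[comp == k]), numeric(1))
  cx <- vapply(keep, function(k) sum(w[comp == k] * cols[comp == k]), numeric(1)) / sw
  cy <- vapply(keep, function(k) sum(w[comp == k] * rows[comp == k]), numeric(1)) / sw
  ord <- order(-maxPhase, cx, cy)
  data.frame(particle_id = seq_along(keep),
             x_px = cx[ord], y_px = cy[ord],
             area_px = as.integer(area[keep][ord]),
             max_phase_rad = maxPhase[ord])
}

#' Estimate particle diameters from maximum phase
#'
#' Under the spherical assumption the apex thickness of a particle equals
#' its diameter, so the diameter estimate is the height conversion of the
#' component's maximum phase.
#'
#' @param records detection data.frame from \code{\link{detectParticles}}
#' @param config an \linkS4class{OpticalConfig}
#' @return the records with height_nm and diameter_nm columns filled
#' @export
estimateDiameters <- function(records, config = OpticalConfig()) {
  validObject(config)
  h <- phaseToHeight(records$max_phase_rad, config)
  records$height_nm <- h
  records$diameter_nm <- h
  records
}

#' Build a single-particle size distribution
#'
#' Number weighting gives every particle weight 1/N; intensity weighting
#' mimics light-scattering detection, where the scattered intensity grows as
#' the sixth power of the diameter, so \eqn{w_i \propto d_i^6}. The
#' histogram spans [0, max diameter] at the stated bin width. The summary
#' holds the weighted mean, the modal bin center, the weighted (population)
#' standard deviation, and PdI = (sd/mean)^2.
#'
#' @param records detection data.frame with diameter_nm, or a numeric vector
#'   of diameters in nm
#' @param weighting "number" (default) or "intensity"
#' @param binWidthNm histogram bin width in nm (default 20)
#' @return a \linkS4class{SizeDistribution}; empty input yields an empty
#'   distribution whose summary is flagged by n = 0
#' @export
buildSizeDistribution <- function(records, weighting = c("number", "intensity"),
                                  binWidthNm = 20) {
  weighting <- match.arg(weighting)
  if (binWidthNm <= 0) stop("binWidthNm must be positive")
  d <- if (is.data.frame(records)) records$diameter_nm else as.numeric(records)
  n <- length(d)
  if (n == 0L) {
    return(new("SizeDistribution",
               diametersNm = numeric(0), weights = numeric(0),
               weighting = weighting, binEdgesNm = numeric(0),
               binCounts = numeric(0), binWeights = numeric(0),
               summary = list(n = 0L, mean_nm = NA_real_, mode_nm = NA_real_,
                              sd_nm = NA_real_, pdi = NA_real_,
                              weighting = weighting)))
  }
  if (any(d <= 0)) stop("diameters must be positive")
  w <- if (weighting == "number") rep(1 / n, n) else {
    raw <- (d / max(d))^6          # scaled to avoid overflow for large d
    raw / sum(raw)
  }
  edges <- seq(0, max(ceiling(max(d) / binWidthNm), 1) * binWidthNm,
               by = binWidthNm)
  bin <- pmin(findInterval(d, edges, left.open = TRUE, rightmost.closed = TRUE),
              length(edges) - 1L)
  bin[bin < 1L] <- 1L
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  bw <- vapply(seq_len(length(edges) - 1L),
               function(k) sum(w[bin == k]), numeric(1))
  mu <- sum(w * d)
  sd <- sqrt(sum(w * (d - mu)^2))
  modeBin <- which.max(bw)
  new("SizeDistribution",
      diametersNm = d, weights = w, weighting = weighting,
      binEdgesNm = edges, binCounts = as.numeric(counts), binWeights = bw,
      summary = list(n = n, mean_nm = mu,
                     mode_nm = (edges[modeBin] + edges[modeBin + 1L]) / 2,
                     sd_nm = sd, pdi = (sd / mu)^2, weighting = weighting))
}

#' Sensitivity of the diameter estimate to the assumed refractive-index
#' contrast
#'
#' The diameter inferred from a measured apex phase scales as
#' \eqn{d(\Delta n) = \phi_{max}\lambda / (p \cdot 2\pi\Delta n)}: an
#' overestimated contrast biases the size downward. Strictly decreasing in
#' \eqn{\Delta n}.
#'
#' @param maxPhaseRad measured maximum phase in radians
#' @param config an \linkS4class{OpticalConfig} (wavelength and pass factor
#'   are used; its deltaN is ignored in favor of the grid)
#' @param deltaNGrid positive contrast values to evaluate
#' @return data.frame with columns delta_n and diameter_nm
#' @export
refractiveIndexSensitivity <- function(maxPhaseRad, config = OpticalConfig(),
                                       deltaNGrid = c(0.02, 0.04, 0.08)) {
  validObject(config)
  if (any(deltaNGrid <= 0)) stop("all deltaN grid values must be positive")
  d <- maxPhaseRad * wavelengthNm(config) /
    (passFactor(config) * 2 * pi * deltaNGrid)
  data.frame(delta_n = deltaNGrid, diameter_nm = d)
}
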