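# Phase retrieval from phase-shifted interferogram stacks: per-pixel linear
# least squares when the shifts are known, and the alternating AIA iteration
# (pixel step / frame step) when they are not.

# Flatten a stack into an M x P intensity matrix (frames as rows).
stackMatrix <- function(stack) {
  t(vapply(stackFrames(stack), as.vector,
           numeric(length(stackFrames(stack)[[1L]]))))
}

#' Retrieve phase with known phase shifts
#'
#' Rewrites the fringe model as \eqn{I_r = a + b\cos\delta_r + c\sin\delta_r}
#' and solves per pixel by least squares over the frames; the phase follows
#' as \eqn{\phi = \mathrm{atan2}(-c, b)}. The 3x3 normal matrix depends only
#' on the shifts, so one factorization serves every pixel.
#'
#' @param stack an \linkS4class{InterferogramStack} with at least 3 frames
#' @param shiftsRad the known per-frame shifts; defaults to the shifts
#'   recorded in the stack
#' @param checkWrap warn when the result crowds the wrap boundary
#'   (disabled for intermediate AIA iterates)
#' @return a \linkS4class{RetrievalResult} (iterations = 0)
#' @export
retrievePhaseKnownShifts <- function(stack, shiftsRad = frameShifts(stack),
                                     checkWrap = TRUE) {
  validObject(stack)
  M <- nFrames(stack)
  if (M < 3L)
    stop("underdetermined: at least 3 frames are needed to solve (a, b, c)")
  if (length(shiftsRad) != M)
    stop("need exactly one shift per frame")
  X <- cbind(1, cos(shiftsRad), sin(shiftsRad))
  coef <- lsSolve(X, stackMatrix(stack), context = sprintf(
    "normal matrix is singular for shifts (%s): shifts congruent modulo pi",
    paste(sprintf("%.4f", shiftsRad), collapse = ", ")))
  shp <- dim(stackFrames(stack)[[1L]])
  a <- matrix(coef[1L, ], shp[1L], shp[2L])
  b <- matrix(coef[2L, ], shp[1L], shp[2L])
  cc <- matrix(coef[3L, ], shp[1L], shp[2L])
  phi <- atan2(-cc, b)
  if (checkWrap) checkWrapRisk(phi)
  new("RetrievalResult",
      phase = new("PhaseMap", values = phi, optics = OpticalConfig()),
      abc = new("ABCMaps", a = a, b = b, c = cc),
      shiftsRad = as.numeric(shiftsRad),
      iterations = 0L,
      shiftHistory = numeric(0),
      converged = TRUE)
}

#' Estimate the per-frame phase shifts given a phase map
#'
#' The frame-wise half of the AIA alternation: for each frame, least squares
#' over pixels for \eqn{I_r = a' + b'\cos\phi + c'\sin\phi} gives
#' \eqn{\delta_r = \mathrm{atan2}(-c', b')}. The returned shifts are
#' re-anchored so the first is 0 (the constant piston is unidentifiable
#' jointly with the shifts).
#'
#' @param stack an \linkS4class{InterferogramStack}
#' @param phase a \linkS4class{PhaseMap} matching the frame shape
#' @return numeric vector of anchored shifts in (-pi, pi], first element 0
#' @export
estimateShiftsGivenPhase <- function(stack, phase) {
  validObject(stack)
  v <- phaseValues(phase)
  if (!identical(dim(v), dim(stackFrames(stack)[[1L]])))
    stop("phase map shape does not match the stack frames")
  G <- cbind(1, cos(as.vector(v)), sin(as.vector(v)))
  coef <- lsSolve(G, t(stackMatrix(stack)),
                  context = "degenerate phase, shifts unidentifiable")
  delta <- atan2(-coef[3L, ], coef[2L, ])
  wrapPi(delta - delta[1L])
}

#' Phase retrieval with unknown shifts: the alternating AIA iteration
#'
#' Alternates the pixel step (\code{\link{retrievePhaseKnownShifts}} at the
#' current shift estimates) and the frame step
#' (\code{\link{estimateShiftsGivenPhase}} at the current phase estimate)
#' until the largest shift change drops below \code{tolRad} or
#' \code{maxIter} is reached. Non-convergence is reported through the
#' \code{converged} flag and the shift-change history, not as an error.
#'
#' The joint problem is invariant under a global sign flip
#' (\eqn{\phi \to -\phi}, \eqn{\delta \to -\delta}) and under a piston
#' absorbed by the anchoring \eqn{\delta_1 = 0}; results are therefore
#' defined up to these symmetries.
#'
#' With exactly 3 frames the pixel step interpolates the data exactly for
#' any non-degenerate shift triple, so the alternation acquires spurious
#' fixed points that only the frame-step residual can distinguish. For
#' M = 3 (and whenever no explicit initialization is given) the iteration is
#' therefore restarted from a small deterministic grid of initial shift
#' triples and the candidate with the smallest frame-step residual is
#' returned; for M >= 4 the equally spaced initialization alone has proven
#' reliable.
#'
#' @param stack an \linkS4class{InterferogramStack} with at least 3 frames
#' @param initShiftsRad starting shifts; default equally spaced over
#'   [0, 2pi) (plus a restart grid when M = 3)
#' @param tolRad convergence tolerance on the max shift change (default 1e-6)
#' @param maxIter maximum number of alternations (default 100)
#' @return a \linkS4class{RetrievalResult} with anchored shifts
#' @export
aiaRetrieve <- function(stack, initShiftsRad = NULL, tolRad = 1e-6,
                        maxIter = 100L) {
  validObject(stack)
  M <- nFrames(stack)
  if (M < 3L) stop("underdetermined: at least 3 frames are needed")
  if (tolRad <= 0) stop("tolRad must be positive")
  if (maxIter < 1L) stop("maxIter must be at least 1")
  inits <- if (!is.null(initShiftsRad)) {
    if (length(initShiftsRad) != M) stop("need one initial shift per frame")
    list(as.numeric(initShiftsRad))
  } else {
    base <- list(2 * pi * (seq_len(M) - 1L) / M)
    if (M == 3L) {
      grid <- c(0.9, 1.9, 2.9, 3.9, 4.9)
      for (a in grid) for (b in grid) {
        if (a != b) base[[length(base) + 1L]] <- c(0, a, b)
      }
    }
    base
  }
  rmsI <- sqrt(mean(stackMatrix(stack)^2))
  best <- NULL
  firstError <- NULL
  for (init in inits) {
    cand <- tryCatch(aiaFromInit(stack, init, tolRad, maxIter),
                     error = function(e) e)
    if (inherits(cand, "error")) {
      if (is.null(firstError)) firstError <- cand
      next
    }
    resid <- frameStepResidual(stack, retrievedPhase(cand))
    if (is.null(best) || resid < best$resid) best <- list(res = cand, resid = resid)
    if (resid < 1e-9 * rmsI) break   # exact fit found: no restart can improve
  }
  if (is.null(best)) stop(firstError)
  checkWrapRisk(phaseValues(retrievedPhase(best$res)))
  best$res
}

# One AIA run from a given initialization.
aiaFromInit <- function(stack, initShifts, tolRad, maxIter) {
  shifts <- wrapPi(initShifts - initShifts[1L])
  history <- numeric(0)
  convergedFlag <- FALSE
  for (k in seq_len(maxIter)) {
    res <- retrievePhaseKnownShifts(stack, shifts, checkWrap = FALSE)
    newShifts <- estimateShiftsGivenPhase(stack, retrievedPhase(res))
    change <- max(abs(wrapPi(newShifts - shifts)))
    history <- c(history, change)
    shifts <- newShifts
    if (change < tolRad) { convergedFlag <- TRUE; break }
  }
  final <- retrievePhaseKnownShifts(stack, shifts, checkWrap = FALSE)
  new("RetrievalResult",
      phase = retrievedPhase(final),
      abc = abcMaps(final),
      shiftsRad = shifts,
      iterations = length(history),
      shiftHistory = history,
      converged = convergedFlag)
}

# Root-mean-square residual of the frame-step fit I_r ~ 1 + cos(phi) +
# sin(phi): zero at the true joint solution, bounded away from zero at the
# spurious three-frame fixed points.
frameStepResidual <- function(stack, phase) {
  v <- as.vector(phaseValues(phase))
  G <- cbind(1, cos(v), sin(v))
  I <- t(stackMatrix(stack))
  coef <- tryCatch(lsSolve(G, I, context = "degenerate"),
                   error = function(e) NULL)
  if (is.null(coef)) return(Inf)
  sqrt(mean((I - G %*% coef)^2))
}

#' Remove background phase
#'
#' Implements the background-removal step of the sizing pipeline: either
#' subtract a reference (sample-free) phase map, fit and subtract a smooth
#' 2-D polynomial surface, or subtract the scalar median. The polynomial fit
#' is made robust to the particles themselves by one re-fit that excludes
#' pixels more than 3 robust sigma above the first fit.
#'
#' @param phase a \linkS4class{PhaseMap}
#' @param method "polynomial" (default), "reference" or "median"
#' @param order total polynomial degree for method = "polynomial"
#'   (default 2: slow illumination curvature without eating particle signal)
#' @param reference a \linkS4class{PhaseMap} or matrix, required for
#'   method = "reference"
#' @return a background-subtracted \linkS4class{PhaseMap}
#' @export
removeBackground <- function(phase, method = c("polynomial", "reference", "median"),
                             order = 2L, reference = NULL) {
  method <- match.arg(method)
  v <- phaseValues(phase)
  out <- switch(method,
    reference = {
      if (is.null(reference)) stop("method = 'reference' requires a reference map")
      ref <- if (is(reference, "PhaseMap")) phaseValues(reference) else as.matrix(reference)
      if (!identical(dim(ref), dim(v)))
        stop("reference shape does not match the phase map")
      v - ref
    },
    median = v - stats::median(v),
    polynomial = {
      if (order < 0) stop("polynomial order must be non-negative")
      v - fitPolynomialSurface(v, order)
    })
  new("PhaseMap", values = out, optics = optics(phase))
}

# Least-squares 2-D polynomial surface of given total degree, with one
# robust re-fit excluding pixels > 3 robust sigma ABOVE the first fit
# (particles are positive bumps). Returns the fitted surface.
fitPolynomialSurface <- function(v, order) {
  nr <- nrow(v); nc <- ncol(v)
  x <- rep(seq(-1, 1, length.out = nc), each = nr)
  y <- rep(seq(-1, 1, length.out = nr), times = nc)
  terms <- list()
  for (i in 0:order) for (j in 0:(order - i)) terms[[length(terms) + 1L]] <- x^i * y^j
  X <- do.call(cbind, terms)
  z <- as.vector(v)
  beta <- lsSolve(X, z, context = "polynomial design is singular")
  resid <- z - as.vector(X %*% beta)
  s <- robustSigma(resid)
  if (s > 0) {
    keep <- resid <= 3 * s
    if (sum(keep) >= ncol(X)) {
      beta <- lsSolve(X[keep, , drop = FALSE], z[keep],
                      context = "polynomial design is singular after masking")
    }
  }
  matrix(as.vector(X %*% beta), nr, nc)
}
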