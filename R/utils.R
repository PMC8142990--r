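# Internal numerical helpers shared across modules.

# Wrap angles to the principal interval (-pi, pi].
wrapPi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Robust sigma = 1.4826 * median absolute deviation (stats::mad default
# constant), the package-wide scale estimate.
robustSigma <- function(x) stats::mad(x)

# Normalized 2-D Gaussian kernel with the given sigma in pixels; odd support
# covering +/- 4 sigma (clipped to maxHalf when the image is small).
gaussianKernel <- function(sigmaPx, maxHalf = Inf) {
  half <- max(1L, as.integer(ceiling(4 * sigmaPx)))
  half <- min(half, maxHalf)
  ax <- seq(-half, half)
  g <- exp(-ax^2 / (2 * sigmaPx^2))
  k <- outer(g, g)
  k / sum(k)
}

# FFT-based convolution of a matrix with a normalized Gaussian kernel.
# Replicate boundary: smooth fields with tilt do not wrap across edges, and
# constant inputs remain exact fixed points up to floating rounding.
convolveGaussian <- function(x, sigmaPx) {
  maxHalf <- as.integer(floor((min(dim(x)) - 1L) / 2L))
  EBImage::filter2(x, gaussianKernel(sigmaPx, maxHalf), boundary = "replicate")
}

# Label connected components of a logical mask at 4- or 8-connectivity.
# Returns an integer matrix, 0 = background, components numbered from 1.
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  out <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  k <- length(idx)
  if (k == 0L) return(out)
  vid <- matrix(0L, nrow(mask), ncol(mask))
  vid[idx] <- seq_len(k)
  nr <- nrow(mask); nc <- ncol(mask)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    r1 <- seq_len(nr - dr); c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1L - dc, nc)
    r2 <- r1 + dr; c2 <- c1 + dc
    both <- mask[r1, c1, drop = FALSE] & mask[r2, c2, drop = FALSE]
    w <- which(both)
    if (length(w)) {
      a <- vid[r1, c1, drop = FALSE][w]
      b <- vid[r2, c2, drop = FALSE][w]
      edges <- c(edges, rbind(a, b))
    }
  }
  g <- igraph::make_graph(edges, n = k, directed = FALSE)
  memb <- igraph::components(g)$membership
  out[idx] <- as.integer(memb)
  out
}

# Evaluate with a private RNG state: deterministic in `seed`, leaves the
# caller's RNG untouched.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Least-squares solve of t(X) X beta = t(X) Y with a singularity check.
# Y may have many columns (one per pixel or frame).
lsSolve <- function(X, Y, context) {
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    stop(context, call. = FALSE)
  }
  solve(XtX, crossprod(X, Y))
}

# Warn if a phase map sits against the wrap boundary: more than 0.1% of
# pixels within 0.1 rad of +/- pi.
checkWrapRisk <- function(values) {
  frac <- mean(abs(abs(values) - pi) < 0.1)
  if (frac > 0.001) {
    warning(sprintf(
      "%.2f%% of pixels lie within 0.1 rad of +/-pi; phase may be wrapped",
      100 * frac), call. = FALSE)
  }
  invisible(frac)
}
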