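# Shared fixtures: smooth random phase fields, non-degenerate random shift
# sets, and sign/piston alignment for comparing AIA output with truth.

# Smooth random phase: low-order random cosine surface, scaled to the given
# peak magnitude (kept well inside (-pi, pi) so comparisons never wrap).
# Deterministic in `seed`.
smoothRandomPhase <- function(shape = c(64L, 64L), peakRad = 2, seed = 1L) {
  withr::with_seed(seed, {
    u <- seq(0, 1, length.out = shape[2L])
    v <- seq(0, 1, length.out = shape[1L])
    z <- matrix(0, shape[1L], shape[2L])
    for (k in 1:4) {
      fu <- runif(1, 0.5, 2.5); fv <- runif(1, 0.5, 2.5)
      pu <- runif(1, 0, 2 * pi); pv <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0.3, 1)
      z <- z + amp * outer(cos(2 * pi * fv * v + pv), cos(2 * pi * fu * u + pu))
    }
    z <- z - mean(z)
    z * (peakRad / max(abs(z)))
  })
}

# Random shifts with pairwise wrapped separation >= minSep and a
# non-singular {1, cos, sin} design. First shift is 0.
randomShifts <- function(M, seed = 1L, minSep = 0.4) {
  withr::with_seed(seed, {
    repeat {
      s <- c(0, sort(runif(M - 1L, 0.2, 2 * pi - 0.2)))
      d <- outer(s, s, "-")
      sep <- abs(atan2(sin(d), cos(d)))[upper.tri(d)]
      X <- cbind(1, cos(s), sin(s))
      if (min(sep) >= minSep && rcond(crossprod(X)) > 1e-6) break
    }
    s
  })
}

# Align an estimated (phase, shifts) pair with truth up to the global sign
# flip and the phase piston; returns the aligned errors.
alignRetrieval <- function(phiEst, shiftEst, phiTrue, shiftTrue) {
  wrap <- function(x) atan2(sin(x), cos(x))
  best <- NULL
  for (s in c(1, -1)) {
    phi <- s * phiEst
    piston <- mean(phiTrue - phi)
    phiErr <- phiTrue - phi - piston
    shErr <- wrap(shiftTrue - wrap(s * shiftEst))
    rmse <- sqrt(mean(phiErr^2))
    if (is.null(best) || rmse < best$phaseRmse) {
      best <- list(phaseRmse = rmse,
                   shiftRmse = sqrt(mean(shErr^2)),
                   sign = s)
    }
  }
  best
}

# Small standard optics used across tests.
testOptics <- function(...) OpticalConfig(...)
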