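# Internal numeric helpers shared by the simulator and the segmenter.

#' Centered moving-average smoothing
#'
#' Smooths a series with a centered moving average whose width is given in
#' seconds and converted to an odd number of samples at the series' rate.
#' Edges are handled by shrinking the window (partial means), so the output
#' has the same length and no phase lag.
#'
#' @param x numeric vector.
#' @param window window width in seconds.
#' @param rate sampling rate in Hz.
#' @return smoothed numeric vector, same length as `x`.
#' @keywords internal
smooth_ma <- function(x, window, rate) {
  n <- length(x)
  half <- max(0L, as.integer(floor(window * rate / 2)))
  if (half == 0L || n < 3L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Raised-cosine ramp: 0 at s = 0, 1 at s >= ramp (s clamped below 0).
rc_ramp <- function(s, ramp) {
  u <- pmin(pmax(s / ramp, 0), 1)
  0.5 * (1 - cos(pi * u))
}

# Pulse supported on [a, b]: raised-cosine ramps of length `ramp` at both
# edges, plateau at (1 - bump) of the peak, and a central raised-cosine bump
# so the maximum `peak` is attained only near the pulse centre (keeps the
# sample maximum close to the nominal peak even with additive noise, while
# the steep edges keep threshold crossings close to the true boundaries).
tukey_pulse <- function(t, a, b, peak, ramp = 0.4, bump = 0.15) {
  dur <- b - a
  if (dur <= 0) return(numeric(length(t)))
  ramp <- min(ramp, dur / 3)
  inside <- t >= a & t <= b
  out <- numeric(length(t))
  ti <- t[inside]
  edge <- rc_ramp(ti - a, ramp) * rc_ramp(b - ti, ramp)
  hann <- 0.5 * (1 - cos(2 * pi * (ti - a) / dur))
  out[inside] <- peak * edge * ((1 - bump) + bump * hann)
  out
}

# Smoothstep between 0 and 1 over [a, b] (clamped outside).
smoothstep <- function(t, a, b) {
  u <- pmin(pmax((t - a) / (b - a), 0), 1)
  u * u * (3 - 2 * u)
}

#' Local peak detection with prominence and spacing constraints
#'
#' Finds local maxima of `x`, keeps those whose topographic prominence is at
#' least `min_prominence`, then enforces a minimum index spacing by greedily
#' keeping higher peaks first (ties broken by earlier index).
#'
#' @param x numeric vector.
#' @param min_prominence minimum prominence (same units as `x`).
#' @param min_distance minimum spacing between kept peaks, in samples.
#' @return integer vector of peak indices, increasing.
#' @keywords internal
find_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    left <- if (j >= 1L) lmin else min(x[1:i])
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    right <- if (j <= n) rmin else min(x[i:n])
    h - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep) || min_distance <= 1L) return(sort(keep))
  ord <- keep[order(-x[keep], keep)]
  chosen <- integer(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(chosen - i) >= min_distance)) {
      chosen <- c(chosen, i)
    }
  }
  sort(chosen)
}

# Draw from a normal distribution truncated to [lo, hi] by resampling
# (vectorized rejection; falls back to clamping after 100 rounds).
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  for (k in seq_len(100)) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

# Internal: stop with a classed error so callers/tests can be specific.
tug_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tugfall_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
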