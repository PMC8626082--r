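# Binless multi-scale-derivative instantaneous firing rate (IFR) and
# peak/onset/trough latency estimation.

#' Logarithmic grid of derivative timescales
#'
#' Timescales are `base^p` for every integer exponent `p` strictly inside
#' `(log_base(1e-3), log_base(tau/10))`, i.e. all scales strictly between
#' 1 ms and a tenth of the analysis window. Bases closer to 1 give a denser
#' grid (more accurate, slower).
#'
#' @param tau analysis-window length (seconds).
#' @param base logarithm base of the grid (default 1.5).
#' @return an object of class `"timescale_grid"` with fields `base`,
#'   `exponents`, `timescales` (seconds, increasing) and `S`.
#' @export
build_timescales <- function(tau, base = 1.5) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (base <= 1) stop("base must be > 1")
  lo <- log(1e-3, base)
  hi <- log(tau / 10, base)
  p <- seq.int(floor(lo) - 1L, ceiling(hi) + 1L)
  p <- p[p > lo & p < hi]                 # strict: exact endpoints excluded
  if (!length(p)) stop("window too short for multi-scale grid")
  structure(list(base = base, exponents = p, timescales = base^p,
                 S = length(p)),
            class = "timescale_grid")
}

# Block boundaries of tied values in a sorted vector: for each element, the
# index of the last element strictly smaller (0 if none) and the first
# element strictly larger (n + 1 if none).
distinct_neighbors <- function(v) {
  n <- length(v)
  first_new <- which(!duplicated(v))       # start index of each value block
  blk <- findInterval(seq_len(n), first_new)
  list(prev = first_new[blk] - 1L,
       next_ = c(first_new[-1L], n + 1L)[blk])
}

#' Multi-scale derivative of the deviation curve
#'
#' For every spike and every timescale, the local slope of the deviation
#' curve `d` is taken between the nearest spikes strictly outside a window
#' of that timescale centered on the spike; slopes are averaged over scales.
#' When the window extends past `[0, tau]` the corresponding endpoint snaps
#' to the first/last sample. Coincident spikes that would give a zero-length
#' span are widened to the nearest distinct neighbors; if none exist that
#' scale contributes 0. The result is bounded below by `-1/tau`.
#'
#' @param curve a `"deviation_curve"` from [deviation_curve()].
#' @param grid a `"timescale_grid"`; default [build_timescales()] at the
#'   curve's `tau`.
#' @return numeric vector `m` of length `n` (one value per pooled spike).
#' @export
multiscale_derivative <- function(curve, grid = NULL) {
  n <- curve$n
  if (n < 3L) stop("need at least 3 pooled spike times")
  if (is.null(grid)) grid <- build_timescales(curve$tau)
  v <- curve$v
  d <- curve$d
  tau <- curve$tau
  nb <- distinct_neighbors(v)
  acc <- numeric(n)
  for (tk in grid$timescales) {
    lo <- v - tk / 2
    hi <- v + tk / 2
    a <- findInterval(lo, v, left.open = TRUE)   # last index with v < lo
    a[lo < 0 | a == 0L] <- 1L                    # edge rule
    b <- findInterval(hi, v) + 1L                # first index with v > hi
    b[hi > tau | b > n] <- n
    # coincident endpoints: widen to nearest distinct values
    co <- v[b] <= v[a]
    if (any(co)) {
      a2 <- nb$prev[a]
      b2 <- nb$next_[b]
      ok <- co & a2 >= 1L & b2 <= n
      a[ok] <- a2[ok]
      b[ok] <- b2[ok]
      dead <- co & !ok                           # no distinct span available
    } else {
      dead <- FALSE
    }
    slope <- (d[b] - d[a]) / (v[b] - v[a])
    if (any(co)) slope[dead] <- 0
    acc <- acc + slope
  }
  acc / grid$S
}

#' Instantaneous firing rate from the multi-scale derivative
#'
#' Rescales the multi-scale derivative `m` into a firing rate in Hz whose
#' ISI-weighted time average equals the mean rate `n/(tau*q)`:
#' `r = n/(tau*q) * (m + 1/tau) / (mbar + 1/tau)`, with `mbar` the
#' trapezoid time-average of `m` over the inter-spike intervals.
#'
#' @param msd multi-scale derivative vector from [multiscale_derivative()].
#' @param curve the `"deviation_curve"` the derivative was computed from.
#' @param q number of events pooled; default taken from `curve`.
#' @return an object of class `"zeta_rate"` with fields `times` (the pooled
#'   relative spike times), `msd`, `msd_mean`, `rate` (Hz), `n`, `q`, `tau`.
#' @export
instantaneous_rate <- function(msd, curve, q = curve$q) {
  v <- curve$v
  n <- curve$n
  tau <- curve$tau
  if (length(msd) != n) stop("msd and curve lengths differ")
  mbar <- sum((msd[-n] + msd[-1L]) / 2 * diff(v)) / tau
  if (mbar + 1 / tau <= 0) stop("degenerate rate normalization")
  rate <- n / (tau * q) * (msd + 1 / tau) / (mbar + 1 / tau)
  structure(list(times = v, msd = msd, msd_mean = mbar, rate = rate,
                 n = n, q = q, tau = tau),
            class = "zeta_rate")
}

#' @export
print.zeta_rate <- function(x, ...) {
  cat(sprintf(
    "Instantaneous firing rate: %d samples on [0, %.4g] s, mean %.3g Hz, peak %.3g Hz\n",
    x$n, x$tau, x$n / (x$tau * x$q), max(x$rate)))
  invisible(x)
}

#' Binless instantaneous firing rate of a neuron around events
#'
#' Convenience pipeline: pool relative spikes, build the deviation curve and
#' timescale grid, take the multi-scale derivative and rescale it into Hz.
#'
#' @inheritParams pool_relative_spikes
#' @param base logarithm base for the timescale grid (default 1.5).
#' @return a `"zeta_rate"` object.
#' @export
ifr <- function(spikes, events, tau = NULL, base = 1.5) {
  tau <- resolve_tau(events, tau)
  rel <- pool_relative_spikes(spikes, events, tau)
  curve <- deviation_curve(rel)
  grid <- build_timescales(tau, base)
  msd <- multiscale_derivative(curve, grid)
  instantaneous_rate(msd, curve)
}

#' Response latencies from an instantaneous firing rate
#'
#' Peak latency is the time of the global rate maximum (earliest on ties),
#' trough latency the time of the global minimum. Onset latency is the time
#' the rising flank of the peak first crosses half-maximum, found by
#' searching backward from the peak for the last sub-half-max sample and
#' linearly interpolating the crossing; the half-max reference is
#' `min + (max - min)/2` so a nonzero baseline does not bias the onset.
#'
#' @param rate a `"zeta_rate"` from [instantaneous_rate()] or [ifr()].
#' @return an object of class `"latency_estimate"`: `peak_time`,
#'   `peak_rate`, `onset_time`, `trough_time`, `trough_rate`, and flags
#'   `constant_rate` / `onset_at_start`.
#' @export
latency_estimates <- function(rate) {
  r <- rate$rate
  v <- rate$times
  rmax <- max(r)
  rmin <- min(r)
  if (rmax == rmin) {
    return(structure(list(peak_time = NA_real_, peak_rate = rmax,
                          onset_time = NA_real_, trough_time = NA_real_,
                          trough_rate = rmin, constant_rate = TRUE,
                          onset_at_start = FALSE),
                     class = "latency_estimate"))
  }
  i_peak <- which.max(r)
  i_trough <- which.min(r)
  half <- rmin + (rmax - rmin) / 2
  below <- which(r[seq_len(i_peak)] < half)
  onset_at_start <- FALSE
  if (length(below)) {
    j <- max(below)                       # last sub-half-max sample pre-peak
    onset_time <- v[j] +
      (half - r[j]) * (v[j + 1L] - v[j]) / (r[j + 1L] - r[j])
  } else {
    onset_time <- v[1L]
    onset_at_start <- TRUE
  }
  structure(list(peak_time = v[i_peak], peak_rate = rmax,
                 onset_time = onset_time, trough_time = v[i_trough],
                 trough_rate = rmin, constant_rate = FALSE,
                 onset_at_start = onset_at_start),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  if (x$constant_rate) {
    cat("Latency estimate: rate is constant; latencies undefined\n")
    return(invisible(x))
  }
  cat(sprintf("Latencies: onset %.4g s, peak %.4g s (%.3g Hz), trough %.4g s (%.3g Hz)%s\n",
              x$onset_time, x$peak_time, x$peak_rate, x$trough_time,
              x$trough_rate,
              if (x$onset_at_start) " [onset clipped to window start]" else ""))
  invisible(x)
}
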