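# Core of the ZETA-test: event-aligned deviation curve, resampled null
# distributions, Gumbel significance, and the composed test.

# Relative spike times pooled over the per-event windows (w_k, w_k + tau],
# raster-style: every window collects its own spikes, so overlapping windows
# (possible after onset jittering) each count a spike and gaps wider than
# tau drop the remainder. For non-overlapping events this coincides with
# assignment to the most recent onset. Returns the unsorted pooled vector.
window_relative_times <- function(x, w, tau) {
  lo <- findInterval(w, x)          # spikes at exactly w_k are excluded
  hi <- findInterval(w + tau, x)    # relative time exactly tau is included
  cnt <- hi - lo
  x[sequence(cnt, from = lo + 1L)] - rep.int(w, cnt)
}

#' Pool spike times relative to event onsets
#'
#' Builds the vector `v` of event-aligned spike times, as in a raster plot:
#' each event contributes the spikes in its window `(onset, onset + tau]`,
#' expressed relative to that onset. Two sentinel spikes at 0 and `tau` are
#' appended so the analysis window is always covered; `n` counts the
#' sentinels. Windows reaching past the last spike are used as-is, and
#' overlapping windows (possible for jittered onsets) each count their
#' spikes.
#'
#' @param spikes a [spike_train()] or numeric vector of spike times.
#' @param events an [event_series()] with at least 2 events.
#' @param tau analysis-window length in seconds; default is the median
#'   onset-to-onset interval of `events`.
#' @return an object of class `"relative_spikes"` with fields `v` (sorted,
#'   sentinels included), `n`, `tau`, `q` and `empty` (TRUE when no real
#'   spike fell in any window).
#' @export
pool_relative_spikes <- function(spikes, events, tau = NULL) {
  x <- if (inherits(spikes, "spike_train")) spikes$times else
    sort(as.numeric(spikes))
  w <- events$onsets
  if (length(w) < 2L) stop("need at least 2 events")
  tau <- resolve_tau(events, tau)
  v <- window_relative_times(x, w, tau)
  empty <- length(v) == 0L
  v <- c(0, sort(v), tau)
  structure(list(v = v, n = length(v), tau = tau, q = length(w),
                 empty = empty),
            class = "relative_spikes")
}

#' Deviation curve of the event-aligned spike distribution
#'
#' Computes the fractional spike positions `g_i = i/n` (the empirical CDF of
#' pooled relative spike times sampled at the spikes), the linear baseline
#' `b_i = v_i/tau` expected for an unmodulated neuron, their difference
#' `delta`, and the mean-centered, time-invariant deviation `d`.
#'
#' @param rel a `"relative_spikes"` object from [pool_relative_spikes()].
#' @return an object of class `"deviation_curve"` with fields `v`, `g`, `b`,
#'   `delta`, `delta_bar`, `d`, `n`, `tau`, `q`.
#' @export
deviation_curve <- function(rel) {
  n <- rel$n
  if (n < 2L) stop("need at least 2 pooled spike times (incl. sentinels)")
  g <- seq_len(n) / n
  b <- rel$v / rel$tau
  delta <- g - b
  delta_bar <- mean(delta)
  structure(list(v = rel$v, g = g, b = b, delta = delta,
                 delta_bar = delta_bar, d = delta - delta_bar,
                 n = n, tau = rel$tau, q = rel$q,
                 empty = isTRUE(rel$empty)),
            class = "deviation_curve")
}

#' Raw ZETA statistic of a deviation curve
#'
#' `zeta_raw` is the maximum absolute mean-centered deviation `max(|d|)`.
#' Ties in the argmax are broken by the earliest spike time. The "inverse"
#' time is the spike time of the most extreme deviation of opposite sign
#' (used to annotate rasters with both the peak and the anti-peak).
#'
#' @param curve a `"deviation_curve"`.
#' @return a list with `zeta_raw`, `zeta_time`, `zeta_sign`,
#'   `inverse_zeta_time`.
#' @export
zeta_statistic <- function(curve) {
  d <- curve$d
  i_max <- which.max(abs(d))            # first = earliest time on ties
  zeta_raw <- abs(d[i_max])
  zeta_sign <- sign(d[i_max])
  if (zeta_raw == 0) {
    return(list(zeta_raw = 0, zeta_time = curve$v[i_max], zeta_sign = 0,
                inverse_zeta_time = curve$v[i_max]))
  }
  i_inv <- if (zeta_sign > 0) which.min(d) else which.max(d)
  list(zeta_raw = zeta_raw, zeta_time = curve$v[i_max],
       zeta_sign = zeta_sign, inverse_zeta_time = curve$v[i_inv])
}

# Interpolate a resampled cumulative-fraction curve onto the original spike
# times. v2 is the resampled pooled vector (with sentinels); values outside
# its support clamp to the boundary fractions.
interp_fraction <- function(v2, v) {
  f <- seq_along(v2) / length(v2)
  stats::approx(v2, f, xout = v, method = "linear", rule = 2,
                ties = max)$y
}

# Shuffle inter-spike intervals of an absolute spike-time vector: permute the
# ISIs and rebuild from the original first spike (conserves spike count and
# total duration).
shuffle_isi <- function(x) {
  if (length(x) < 3L) stop("need at least 3 spikes to shuffle ISIs")
  dt <- diff(x)
  c(x[1L], x[1L] + cumsum(sample(dt)))
}

# One null ZETA sample against a (possibly surrogate) spike/event pair,
# interpolated onto original v and compared to the original baseline b.
null_zeta_once <- function(x2, w2, tau, v, b) {
  v2 <- window_relative_times(x2, w2, tau)
  if (length(v2) < 2L) return(NA_real_)    # degenerate resample
  v2 <- c(0, sort(v2), tau)
  g2 <- interp_fraction(v2, v)
  d2 <- g2 - b
  d2 <- d2 - mean(d2)
  max(abs(d2))
}

null_distribution <- function(spikes, events, tau, resamples, mode, seed) {
  x <- if (inherits(spikes, "spike_train")) spikes$times else
    sort(as.numeric(spikes))
  w <- events$onsets
  tau <- resolve_tau(events, tau)
  if (resamples < 2L) stop("need at least 2 resamples")
  if (mode == "isi" && length(x) < 3L) {
    stop("need at least 3 spikes for ISI shuffling")
  }
  rel <- pool_relative_spikes(x, events, tau)
  curve <- deviation_curve(rel)
  if (!is.null(seed)) set.seed(seed)
  q <- length(w)
  samples <- numeric(resamples)
  for (j in seq_len(resamples)) {
    if (mode == "jitter") {
      w2 <- w + stats::runif(q, -tau, tau)
      x2 <- x
    } else {
      w2 <- w
      x2 <- shuffle_isi(x)
    }
    samples[j] <- null_zeta_once(x2, w2, tau, curve$v, curve$b)
  }
  degenerate <- is.na(samples)
  samples[degenerate] <- 0
  structure(list(zeta_samples = samples, P = resamples, mode = mode,
                 rng_seed = seed, n_degenerate = sum(degenerate)),
            class = "zeta_null")
}

#' Jitter-resampled null distribution for ZETA
#'
#' For each resample, every event time is displaced independently by a
#' uniform offset on `[-tau, tau]`, the pooled cumulative fraction curve is
#' recomputed, linearly interpolated back onto the original spike times, and
#' the maximum absolute mean-centered deviation recorded. Resamples that
#' capture no spikes contribute 0 and are counted in `n_degenerate`.
#'
#' @inheritParams pool_relative_spikes
#' @param resamples number of resamples `P` (default 100).
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `"zeta_null"` with fields `zeta_samples`, `P`,
#'   `mode`, `rng_seed`, `n_degenerate`.
#' @export
jitter_null <- function(spikes, events, tau = NULL, resamples = 100,
                        seed = NULL) {
  null_distribution(spikes, events, tau, resamples, "jitter", seed)
}

#' ISI-shuffle null distribution for ZETA
#'
#' Per resample, the inter-spike intervals of the full train are randomly
#' permuted and the surrogate train rebuilt from the original first spike;
#' the null ZETA sample is then computed against the original events exactly
#' as in [jitter_null()]. The surrogate conserves spike count and total
#' duration.
#'
#' @inheritParams jitter_null
#' @return an object of class `"zeta_null"`.
#' @export
isi_shuffle_null <- function(spikes, events, tau = NULL, resamples = 100,
                             seed = NULL) {
  null_distribution(spikes, events, tau, resamples, "isi", seed)
}

#' Gumbel significance of a ZETA value
#'
#' Fits a Gumbel extreme-value distribution to the null samples by moment
#' matching (`beta = sqrt(6 Var)/pi`, `m = mean - beta*gamma`, with gamma the
#' Euler-Mascheroni constant) and reads out the upper-tail p-value at the
#' observed statistic. The corrected ZETA is the two-tailed standard-normal
#' equivalent `qnorm(1 - p/2)`.
#'
#' @param null a `"zeta_null"` or a numeric vector of null samples.
#' @param zeta_raw observed maximum absolute deviation.
#' @return a list with `p`, `zeta_corrected`, `fit` (mode `mode_m`, scale
#'   `beta`, `gamma_const`) and `saturated` (TRUE when p underflowed and was
#'   clamped to the smallest positive double).
#' @export
gumbel_significance <- function(null, zeta_raw) {
  samples <- if (inherits(null, "zeta_null")) null$zeta_samples else
    as.numeric(null)
  if (length(samples) < 2L) stop("need at least 2 null samples")
  v <- stats::var(samples)
  if (v <= 0) stop("degenerate null: zero variance of null samples")
  gamma_const <- -digamma(1)            # Euler-Mascheroni, ~0.5772157
  beta <- sqrt(6 * v) / pi
  mode_m <- mean(samples) - beta * gamma_const
  z <- (zeta_raw - mode_m) / beta
  # p = 1 - exp(-exp(-z)); -expm1 keeps precision in the small-p tail
  p <- -expm1(-exp(-z))
  saturated <- FALSE
  if (p <= 0) {
    p <- .Machine$double.xmin
    saturated <- TRUE
  }
  zeta_corrected <- stats::qnorm(p / 2, lower.tail = FALSE)
  list(p = p, zeta_corrected = zeta_corrected,
       fit = list(mode_m = mode_m, beta = beta, gamma_const = gamma_const),
       saturated = saturated)
}

#' The ZETA-test for time-locked neuronal responsiveness
#'
#' Tests whether a neuron's spiking is statistically modulated relative to a
#' series of events, without binning and without assumptions on the response
#' shape. The observed statistic is the maximum absolute mean-centered
#' deviation between the event-aligned cumulative spike distribution and a
#' linear baseline; significance comes from a resampled null (onset jitter by
#' default, or ISI shuffling) through a Gumbel extreme-value fit.
#'
#' @inheritParams jitter_null
#' @param null_mode `"jitter"` (displace event onsets; default) or `"isi"`
#'   (shuffle inter-spike intervals).
#' @return an object of class `"zeta_result"`: fields `zeta_raw`,
#'   `zeta_time`, `zeta_sign`, `inverse_zeta_time`, `p`, `zeta_corrected`,
#'   `p_empirical` (percentile of the observed statistic among the null
#'   samples), `null` (the `"zeta_null"`), `curve` (the
#'   `"deviation_curve"`), `fit`, and flags `no_spikes`/`saturated`.
#' @examples
#' set.seed(1)
#' ev <- event_series(seq(0, 38, by = 2))
#' sp <- spike_train(sort(c(runif(200, 0, 40), rep(ev$onsets, 2) + 0.1)))
#' zeta_test(sp, ev, resamples = 50, seed = 1)
#' @export
zeta_test <- function(spikes, events, tau = NULL, resamples = 100,
                      null_mode = c("jitter", "isi"), seed = NULL) {
  null_mode <- match.arg(null_mode)
  tau <- resolve_tau(events, tau)
  rel <- pool_relative_spikes(spikes, events, tau)
  curve <- deviation_curve(rel)
  if (rel$empty) {
    res <- list(zeta_raw = 0, zeta_time = NA_real_, zeta_sign = 0,
                inverse_zeta_time = NA_real_, p = 1, zeta_corrected = 0,
                p_empirical = 1, null = NULL, curve = curve, fit = NULL,
                tau = tau, null_mode = null_mode,
                no_spikes = TRUE, saturated = FALSE)
    return(structure(res, class = "zeta_result"))
  }
  stat <- zeta_statistic(curve)
  nd <- null_distribution(spikes, events, tau, resamples, null_mode, seed)
  sig <- gumbel_significance(nd, stat$zeta_raw)
  p_emp <- (1 + sum(nd$zeta_samples >= stat$zeta_raw)) / (1 + nd$P)
  res <- c(stat,
           list(p = sig$p, zeta_corrected = sig$zeta_corrected,
                p_empirical = p_emp, null = nd, curve = curve,
                fit = sig$fit, tau = tau, null_mode = null_mode,
                no_spikes = FALSE, saturated = sig$saturated))
  structure(res, class = "zeta_result")
}

#' @export
print.zeta_result <- function(x, ...) {
  cat("ZETA-test (null:", x$null_mode, ")\n")
  if (x$no_spikes) {
    cat("  no spikes in any event window: p = 1\n")
    return(invisible(x))
  }
  cat(sprintf("  zeta (corrected) = %.3f, p = %.4g%s\n",
              x$zeta_corrected, x$p,
              if (x$saturated) " (saturated)" else ""))
  cat(sprintf("  max |deviation| = %.4f at t = %.4f s (sign %+d)\n",
              x$zeta_raw, x$zeta_time, as.integer(x$zeta_sign)))
  cat(sprintf("  opposite extreme at t = %.4f s; window tau = %.4g s, %d resamples\n",
              x$inverse_zeta_time, x$tau, x$null$P))
  invisible(x)
}

#' @export
as.data.frame.zeta_result <- function(x, ..., neuron_id = NA_character_) {
  data.frame(neuron_id = neuron_id, test = paste0("zeta-", x$null_mode),
             p = x$p, statistic = x$zeta_corrected, zeta_raw = x$zeta_raw,
             zeta_time = x$zeta_time, inverse_zeta_time = x$inverse_zeta_time,
             stringsAsFactors = FALSE)
}
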