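# Comparison tests the ZETA-test is benchmarked against: paired mean-rate
# t-test, optimal-bin PSTH ANOVA, multi-timescale ANOVA, and the
# renewal-process surrogate tests.

# Per-trial spike counts in [onset + from, onset + to) for every event.
epoch_counts <- function(x, onsets, from, to) {
  x <- sort(x)
  findInterval(onsets + to, x, left.open = TRUE) -
    findInterval(onsets + from, x, left.open = TRUE)
}

#' Per-trial per-bin spike-count matrix (PSTH counts)
#'
#' Bins the relative spike times of each trial into uniform bins of width
#' `bin_width` covering `[0, floor(tau/bin_width) * bin_width)`.
#'
#' @inheritParams pool_relative_spikes
#' @param bin_width bin width in seconds.
#' @return integer matrix, trials x bins.
#' @export
psth_counts <- function(spikes, events, bin_width, tau = NULL) {
  x <- if (inherits(spikes, "spike_train")) spikes$times else
    sort(as.numeric(spikes))
  w <- events$onsets
  tau <- resolve_tau(events, tau)
  nb <- floor(tau / bin_width + 1e-9)
  if (nb < 1L) stop("bin width exceeds the analysis window")
  lo <- findInterval(w, x)
  hi <- findInterval(w + nb * bin_width, x)
  cnt <- hi - lo
  t_rel <- x[sequence(cnt, from = lo + 1L)] - rep.int(w, cnt)
  trial <- rep.int(seq_along(w), cnt)
  bin <- ceiling(t_rel / bin_width)
  bin[bin < 1L] <- 1L
  counts <- tabulate((trial - 1L) * nb + bin, nbins = length(w) * nb)
  matrix(counts, nrow = length(w), ncol = nb, byrow = TRUE)
}

#' Paired mean-rate t-test between stimulus and baseline epochs
#'
#' Computes per-trial firing rates in a stimulus epoch and a baseline epoch
#' (both relative to each event onset) and applies a paired two-sided
#' t-test across trials. Zero variance of the paired differences yields
#' p = 1 with a flag (a defined value is needed in screening pipelines).
#'
#' @inheritParams pool_relative_spikes
#' @param stim_window numeric `(start, end)` of the stimulus epoch, seconds
#'   relative to onset.
#' @param base_window numeric `(start, end)` of the baseline epoch.
#' @param neuron_id identifier copied into the record.
#' @return a [result_record()] with fields `p`, `statistic` (t), `df`,
#'   `mean_stim_rate`, `mean_base_rate`, `degenerate`.
#' @export
mean_rate_ttest <- function(spikes, events, stim_window = c(0, 1),
                            base_window = c(1, 1.5),
                            neuron_id = NA_character_) {
  x <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  w <- events$onsets
  if (length(w) < 2L) stop("need at least 2 trials")
  if (diff(stim_window) <= 0 || diff(base_window) <= 0) {
    stop("epochs must have positive length")
  }
  if (stim_window[1] < base_window[2] && base_window[1] < stim_window[2]) {
    stop("stimulus and baseline epochs must not overlap")
  }
  rs <- epoch_counts(x, w, stim_window[1], stim_window[2]) /
    diff(stim_window)
  rb <- epoch_counts(x, w, base_window[1], base_window[2]) /
    diff(base_window)
  diffs <- rs - rb
  if (stats::sd(diffs) == 0) {
    return(result_record(neuron_id, "mean-rate-ttest", p = 1,
                         statistic = NA_real_, df = length(w) - 1L,
                         mean_stim_rate = mean(rs), mean_base_rate = mean(rb),
                         degenerate = TRUE))
  }
  ht <- stats::t.test(rs, rb, paired = TRUE)
  result_record(neuron_id, "mean-rate-ttest", p = ht$p.value,
                statistic = unname(ht$statistic), df = unname(ht$parameter),
                mean_stim_rate = mean(rs), mean_base_rate = mean(rb),
                degenerate = FALSE)
}

#' Optimal PSTH bin width (Shimazaki-Shinomoto cost)
#'
#' Minimizes the bin-width cost `C(D) = (2*kbar - v) / (n_trials * D)^2`,
#' where `kbar` and `v` are the mean and (biased) variance over bins of the
#' trial-pooled spike counts. Candidate widths are those that tile the
#' analysis window exactly (`D = tau / nb` for every integer bin count with
#' `D` inside `range`), which avoids partial-coverage artifacts at the
#' window end, and the cost is evaluated exhaustively over all of them: the
#' admissible set is small enough that a full scan is cheap, and the cost
#' landscape of sharply peaked neurons has isolated minima that defeat
#' coarse-to-fine refinement.
#'
#' @inheritParams pool_relative_spikes
#' @param range admissible bin-width interval, seconds
#'   (default `c(0.001, tau/2)`).
#' @return a list with `bin_width` (the minimizer), `n_bins`, `cost`, and
#'   `curve` (data frame of every `(bin_width, cost)` evaluated).
#' @export
optimal_bin_width <- function(spikes, events, tau = NULL, range = NULL) {
  x <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  tau <- resolve_tau(events, tau)
  if (is.null(range)) range <- c(0.001, tau / 2)
  n_trials <- events$q
  nbs <- seq.int(max(2L, ceiling(tau / range[2])), floor(tau / range[1]))
  if (!length(nbs)) stop("no admissible bin width in range")
  if (!length(x)) stop("no spikes fall in any bin")
  costs <- vapply(nbs, function(nb) {
    cnt <- colSums(psth_counts(x, events, tau / nb, tau))
    kbar <- mean(cnt)
    vv <- mean((cnt - kbar)^2)
    (2 * kbar - vv) / (n_trials * tau / nb)^2
  }, numeric(1))
  best <- which.min(costs)
  list(bin_width = tau / nbs[best], n_bins = nbs[best], cost = costs[best],
       curve = data.frame(bin_width = tau / nbs, cost = costs))
}

# One-way ANOVA with bins as groups and per-trial counts as observations.
anova_on_counts <- function(counts) {
  if (max(counts) == min(counts)) {
    return(list(p = 1, F = NA_real_, degenerate = TRUE))
  }
  grp <- factor(rep(seq_len(ncol(counts)), each = nrow(counts)))
  ht <- stats::oneway.test(as.vector(counts) ~ grp, var.equal = TRUE)
  p <- ht$p.value
  if (is.na(p)) p <- 1
  list(p = p, F = unname(ht$statistic), degenerate = FALSE)
}

#' PSTH one-way ANOVA for responsiveness
#'
#' Builds a PSTH count matrix (trials x bins) at the given bin width and
#' tests with a one-way ANOVA whether mean counts differ across bins
#' (bins as groups, trials as replicates).
#'
#' @inheritParams psth_counts
#' @param neuron_id identifier copied into the record.
#' @return a [result_record()] with `p`, `statistic` (F), `bin_width`,
#'   `n_bins`, `degenerate`.
#' @export
psth_anova <- function(spikes, events, bin_width, tau = NULL,
                       neuron_id = NA_character_) {
  tau <- resolve_tau(events, tau)
  counts <- psth_counts(spikes, events, bin_width, tau)
  if (ncol(counts) < 2L) stop("need at least 2 bins")
  if (nrow(counts) < 2L) stop("need at least 2 trials")
  res <- anova_on_counts(counts)
  result_record(neuron_id, "psth-anova", p = res$p, statistic = res$F,
                bin_width = bin_width, n_bins = ncol(counts),
                degenerate = res$degenerate)
}

#' Multi-timescale ANOVA battery
#'
#' Runs one PSTH ANOVA per bin width on a base-2 logarithmic grid
#' `center_bin * 2^(-steps..steps)` (19 widths by default, one movie frame
#' at the center), drops widths that do not fit at least two bins in the
#' window (with a warning), and reports the Bonferroni-corrected minimum
#' p-value across the widths actually tested.
#'
#' @inheritParams psth_anova
#' @param center_bin central bin width in seconds (default 1/60 s).
#' @param steps half-width of the exponent grid (default 9).
#' @return a [result_record()] with `p` (Bonferroni-corrected), `statistic`
#'   (F at the winning width), `best_bin_width`, `n_widths`, and aux vectors
#'   `bin_widths`, `p_values`.
#' @export
multiscale_anova <- function(spikes, events, tau = NULL, center_bin = 1 / 60,
                             steps = 9L, neuron_id = NA_character_) {
  tau <- resolve_tau(events, tau)
  widths <- center_bin * 2^seq.int(-steps, steps)
  fits <- floor(tau / widths) >= 2
  if (!all(fits)) {
    warning(sprintf("dropping %d bin widths exceeding the window",
                    sum(!fits)))
  }
  widths <- widths[fits]
  if (!length(widths)) stop("no bin width fits the analysis window")
  recs <- lapply(widths, function(bw) psth_anova(spikes, events, bw, tau))
  pv <- vapply(recs, `[[`, numeric(1), "p")
  k <- which.min(pv)
  rec <- result_record(neuron_id, "multiscale-anova",
                       p = min(1, length(widths) * pv[k]),
                       statistic = recs[[k]]$statistic,
                       best_bin_width = widths[k], n_widths = length(widths))
  rec$bin_widths <- widths
  rec$p_values <- pv
  rec
}

# Trial-averaged 1 ms (or other) binned rate vector.
trial_average_counts <- function(x, events, bin, tau) {
  colMeans(psth_counts(x, events, bin, tau))
}

#' Renewal-process surrogate tests for responsiveness
#'
#' Implements the four decomposition tests built from binned trial-averaged
#' spike counts (1 ms bins by default):
#' \describe{
#'   \item{poiss-ks}{one-sample KS test of trial-averaged per-bin counts
#'     against the analytic homogeneous-Poisson trial-average null
#'     (a scaled Poisson with mean `T * lambda * bin`); a two-sample Monte
#'     Carlo variant is available via `ks_two_sample = TRUE`.}
#'   \item{sisi-ks}{two-sample KS test of the observed trial-averaged counts
#'     against counts from ISI-shuffled surrogate trains.}
#'   \item{sisi-g}{Gumbel p-value of the maximum absolute deviation of the
#'     trial-averaged PSTH from its mean, against ISI-shuffled surrogates.}
#'   \item{sisi-ig}{Gumbel p-value of the maximum absolute mean-centered
#'     cumulative-count deviation (cumulative sum of mean-subtracted counts,
#'     itself mean-subtracted), against ISI-shuffled surrogates.}
#' }
#'
#' @inheritParams pool_relative_spikes
#' @param tests which of the four tests to run.
#' @param replicates number of ISI-shuffle surrogates (>= 2; default 100).
#' @param bin bin width in seconds (default 0.001).
#' @param seed optional integer seed.
#' @param ks_two_sample use the two-sample Monte Carlo variant of the
#'   Poisson KS test instead of the analytic one-sample version.
#' @param neuron_id identifier copied into the records.
#' @return a named list of [result_record()]s, one per requested test.
#' @export
surrogate_tests <- function(spikes, events, tau = NULL,
                            tests = c("poiss-ks", "sisi-ks", "sisi-g",
                                      "sisi-ig"),
                            replicates = 100, bin = 0.001, seed = NULL,
                            ks_two_sample = FALSE,
                            neuron_id = NA_character_) {
  tests <- match.arg(tests, several.ok = TRUE)
  x <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  tau <- resolve_tau(events, tau)
  if (!is.null(seed)) set.seed(seed)
  n_trials <- events$q
  xbar <- trial_average_counts(x, events, bin, tau)
  nb <- length(xbar)
  out <- list()
  if ("poiss-ks" %in% tests) {
    lambda <- sum(xbar) / (nb * bin)        # per-trial mean rate, Hz
    if (ks_two_sample) {
      h0 <- stats::rpois(n_trials * nb, lambda * bin * n_trials) / n_trials
      ht <- suppressWarnings(stats::ks.test(xbar, h0))
    } else {
      ht <- suppressWarnings(
        stats::ks.test(round(xbar * n_trials), stats::ppois,
                       lambda * bin * n_trials))
    }
    out[["poiss-ks"]] <- result_record(neuron_id, "poiss-ks", p = ht$p.value,
                                       statistic = unname(ht$statistic),
                                       rate = lambda, bin = bin)
  }
  need_surr <- any(c("sisi-ks", "sisi-g", "sisi-ig") %in% tests)
  if (need_surr) {
    if (replicates < 2L) stop("need at least 2 surrogate replicates")
    if (length(x) < 3L) stop("need at least 3 spikes for ISI shuffling")
    surr <- matrix(0, nrow = replicates, ncol = nb)
    for (r in seq_len(replicates)) {
      surr[r, ] <- trial_average_counts(shuffle_isi(x), events, bin, tau)
    }
    if ("sisi-ks" %in% tests) {
      ht <- suppressWarnings(stats::ks.test(xbar, as.vector(surr)))
      out[["sisi-ks"]] <- result_record(neuron_id, "sisi-ks", p = ht$p.value,
                                        statistic = unname(ht$statistic),
                                        replicates = replicates, bin = bin)
    }
    if ("sisi-g" %in% tests) {
      stat_fun <- function(z) max(abs(z - mean(z)))
      obs <- stat_fun(xbar)
      nulls <- apply(surr, 1L, stat_fun)
      sig <- gumbel_significance(nulls, obs)
      out[["sisi-g"]] <- result_record(neuron_id, "sisi-g", p = sig$p,
                                       statistic = obs,
                                       zeta_corrected = sig$zeta_corrected,
                                       replicates = replicates, bin = bin)
    }
    if ("sisi-ig" %in% tests) {
      stat_fun <- function(z) {
        tj <- cumsum(z - mean(z))
        max(abs(tj - mean(tj)))
      }
      obs <- stat_fun(xbar)
      nulls <- apply(surr, 1L, stat_fun)
      sig <- gumbel_significance(nulls, obs)
      out[["sisi-ig"]] <- result_record(neuron_id, "sisi-ig", p = sig$p,
                                        statistic = obs,
                                        zeta_corrected = sig$zeta_corrected,
                                        replicates = replicates, bin = bin)
    }
  }
  out
}
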