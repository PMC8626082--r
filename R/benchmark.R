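# ROC/AUC machinery and end-to-end simulation benchmark runners.

#' ROC curve and AUC from two sets of p-values
#'
#' Sweeps the significance level over all observed p-values; the
#' true-positive (inclusion) rate is the fraction of positives with
#' `p < alpha`, the false-positive rate likewise for negatives. The AUC is
#' the trapezoid area of that curve, which on finite samples equals the
#' Wilcoxon-Mann-Whitney rank statistic `U/(n_pos*n_neg)` (ties credited
#' 1/2).
#'
#' @param p_positives p-values of the ground-truth positive class.
#' @param p_negatives p-values of the ground-truth negative class.
#' @return an object of class `"roc_result"`: `alpha`, `tpr`, `fpr`, `auc`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(p_positives, p_negatives) {
  if (!length(p_positives) || !length(p_negatives)) {
    stop("both classes must be non-empty")
  }
  sp <- sort(p_positives)
  sn <- sort(p_negatives)
  alpha <- c(0, sort(unique(c(sp, sn))), Inf)
  tpr <- findInterval(alpha, sp, left.open = TRUE) / length(sp)
  fpr <- findInterval(alpha, sn, left.open = TRUE) / length(sn)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(alpha = alpha, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = length(sp), n_neg = length(sn)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives vs %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Inclusion rate at a significance level
#'
#' Fraction of p-values below `alpha`, with an exact binomial 95%
#' confidence interval.
#'
#' @param p_values p-values in \[0, 1\].
#' @param alpha significance level (default 0.05).
#' @return a list with `rate`, `ci` (length-2), `n_included`, `n`.
#' @export
inclusion_rate <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("empty p-value set")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  k <- sum(p_values < alpha)
  n <- length(p_values)
  ci <- stats::binom.test(k, n)$conf.int
  list(rate = k / n, ci = as.numeric(ci), n_included = k, n = n)
}

# Bootstrap CI of an AUC over neurons (percentile method).
auc_bootstrap_ci <- function(p_pos, p_neg, n_boot = 1000, level = 0.95) {
  stats_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    stats_b[b] <- roc_auc(sample(p_pos, replace = TRUE),
                          sample(p_neg, replace = TRUE))$auc
  }
  stats::quantile(stats_b, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
}

#' Bursting-cell power benchmark
#'
#' Simulates a stimulus-responsive and a rate-matched unresponsive bursting
#' population, runs the onset-jitter ZETA-test, the ISI-shuffle ZETA-test
#' and the paired mean-rate t-test on every neuron, and reports the three
#' ROC AUCs of p-values against ground truth (with bootstrap CIs).
#'
#' @param n_per_class neurons per class (default 250).
#' @param resamples ZETA resamples per neuron (default 100).
#' @param repeats grating repetitions per direction (default 20; with 24
#'   directions this gives 480 trials).
#' @param stim_epoch,base_epoch t-test epochs relative to onset, seconds.
#' @param n_boot bootstrap resamples for the AUC CIs (default 500).
#' @param seed integer seed.
#' @return a list of class `"benchmark_report"` with per-test AUCs
#'   (`auc_zeta_jitter`, `auc_zeta_isi`, `auc_ttest`), bootstrap CIs, ROC
#'   objects, and the per-neuron p-value table `p_table`.
#' @export
run_bursting_benchmark <- function(n_per_class = 250, resamples = 100,
                                   repeats = 20, stim_epoch = c(0, 1),
                                   base_epoch = c(1, 1.5), n_boot = 500,
                                   seed = 1) {
  pop_pos <- simulate_bursting(n_per_class, responsive = TRUE,
                               repeats = repeats, seed = seed)
  pop_neg <- simulate_bursting(n_per_class, responsive = FALSE,
                               repeats = repeats, seed = seed + 1L)
  run_tests <- function(pop, seed0) {
    n <- length(pop$trains)
    out <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, c("zeta_jitter", "zeta_isi",
                                          "ttest")))
    for (i in seq_len(n)) {
      tr <- pop$trains[[i]]
      ev <- pop$events[[i]]
      out[i, 1] <- zeta_test(tr, ev, resamples = resamples,
                             null_mode = "jitter", seed = seed0 + i)$p
      out[i, 2] <- zeta_test(tr, ev, resamples = resamples,
                             null_mode = "isi", seed = seed0 + i)$p
      out[i, 3] <- mean_rate_ttest(tr, ev, stim_epoch, base_epoch)$p
    }
    out
  }
  p_pos <- run_tests(pop_pos, seed + 1000L)
  p_neg <- run_tests(pop_neg, seed + 2000L)
  set.seed(seed + 3000L)
  rocs <- lapply(colnames(p_pos), function(nm) {
    roc_auc(p_pos[, nm], p_neg[, nm])
  })
  names(rocs) <- colnames(p_pos)
  cis <- lapply(colnames(p_pos), function(nm) {
    auc_bootstrap_ci(p_pos[, nm], p_neg[, nm], n_boot = n_boot)
  })
  names(cis) <- colnames(p_pos)
  p_table <- data.frame(
    neuron_id = c(pop_pos$truth$neuron_id, pop_neg$truth$neuron_id),
    modulated = c(pop_pos$truth$modulated, pop_neg$truth$modulated),
    rbind(p_pos, p_neg), stringsAsFactors = FALSE)
  structure(list(auc_zeta_jitter = rocs$zeta_jitter$auc,
                 auc_zeta_isi = rocs$zeta_isi$auc,
                 auc_ttest = rocs$ttest$auc,
                 ci_zeta_jitter = cis$zeta_jitter,
                 ci_zeta_isi = cis$zeta_isi,
                 ci_ttest = cis$ttest,
                 rocs = rocs, p_table = p_table,
                 n_per_class = n_per_class, resamples = resamples,
                 seed = seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report\n")
  for (nm in names(x)) {
    if (startsWith(nm, "auc_") && is.numeric(x[[nm]])) {
      ci <- x[[paste0("ci_", sub("^auc_", "", nm))]]
      if (!is.null(ci)) {
        cat(sprintf("  %s = %.4f [%.4f, %.4f]\n", nm, x[[nm]], ci[1], ci[2]))
      } else {
        cat(sprintf("  %s = %.4f\n", nm, x[[nm]]))
      }
    }
  }
  invisible(x)
}

#' Type-I calibration benchmark on event-unlocked twins
#'
#' Simulates a population, destroys the event locking with [make_null_twin()]
#' (independent onset jitter by default), runs the ZETA-test and optionally
#' the mean-rate t-test on every twin, and reports false-positive rates
#' across a grid of significance levels.
#'
#' @param n_neurons number of neurons (default 1000).
#' @param resamples ZETA resamples (default 100).
#' @param alpha_grid significance levels to evaluate (default
#'   `c(0.01, 0.05, 0.1)`).
#' @param generator population generator: `"tuned-poisson"` (default) or a
#'   function `(n, seed) -> sim_population`.
#' @param twin_mode null-twin construction, `"jitter"` or `"isi-shuffle"`.
#' @param with_ttest also run the paired t-test (stim `[0,1]` vs ITI
#'   `[1, 1.5]` s) on the twins.
#' @param seed integer seed.
#' @return a `"benchmark_report"` list with `fpr` (data frame: alpha, test,
#'   rate, CI) and the per-neuron p-values.
#' @export
run_calibration_benchmark <- function(n_neurons = 1000, resamples = 100,
                                      alpha_grid = c(0.01, 0.05, 0.1),
                                      generator = "tuned-poisson",
                                      twin_mode = c("jitter", "isi-shuffle"),
                                      with_ttest = FALSE, seed = 1) {
  twin_mode <- match.arg(twin_mode)
  pop <- if (is.function(generator)) {
    generator(n_neurons, seed)
  } else {
    simulate_tuned_poisson(n_neurons, seed = seed)
  }
  twin <- make_null_twin(pop, mode = twin_mode, seed = seed + 1L)
  n <- length(twin$trains)
  p_zeta <- numeric(n)
  p_t <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- twin$trains[[i]]
    ev <- twin$events[[i]]
    p_zeta[i] <- zeta_test(tr, ev, resamples = resamples,
                           seed = seed + 10L + i)$p
    if (with_ttest) {
      p_t[i] <- mean_rate_ttest(tr, ev, c(0, 1), c(1, 1.5))$p
    }
  }
  rows <- list()
  for (a in alpha_grid) {
    ir <- inclusion_rate(p_zeta, a)
    rows[[length(rows) + 1L]] <-
      data.frame(test = "zeta", alpha = a, fpr = ir$rate,
                 ci_lo = ir$ci[1], ci_hi = ir$ci[2])
    if (with_ttest) {
      ir <- inclusion_rate(p_t, a)
      rows[[length(rows) + 1L]] <-
        data.frame(test = "ttest", alpha = a, fpr = ir$rate,
                   ci_lo = ir$ci[1], ci_hi = ir$ci[2])
    }
  }
  structure(list(fpr = do.call(rbind, rows), p_zeta = p_zeta,
                 p_ttest = if (with_ttest) p_t else NULL,
                 n_neurons = n, resamples = resamples,
                 twin_mode = twin_mode, seed = seed),
            class = "benchmark_report")
}

# PSTH-based peak latency: center of the bin with the highest trial-averaged
# count (earliest bin on ties).
psth_peak_latency <- function(spikes, events, bin_width, tau) {
  avg <- colMeans(psth_counts(spikes, events, bin_width, tau))
  (which.max(avg) - 0.5) * bin_width
}

#' Peak-latency estimation benchmark
#'
#' For every peak-jitter width sigma, simulates peak-benchmark neurons and
#' compares the binless IFR peak-latency estimate against fixed-bin PSTH
#' estimates over a base-1.5 logarithmic bin grid (1.00-57.67 ms by
#' default). Reports per-sigma mean and SD of the IFR error, the mean
#' absolute error per PSTH bin width, and the best fixed bin.
#'
#' @param sigmas peak jitter SDs, seconds (default 1-10 ms).
#' @param base_rate background rate, Hz (default 32).
#' @param n_neurons neurons per sigma (default 50).
#' @param trials trials per neuron (default 100).
#' @param bin_grid PSTH bin widths, seconds (default `1.5^(0:10)` ms).
#' @param seed integer seed.
#' @return a `"benchmark_report"` list with `summary` (data frame per
#'   sigma: IFR mean/SD error, best-bin mean absolute error) and
#'   `psth_errors` (matrix sigma x bin width of mean absolute errors).
#' @export
run_latency_benchmark <- function(sigmas = seq(0.001, 0.01, by = 0.001),
                                  base_rate = 32, n_neurons = 50,
                                  trials = 100,
                                  bin_grid = 1.5^(0:10) / 1000, seed = 1) {
  n_sig <- length(sigmas)
  psth_err <- matrix(NA_real_, n_sig, length(bin_grid),
                     dimnames = list(sprintf("%.3f", sigmas * 1000),
                                     sprintf("%.2f", bin_grid * 1000)))
  ifr_mean <- ifr_sd <- ifr_abs <- numeric(n_sig)
  ifr_errs <- matrix(NA_real_, n_sig, n_neurons)
  psth_abs_per_neuron <- array(NA_real_, c(n_sig, length(bin_grid),
                                           n_neurons))
  for (s in seq_len(n_sig)) {
    pop <- simulate_peak_latency(n_neurons, base_rate = base_rate,
                                 sigma = sigmas[s], trials = trials,
                                 seed = seed + s)
    for (i in seq_len(n_neurons)) {
      tr <- pop$trains[[i]]
      ev <- pop$events[[i]]
      truth <- pop$truth$peak_time[i]
      rate <- ifr(tr, ev)
      lat <- latency_estimates(rate)
      ifr_errs[s, i] <- lat$peak_time - truth
      tau <- default_window(ev)
      for (b in seq_along(bin_grid)) {
        psth_abs_per_neuron[s, b, i] <-
          abs(psth_peak_latency(tr, ev, bin_grid[b], tau) - truth)
      }
    }
    ifr_mean[s] <- mean(ifr_errs[s, ])
    ifr_sd[s] <- stats::sd(ifr_errs[s, ])
    ifr_abs[s] <- mean(abs(ifr_errs[s, ]))
    psth_err[s, ] <- apply(psth_abs_per_neuron[s, , , drop = FALSE], 2,
                           mean)
  }
  best_bin <- apply(psth_err, 1, which.min)
  summary <- data.frame(sigma = sigmas, ifr_mean_error = ifr_mean,
                        ifr_sd_error = ifr_sd, ifr_abs_error = ifr_abs,
                        best_bin_width = bin_grid[best_bin],
                        best_bin_abs_error = psth_err[cbind(seq_len(n_sig),
                                                            best_bin)])
  structure(list(summary = summary, psth_errors = psth_err,
                 ifr_errors = ifr_errs,
                 psth_abs_per_neuron = psth_abs_per_neuron,
                 bin_grid = bin_grid, sigmas = sigmas,
                 base_rate = base_rate, n_neurons = n_neurons,
                 trials = trials, seed = seed),
            class = "benchmark_report")
}
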