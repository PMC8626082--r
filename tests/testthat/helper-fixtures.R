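# Shared fixtures, built in code at test time.

# Homogeneous Poisson spike train over [0, total] seconds.
poisson_train <- function(rate, total, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, rate * total)
  spike_train(sort(runif(n, 0, total)))
}

# Regular event grid: q events every `period` seconds starting at 0.
event_grid <- function(q, period) {
  event_series((seq_len(q) - 1) * period)
}

# Train realizing prescribed per-trial spike counts in two epochs of each
# trial (epochs relative to onset); spikes are spread regularly inside each
# epoch so counts are exact.
counts_train <- function(events, stim_counts, base_counts,
                         stim_window = c(0, 1), base_window = c(1, 2)) {
  w <- events$onsets
  place <- function(k, lo, hi, onset) {
    if (k == 0) return(numeric(0))
    onset + seq(lo + (hi - lo) / (2 * k), hi - (hi - lo) / (2 * k),
                length.out = k)
  }
  spikes <- c(
    unlist(mapply(place, stim_counts, MoreArgs = list(),
                  lo = stim_window[1], hi = stim_window[2], onset = w,
                  SIMPLIFY = FALSE)),
    unlist(mapply(place, base_counts, MoreArgs = list(),
                  lo = base_window[1], hi = base_window[2], onset = w,
                  SIMPLIFY = FALSE)))
  spike_train(sort(spikes))
}

# Neuron with a constant background and an extra spike at `peak_t` in every
# trial: strong, reliable event-locked peak.
peaked_train <- function(events, tau, background = 10, peak_t = 0.1,
                         jitter = 0.002, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- events$onsets
  total <- max(w) + tau
  bg <- sort(runif(rpois(1, background * total), 0, total))
  spikes <- c(bg, w + peak_t + rnorm(length(w), 0, jitter))
  spike_train(sort(spikes[spikes >= 0]))
}

# Manual paired two-sided t-test (textbook formulas), as an oracle.
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, p = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE))
}

# Manual one-way ANOVA (textbook formulas) on a trials x bins count matrix.
anova_oracle <- function(counts) {
  groups <- rep(seq_len(ncol(counts)), each = nrow(counts))
  y <- as.vector(counts)
  gm <- tapply(y, groups, mean)
  ssb <- sum(tabulate(groups) * (gm - mean(y))^2)
  ssw <- sum((y - gm[groups])^2)
  df1 <- ncol(counts) - 1
  df2 <- length(y) - ncol(counts)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Mann-Whitney AUC by explicit pairwise comparison (ties credited 1/2).
pairwise_auc_oracle <- function(p_pos, p_neg) {
  cmp <- outer(p_pos, p_neg, FUN = function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}
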