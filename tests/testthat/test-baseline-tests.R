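test_that("paired mean-rate t-test matches a textbook computation", {
  ev <- event_grid(5, 2)
  tr <- counts_train(ev, stim_counts = c(5, 6, 4, 7, 5),
                     base_counts = c(1, 0, 2, 1, 1))
  rec <- mean_rate_ttest(tr, ev, stim_window = c(0, 1),
                         base_window = c(1, 2))
  oracle <- paired_t_oracle(c(5, 6, 4, 7, 5), c(1, 0, 2, 1, 1))
  expect_equal(rec$p, oracle$p, tolerance = 1e-12)
  expect_equal(rec$statistic, oracle$t, tolerance = 1e-12)

  # identical epoch rates in every trial: defined convention p = 1
  tr2 <- counts_train(ev, stim_counts = rep(3, 5), base_counts = rep(3, 5))
  rec2 <- mean_rate_ttest(tr2, ev, c(0, 1), c(1, 2))
  expect_equal(rec2$p, 1)
  expect_true(rec2$degenerate)

  expect_error(mean_rate_ttest(tr, ev, c(0, 1), c(0.5, 1.5)), "overlap")
})

test_that("a strong rate step is detected with very small p", {
  set.seed(15)
  ev <- event_grid(100, 2)
  stim <- rpois(100, 20)
  base <- rpois(100, 5)
  tr <- counts_train(ev, stim, base)
  expect_lt(mean_rate_ttest(tr, ev, c(0, 1), c(1, 2))$p, 1e-6)
})

test_that("PSTH ANOVA matches a hand-computed one-way ANOVA", {
  # trials x bins count matrix [[1,5],[2,6],[1,7]]
  counts <- matrix(c(1, 2, 1, 5, 6, 7), nrow = 3)
  ev <- event_grid(3, 1)
  tr <- counts_train(ev, counts[, 1], counts[, 2],
                     stim_window = c(0, 0.5), base_window = c(0.5, 1))
  rec <- psth_anova(tr, ev, bin_width = 0.5, tau = 1)
  oracle <- anova_oracle(counts)
  expect_equal(rec$p, oracle$p, tolerance = 1e-12)
  expect_equal(rec$statistic, oracle$F, tolerance = 1e-12)

  # all counts identical: degenerate, p = 1
  tr2 <- counts_train(ev, rep(2, 3), rep(2, 3),
                      stim_window = c(0, 0.5), base_window = c(0.5, 1))
  rec2 <- psth_anova(tr2, ev, 0.5, tau = 1)
  expect_equal(rec2$p, 1)
  expect_true(rec2$degenerate)

  # power sanity: a sharp onset peak at 25 ms bins
  ev3 <- event_grid(50, 2)
  tr3 <- peaked_train(ev3, 2, background = 5, seed = 16)
  expect_lt(psth_anova(tr3, ev3, 0.025)$p, 0.001)
})

test_that("optimal bin width equals an independent brute-force evaluation", {
  set.seed(17)
  for (k in 1:8) {
    ev <- event_grid(30, 2)
    tr <- peaked_train(ev, 2, background = runif(1, 2, 15),
                       peak_t = runif(1, 0.05, 0.5),
                       jitter = runif(1, 0.005, 0.05))
    res <- optimal_bin_width(tr, ev, tau = 2)
    # independent oracle: per-trial histograms over every admissible
    # window-tiling width, cost computed from scratch
    oracle <- vapply(2:2000, function(nb) {
      d <- 2 / nb
      cnt <- rep(0, nb)
      for (w in ev$onsets) {
        rel <- tr$times[tr$times > w & tr$times <= w + 2] - w
        h <- hist(rel, breaks = seq(0, 2, length.out = nb + 1),
                  plot = FALSE, right = TRUE)
        cnt <- cnt + h$counts
      }
      kbar <- mean(cnt)
      (2 * kbar - mean((cnt - kbar)^2)) / (30 * d)^2
    }, numeric(1))
    expect_equal(res$cost, min(oracle), tolerance = 1e-12)
    expect_equal(res$n_bins, (2:2000)[which.min(oracle)])
  }
})

test_that("the bin-width cost favors wide bins for a structureless train", {
  tr <- poisson_train(20, 60, seed = 18)
  ev <- event_grid(30, 2)
  res <- optimal_bin_width(tr, ev, tau = 2)
  expect_gt(res$bin_width, 0.5)     # toward the largest allowed (tau/2 = 1)
})

test_that("multi-timescale ANOVA builds the base-2 width battery", {
  ev <- event_grid(20, 20)
  tr <- poisson_train(5, 400, seed = 19)
  rec <- multiscale_anova(tr, ev, tau = 20)
  expect_equal(rec$n_widths, 19)
  expect_equal(rec$bin_widths, (1 / 60) * 2^(-9:9))
  expect_equal(rec$p, min(1, 19 * min(rec$p_values)))

  # widths that do not fit the window are dropped with a warning
  ev2 <- event_grid(20, 2)
  tr2 <- poisson_train(5, 40, seed = 20)
  expect_warning(rec2 <- multiscale_anova(tr2, ev2, tau = 2), "dropping")
  expect_lt(rec2$n_widths, 19)
  expect_equal(rec2$p, min(1, rec2$n_widths * min(rec2$p_values)))
})

test_that("surrogate tests reproduce the hand-computed cumulative statistic", {
  # two identical trials with 1 ms-binned counts [2,0,0,2]:
  # T0 = cumsum([1,-1,-1,1]) = [1,0,-1,0], centered max|.| = 1
  ev <- event_series(c(0, 0.004))
  x <- c(0.0002, 0.0003, 0.0035, 0.0036,
         0.0042, 0.0043, 0.0075, 0.0076)
  res <- surrogate_tests(x, ev, tau = 0.004, tests = "sisi-ig",
                         replicates = 10, seed = 30)
  expect_equal(res[["sisi-ig"]]$statistic, 1)

  # determinism
  res2 <- surrogate_tests(x, ev, tau = 0.004, replicates = 10, seed = 30)
  res3 <- surrogate_tests(x, ev, tau = 0.004, replicates = 10, seed = 30)
  for (nm in names(res2)) expect_identical(res2[[nm]]$p, res3[[nm]]$p)

  expect_error(surrogate_tests(x, ev, tau = 0.004, tests = "sisi-g",
                               replicates = 1), "at least 2")
})

test_that("surrogate tests detect strongly modulated neurons", {
  set.seed(31)
  ev <- event_grid(60, 2)
  w <- ev$onsets
  # rate step (20 Hz -> 2 Hz): detected by the distribution-shape KS tests
  step <- spike_train(sort(c(
    unlist(lapply(w, function(o) o + runif(rpois(1, 20), 0, 1))),
    unlist(lapply(w, function(o) o + 1 + runif(rpois(1, 2), 0, 1))))))
  res_ks <- surrogate_tests(step, ev, tau = 2,
                            tests = c("poiss-ks", "sisi-ks", "sisi-ig"),
                            replicates = 60, seed = 32)
  expect_lt(res_ks[["poiss-ks"]]$p, 0.01)
  expect_lt(res_ks[["sisi-ks"]]$p, 0.01)
  expect_lt(res_ks[["sisi-ig"]]$p, 0.01)
  # sharp reliable peak: detected by the extreme-deviation Gumbel tests
  peak <- peaked_train(ev, 2, background = 8, jitter = 0.005, seed = 31)
  res_g <- surrogate_tests(peak, ev, tau = 2,
                           tests = c("sisi-g", "sisi-ig"),
                           replicates = 60, seed = 33)
  expect_lt(res_g[["sisi-g"]]$p, 0.01)
  expect_lt(res_g[["sisi-ig"]]$p, 0.01)
})

test_that("Gumbel-based surrogate tests are calibrated under their own null", {
  set.seed(33)
  n_sim <- 300
  pg <- pig <- numeric(n_sim)
  ev <- event_grid(30, 1)
  for (k in seq_len(n_sim)) {
    tr <- poisson_train(15, 30)
    res <- surrogate_tests(tr, ev, tau = 1, tests = c("sisi-g", "sisi-ig"),
                           replicates = 40, seed = sample.int(1e6, 1))
    pg[k] <- res[["sisi-g"]]$p
    pig[k] <- res[["sisi-ig"]]$p
  }
  # 3-sigma binomial band around 0.05 at n = 300: (0.012, 0.088)
  expect_gt(mean(pg < 0.05), 0.012)
  expect_lt(mean(pg < 0.05), 0.088)
  expect_gt(mean(pig < 0.05), 0.012)
  expect_lt(mean(pig < 0.05), 0.088)
})
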