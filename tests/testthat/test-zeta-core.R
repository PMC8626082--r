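test_that("relative-spike pooling assigns spikes to the most recent onset", {
  ev <- event_series(c(0, 1.5))
  rel <- pool_relative_spikes(c(0.2, 0.4, 1.7), ev, tau = 1.5)
  expect_equal(rel$v, c(0, 0.2, 0.2, 0.4, 1.5))
  expect_equal(rel$n, 5)
  expect_false(rel$empty)

  # boundary: relative time exactly tau is included
  rel2 <- pool_relative_spikes(2.0, event_series(c(0, 1)), tau = 1)
  expect_equal(rel2$v, c(0, 1.0, 1.0))

  # no spikes anywhere: sentinel-only vector, flagged
  rel3 <- pool_relative_spikes(numeric(0), ev, tau = 1.5)
  expect_equal(rel3$v, c(0, 1.5))
  expect_true(rel3$empty)
})

test_that("deviation curve matches hand-computed values and is mean-centered", {
  rel <- structure(list(v = c(0, 0.2, 0.4, 1.0), n = 4L, tau = 1, q = 2,
                        empty = FALSE), class = "relative_spikes")
  cv <- deviation_curve(rel)
  expect_equal(cv$g, c(0.25, 0.5, 0.75, 1))
  expect_equal(cv$b, c(0, 0.2, 0.4, 1))
  expect_equal(cv$delta, c(0.25, 0.30, 0.35, 0))
  expect_equal(cv$delta_bar, 0.225)
  expect_equal(cv$d, c(0.025, 0.075, 0.125, -0.225))

  rel2 <- structure(list(v = c(0, 0.5, 1.0), n = 3L, tau = 1, q = 2,
                         empty = FALSE), class = "relative_spikes")
  cv2 <- deviation_curve(rel2)
  expect_equal(cv2$delta, c(1 / 3, 1 / 6, 0))
  expect_equal(cv2$d, c(1 / 6, 0, -1 / 6))

  # sum(d) == 0 on arbitrary pooled vectors
  set.seed(1)
  for (k in 1:20) {
    tau <- runif(1, 0.5, 3)
    rel <- pool_relative_spikes(sort(runif(50, 0, 10)),
                                event_series(c(0, 2, 4, 6, 8)), tau = tau)
    expect_equal(sum(deviation_curve(rel)$d), 0, tolerance = 1e-12)
  }
})

test_that("zeta statistic takes the extreme deviation with earliest-time ties", {
  cv <- structure(list(v = c(0, 0.2, 0.4, 1.0), d = c(0.025, 0.075, 0.125,
                                                      -0.225)),
                  class = "deviation_curve")
  st <- zeta_statistic(cv)
  expect_equal(st$zeta_raw, 0.225)
  expect_equal(st$zeta_time, 1.0)
  expect_equal(st$zeta_sign, -1)
  expect_equal(st$inverse_zeta_time, 0.4)

  tie <- structure(list(v = c(0, 0.3, 0.6, 1), d = c(0.3, -0.3, 0.3, -0.3)),
                   class = "deviation_curve")
  expect_equal(zeta_statistic(tie)$zeta_time, 0)   # earliest of the ties

  flat <- structure(list(v = c(0, 1), d = c(0, 0)), class = "deviation_curve")
  expect_equal(zeta_statistic(flat)$zeta_raw, 0)
})

test_that("Gumbel significance matches analytic evaluations", {
  # statistic at the fitted mode: p = 1 - exp(-1)
  set.seed(2)
  s <- rnorm(50, 1, 0.2)
  fit <- gumbel_significance(s, zeta_raw = mean(s) -
                               sqrt(6 * var(s)) / pi * (-digamma(1)))
  expect_equal(fit$p, 1 - exp(-1), tolerance = 1e-12)

  # mean 1, var 1, zeta = 3  =>  beta = sqrt(6)/pi, m ~ 0.5499, p ~ 0.042
  s2 <- c(1 - sqrt(0.5), 1 + sqrt(0.5))
  fit2 <- gumbel_significance(s2, 3)
  expect_equal(fit2$fit$beta, sqrt(6) / pi, tolerance = 1e-12)
  expect_equal(fit2$fit$mode_m, 1 - sqrt(6) / pi * (-digamma(1)),
               tolerance = 1e-12)
  expect_equal(fit2$p, 0.042, tolerance = 0.02)
  expect_equal(fit2$zeta_corrected, qnorm(1 - fit2$p / 2), tolerance = 1e-9)

  # strictly decreasing in the observed statistic for a fixed fit
  ps <- vapply(seq(0.5, 4, by = 0.25),
               function(z) gumbel_significance(s2, z)$p, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(gumbel_significance(c(1, 1, 1), 2), "degenerate")

  # extreme statistic: p clamped away from zero and flagged
  sat <- gumbel_significance(s2, 1e6)
  expect_gt(sat$p, 0)
  expect_true(sat$saturated)
})

test_that("null distributions are reproducible and structurally sound", {
  tr <- poisson_train(20, 40, seed = 3)
  ev <- event_grid(20, 2)
  n1 <- jitter_null(tr, ev, resamples = 30, seed = 11)
  n2 <- jitter_null(tr, ev, resamples = 30, seed = 11)
  expect_identical(n1$zeta_samples, n2$zeta_samples)
  expect_true(all(is.finite(n1$zeta_samples)) && all(n1$zeta_samples >= 0))

  i1 <- isi_shuffle_null(tr, ev, resamples = 30, seed = 12)
  i2 <- isi_shuffle_null(tr, ev, resamples = 30, seed = 12)
  expect_identical(i1$zeta_samples, i2$zeta_samples)
  expect_false(identical(n1$zeta_samples, i1$zeta_samples))
})

test_that("ISI shuffling conserves spike count and total duration", {
  set.seed(4)
  x <- sort(runif(200, 0, 50))
  for (k in 1:10) {
    x0 <- zetatest:::shuffle_isi(x)
    expect_length(x0, length(x))
    expect_equal(x0[1], x[1])
    expect_equal(max(x0) - min(x0), max(x) - min(x), tolerance = 1e-12)
    expect_equal(sort(diff(x0)), sort(diff(x)), tolerance = 1e-12)
  }
})

test_that("jitter and ISI-shuffle nulls agree for a homogeneous Poisson train", {
  tr <- poisson_train(20, 60, seed = 5)
  ev <- event_grid(40, 1.5)
  nj <- jitter_null(tr, ev, resamples = 1000, seed = 21)
  ni <- isi_shuffle_null(tr, ev, resamples = 1000, seed = 22)
  ks <- suppressWarnings(ks.test(nj$zeta_samples, ni$zeta_samples))
  expect_gt(ks$p.value, 0.01)
})

test_that("the composed test is deterministic, two-sided, and flags empty input", {
  ev <- event_grid(30, 2)
  tr <- peaked_train(ev, 2, background = 8, seed = 6)
  z1 <- zeta_test(tr, ev, resamples = 100, seed = 7)
  z2 <- zeta_test(tr, ev, resamples = 100, seed = 7)
  expect_identical(z1$p, z2$p)
  expect_lt(z1$p, 0.01)                      # reliable peak is detected
  expect_true(z1$p > 0 && z1$p <= 1)
  expect_equal(z1$zeta_corrected, qnorm(1 - z1$p / 2), tolerance = 1e-9)

  z0 <- zeta_test(spike_train(numeric(0)), ev, resamples = 50, seed = 1)
  expect_equal(z0$p, 1)
  expect_true(z0$no_spikes)
  expect_equal(z0$zeta_raw, 0)
})

test_that("null p-values are roughly uniform for an unmodulated neuron", {
  set.seed(8)
  p <- replicate(100, {
    tr <- poisson_train(15, 30)
    zeta_test(tr, event_grid(15, 2), resamples = 60,
              seed = sample.int(1e6, 1))$p
  })
  expect_gt(median(p), 0.25)
  expect_lt(median(p), 0.75)
  expect_lt(mean(p < 0.05), 0.15)
})

test_that("zeta is invariant to circular shifts of the event times", {
  set.seed(9)
  q <- 20
  tau <- 1.5
  total <- q * tau
  x <- sort(runif(300, 0, total))
  w <- (seq_len(q) - 1) * tau
  # sentinel-free curve: the invariance is exact
  zeta_pure <- function(x, w) {
    v <- pool_relative_spikes(x, event_series(w), tau = tau)$v
    v <- v[-c(1, length(v))]
    delta <- seq_along(v) / length(v) - v / tau
    max(abs(delta - mean(delta)))
  }
  # runtime statistic: the two fixed sentinels add an O(2/n) edge effect
  zeta_runtime <- function(x, w) {
    rel <- pool_relative_spikes(x, event_series(w), tau = tau)
    zeta_statistic(deviation_curve(rel))$zeta_raw
  }
  z0p <- zeta_pure(x, w)
  z0r <- zeta_runtime(x, w)
  n <- length(x) + 2
  for (delta in c(0.211, 0.5, 0.75, 1.234)) {
    x_wrapped <- sort(c(x[x >= delta], x[x < delta] + total))
    expect_equal(zeta_pure(x_wrapped, w + delta), z0p, tolerance = 1e-12)
    expect_lt(abs(zeta_runtime(x_wrapped, w + delta) - z0r), 4 / n)
  }
})
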