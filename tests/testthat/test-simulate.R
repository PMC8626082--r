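test_that("all generators are reproducible from (params, seed)", {
  gens <- list(
    function(s) simulate_tuned_poisson(3, repeats = 2, seed = s),
    function(s) simulate_rate_duration_grid(0.5, 0.5, n_neurons = 3,
                                            trials = 10, seed = s),
    function(s) simulate_bursting(3, repeats = 2, seed = s),
    function(s) simulate_peak_latency(3, trials = 20, seed = s))
  for (g in gens) {
    a <- g(101)
    b <- g(101)
    c_ <- g(102)
    for (i in seq_along(a$trains)) {
      expect_identical(a$trains[[i]]$times, b$trains[[i]]$times)
    }
    expect_false(identical(a$trains[[1]]$times, c_$trains[[1]]$times))
    expect_identical(a$truth, b$truth)
  }
})

test_that("tuned-Poisson rate parameters have the prescribed means", {
  pop <- simulate_tuned_poisson(2000, seed = 40, rates_only = TRUE)
  mb <- pop$truth$mu_base
  ms <- pop$truth$mu_stim
  expect_lt(abs(mean(mb) - 5), 3 * sd(mb) / sqrt(length(mb)))
  expect_lt(abs(mean(ms) - 25), 3 * sd(ms) / sqrt(length(ms)))
  expect_null(pop$trains)
})

test_that("tuned-Poisson spike counts track the drawn rates", {
  pop <- simulate_tuned_poisson(30, seed = 41)
  for (i in seq_len(5)) {
    ev <- pop$events[[i]]
    x <- pop$trains[[i]]$times
    # ITI epochs run at mu_base: compare realized vs expected count
    iti_count <- sum(zetatest:::epoch_counts(x, ev$onsets, 1, 2))
    expected <- pop$truth$mu_base[i] * ev$q
    expect_lt(abs(iti_count - expected), 5 * sqrt(expected + 1))
  }
  # spike counts per direction peak at the preferred direction for a
  # strongly tuned neuron
  j <- which.max(pop$truth$mu_stim - pop$truth$mu_base)
  ev <- pop$events[[j]]
  cnt <- zetatest:::epoch_counts(pop$trains[[j]]$times, ev$onsets, 0, 1)
  percir <- tapply(cnt, ev$labels, mean)
  dirs <- as.numeric(names(percir)) * pi / 180
  dist_pref <- pmin(abs(dirs - pop$truth$theta[j]),
                    abs(dirs - pop$truth$theta[j] - pi),
                    abs(dirs - pop$truth$theta[j] + pi),
                    abs(dirs - pop$truth$theta[j] - 2 * pi))
  expect_lt(dist_pref[which.max(percir)], pi / 4)
})

test_that("rate/duration grid conserves the stimulus-second spike count", {
  for (par in list(c(0, 1), c(0.5, 0.5), c(1, 0.75))) {
    pop <- simulate_rate_duration_grid(par[1], par[2], n_neurons = 30,
                                       trials = 50, seed = 42 + par[1] * 10)
    counts <- unlist(lapply(seq_along(pop$trains), function(i) {
      zetatest:::epoch_counts(pop$trains[[i]]$times,
                              pop$events[[i]]$onsets, 0, 1)
    }))
    expected <- 1 + par[1]
    expect_lt(abs(mean(counts) - expected),
              4 * sd(counts) / sqrt(length(counts)))
  }
  expect_error(simulate_rate_duration_grid(0.5, 0), "t_r")
  expect_false(simulate_rate_duration_grid(0, 1, n_neurons = 1, trials = 5,
                                           seed = 1)$truth$modulated[1])
  expect_true(simulate_rate_duration_grid(0, 0.5, n_neurons = 1, trials = 5,
                                          seed = 1)$truth$modulated[1])
})

test_that("bursting populations have matched rates but distinct structure", {
  pr <- simulate_bursting(150, responsive = TRUE, seed = 43)
  pu <- simulate_bursting(150, responsive = FALSE, seed = 44)
  # responsive/unresponsive marginal rate distributions overlap strongly
  ks <- suppressWarnings(ks.test(pr$truth$rate_hz, pu$truth$rate_hz))
  expect_gt(ks$p.value, 0.01)
  qr <- quantile(pr$truth$rate_hz, c(0.25, 0.75))
  qu <- quantile(pu$truth$rate_hz, c(0.25, 0.75))
  expect_lt(max(abs(qr - qu) / qr), 0.25)

  # burst-intensity scales: preferred-direction inter-burst intervals are
  # below ~1.3 s on average, baseline ones tens of seconds
  peak_int <- pr$truth$r_b +
    pr$truth$r_t * von_mises_pdf(0, 0, pr$truth$kappa)
  expect_lt(1 / mean(peak_int), 1.3)
  expect_gt(1 / mean(pr$truth$r_b), 12)
  expect_lt(1 / mean(pr$truth$r_b), 30)
})

test_that("peak-latency neurons place the extra spikes as specified", {
  # background off: ~trials/2 spikes, all near 100 ms after an onset
  pop0 <- simulate_peak_latency(5, base_rate = 0, trials = 100, seed = 45)
  for (i in seq_len(5)) {
    x <- pop0$trains[[i]]$times
    expect_equal(length(x), 50)
    rel <- x - pop0$events[[i]]$onsets[findInterval(x,
                                                    pop0$events[[i]]$onsets)]
    expect_true(all(rel > 0.05 & rel < 0.15))
  }
  # at 32 Hz the added spikes are ~0.78% of the total
  pop32 <- simulate_peak_latency(30, base_rate = 32, trials = 100, seed = 46)
  frac <- 50 / mean(vapply(pop32$trains, function(tr) length(tr$times),
                           numeric(1)))
  expect_equal(frac, 0.0078, tolerance = 0.05)
})

test_that("null twins preserve the stated train/event structure", {
  pop <- simulate_tuned_poisson(5, repeats = 3, seed = 47)
  tw <- make_null_twin(pop, mode = "jitter", seed = 48)
  for (i in 1:5) {
    expect_identical(tw$trains[[i]]$times, pop$trains[[i]]$times)
    expect_false(identical(tw$events[[i]]$onsets, pop$events[[i]]$onsets))
    expect_equal(tw$events[[i]]$q, pop$events[[i]]$q)
  }
  expect_false(any(tw$truth$modulated))

  tw2 <- make_null_twin(pop, mode = "isi-shuffle", seed = 49)
  for (i in 1:5) {
    x0 <- pop$trains[[i]]$times
    x1 <- tw2$trains[[i]]$times
    expect_length(x1, length(x0))
    expect_equal(max(x1) - min(x1), max(x0) - min(x0), tolerance = 1e-9)
    expect_identical(tw2$events[[i]]$onsets, pop$events[[i]]$onsets)
  }
})
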