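test_that("detect_spikes finds threshold crossings and merges refractory ones", {
  t <- seq(0, 1000, by = 0.1)
  quiet <- make_trace(t, rep(-60, length(t)))
  expect_length(detect_spikes(quiet)$times, 0)
  # three well-separated spikes as narrow triangular bumps
  v <- rep(-60, length(t))
  for (ts in c(200, 500, 800)) v[abs(t - ts) < 1] <- 20
  expect_equal(detect_spikes(make_trace(t, v))$times,
               c(200, 500, 800), tolerance = 0.01)
  # two crossings 1 ms apart with 2 ms refractory merge into one
  v2 <- rep(-60, length(t))
  v2[abs(t - 300) < 0.3] <- 20
  v2[abs(t - 301) < 0.3] <- 20
  expect_length(detect_spikes(make_trace(t, v2), refractory = 2)$times, 1)
})

test_that("rate_histogram counts per sweep and bin", {
  h0 <- rate_histogram(list(numeric(0), numeric(0)), bin = 20,
                       window = c(0, 200))
  expect_true(all(h0$rate == 0))
  # one spike per sweep in one 20 ms bin -> 50 Hz
  h1 <- rate_histogram(lapply(1:10, function(i) 110 + i * 0.1), bin = 20,
                       window = c(0, 200))
  expect_equal(h1$rate[h1$centers == 110], 50)
  expect_true(all(h1$rate[h1$centers != 110] == 0))
  expect_error(rate_histogram(list(1), bin = 0), "bin")
})

test_that("rate_histogram recovers a homogeneous Poisson rate", {
  n_sweeps <- 200
  dur <- 2000
  rate <- 5
  set.seed(99)
  trains <- lapply(seq_len(n_sweeps), function(i) {
    sort(runif(rpois(1, rate * dur / 1000), 0, dur))
  })
  h <- rate_histogram(trains, bin = 20, window = c(0, dur),
                      baseline_window = c(0, dur))
  se <- sqrt(rate / (n_sweeps * (dur / 1000)))
  expect_lt(abs(mean(h$rate) - rate), 3 * se)
  expect_equal(h$baseline, mean(h$rate))
})

test_that("pause_rebound on a flat histogram flags no crossings", {
  h <- bin_profile(list(time = 0:4000, rate = rep(6, 4001)), bin = 20,
                   align = 1000, window = c(-1000, 2000))
  pr <- pause_rebound(h)
  expect_equal(pr$pause_amplitude, 100)
  expect_true(is.na(pr$pause_onset) && is.na(pr$pause_end))
  expect_true(is.na(pr$rebound_onset))
})

test_that("pause_rebound recovers a hand-computable rectangular dip", {
  # 100% everywhere except three consecutive 20 ms bins at 40%
  rate <- rep(10, 150)
  rate[76:78] <- 4
  h <- structure(list(edges = seq(0, 3000, by = 20),
                      centers = seq(10, 2990, by = 20), rate = rate,
                      n_sweeps = 1, baseline = 10,
                      baseline_window = c(-Inf, 1400), bin = 20),
                 class = "rate_histogram")
  pr <- pause_rebound(h, search_window = c(1400, 1700))
  expect_equal(pr$pause_amplitude, 40)       # centered 3-bin moving average
  expect_equal(pr$pause_duration, 60, tolerance = 20 / 60)  # within 1 bin
  expect_equal(pr$pause_onset, 1500, tolerance = 20 / 1500)
})

test_that("pause_rebound orders dip before peak and is scale invariant", {
  rate <- rep(8, 150)
  rate[80:85] <- 2          # pause
  rate[90:95] <- 14         # rebound
  mk <- function(r) structure(
    list(edges = seq(0, 3000, by = 20), centers = seq(10, 2990, by = 20),
         rate = r, n_sweeps = 1, baseline = mean(r[1:50]),
         baseline_window = c(-Inf, 1000), bin = 20),
    class = "rate_histogram")
  pr <- pause_rebound(mk(rate), search_window = c(1500, 2100))
  expect_lte(pr$pause_end, pr$rebound_onset)
  expect_lt(pr$pause_amplitude, 100)
  expect_gt(pr$rebound_amplitude, 100)
  pr2 <- pause_rebound(mk(rate * 3.7), search_window = c(1500, 2100))
  expect_equal(pr2$pause_amplitude, pr$pause_amplitude)
  expect_equal(pr2$rebound_amplitude, pr$rebound_amplitude)
  expect_equal(pr2$pause_duration, pr$pause_duration)
  bad <- mk(rate)
  bad$baseline <- 0
  expect_error(pause_rebound(bad), "baseline")
})

test_that("undershoot measures trough, peak, ratio and latency", {
  t <- seq(0, 2000, by = 0.5)
  ep <- list(input = c(200, 1000))
  flat <- make_trace(t, rep(-40, length(t)), rmp = -40, epochs = ep)
  u0 <- undershoot(flat)
  expect_equal(u0$trough, 0)
  expect_equal(u0$ratio, 0)
  # constructed dip of 2.72 mV below rest at t = 1300, peak +5 during input
  v <- rep(-40, length(t))
  v <- v + 5 * exp(-((t - 600) / 100)^2) - 2.72 * exp(-((t - 1300) / 80)^2)
  tr <- make_trace(t, v, rmp = -40, epochs = ep)
  u <- undershoot(tr)
  expect_equal(u$trough, 2.72, tolerance = 1e-6)
  expect_equal(u$peak, 5, tolerance = 1e-6)
  expect_equal(u$trough_latency, 300, tolerance = 1e-6)
  # linear scaling doubles both, leaves the ratio unchanged
  tr2 <- make_trace(t, -40 + 2 * (v + 40), rmp = -40, epochs = ep)
  u2 <- undershoot(tr2)
  expect_equal(u2$trough, 2 * u$trough, tolerance = 1e-6)
  expect_equal(u2$ratio, u$ratio, tolerance = 1e-6)
  expect_error(undershoot(make_trace(t, v, rmp = -40)), "input")
})

test_that("phase_lag recovers analytic shifts at the reference frequency", {
  centers <- seq(10, 3990, by = 20)
  prof <- function(shift_deg) {
    list(centers = centers,
         rate = 5 + 3 * cos(2 * pi * centers / 1000 - shift_deg * pi / 180))
  }
  expect_equal(phase_lag(prof(0), prof(0), 1), 0, tolerance = 1e-9)
  expect_equal(phase_lag(prof(0), prof(90), 1), 90, tolerance = 2)
  anti <- prof(0)
  anti$rate <- 10 - anti$rate
  expect_equal(abs(phase_lag(prof(0), anti, 1)), 180, tolerance = 2)
  # antisymmetry modulo wrapping
  for (d in c(30, 60, 135)) {
    expect_equal(phase_lag(prof(0), prof(d), 1),
                 -phase_lag(prof(d), prof(0), 1), tolerance = 1e-6)
  }
  flat <- list(centers = centers, rate = rep(4, length(centers)))
  expect_error(phase_lag(flat, flat, 1), "power")
})

test_that("classify_unit applies the extracellular criteria", {
  expect_equal(classify_unit(5, 1.3, 30), "pChI")
  expect_equal(classify_unit(0.4, 1.3, 30), "SPN")
  expect_equal(classify_unit(5, 1.3, 8), "LTS")
  expect_equal(classify_unit(15, 0.6, 3), "FSI")
  expect_equal(classify_unit(15, 1.3, 30), "unclassified")
})

test_that("rate_voltage_correlation is 1 for linear relations, low for noise", {
  t <- seq(0, 10000, by = 1)
  v <- -50 + 10 * sin(2 * pi * t / 2000)
  tr <- make_trace(t, v)
  centers <- seq(10, 9990, by = 20)
  lin <- list(centers = centers,
              rate = 5 + 2 * sin(2 * pi * centers / 2000))
  expect_equal(rate_voltage_correlation(lin, tr), 1, tolerance = 1e-4)
  neg <- lin
  neg$rate <- 10 - lin$rate
  expect_equal(rate_voltage_correlation(neg, tr), 1, tolerance = 1e-4)
  # independent white noise: r^2 stays small for most seeds
  set.seed(5)
  r2 <- vapply(1:20, function(i) {
    rate_voltage_correlation(
      list(centers = centers, rate = runif(length(centers))),
      make_trace(t, rnorm(length(t))))
  }, 0)
  expect_gte(mean(r2 < 0.1), 0.9)
  flat <- list(centers = centers, rate = rep(2, length(centers)))
  expect_error(rate_voltage_correlation(flat, tr), "constant")
})

test_that("spike trains round-trip through delimited text", {
  trains <- list(spike_train(c(10, 55.5, 120)), spike_train(numeric(0)),
                 spike_train(c(3.25, 99)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spike_trains(trains, path)
  rt <- read_spike_trains(path)
  expect_equal(length(rt), 2)                  # empty sweep drops out
  expect_equal(rt[[1]]$times, c(10, 55.5, 120))
  expect_equal(rt[[2]]$times, c(3.25, 99))
  expect_error(spike_train(c(5, 4)), "increasing")
})
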